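# Quadripartite structure: inverted-repeat detection by seed-and-extend,
# LSC/IRa/SSC/IRb partitioning, and the one-IR-trimmed linearisation used by
# all downstream variability analyses.

#' Find the large inverted repeat of a plastome
#'
#' Seed-and-extend search for the maximal pair of non-overlapping intervals
#' whose sequences are reverse complements up to a mismatch budget. Exact
#' k-mer seeds (k = 25 by default) are matched against the reverse
#' complement of the genome, grouped by anti-diagonal (ungapped inverted
#' matches share the constant `start_a + end_b`), and the best group is
#' extended outwards base by base with an X-drop stop (match +1, mismatch
#' -1, stop when the running score falls `xdrop` below its maximum, then
#' trimmed back to the maximum).
#'
#' @param genome a `"plastome"`.
#' @param min_len minimum acceptable repeat length in bp. Plastid IRs are
#'   typically ~25 kb; the permissive default of 1000 costs nothing.
#' @param max_mismatch_frac maximum tolerated fraction of mismatched
#'   positions over the final repeat interval; must be below 0.1.
#' @param k seed k-mer length.
#' @param xdrop X-drop budget in mismatch-equivalents for the extension.
#' @return an object of class `"ir_hit"`: a list with `found` (logical),
#'   and if found `ira`/`irb` (integer `c(start, end)`, `ira` the
#'   lower-coordinate copy), `length`, `mismatches` and `mismatch_frac`.
#'   When no repeat of at least `min_len` exists the result has
#'   `found = FALSE` rather than raising an error.
#' @export
find_inverted_repeat <- function(genome, min_len = 1000L,
                                 max_mismatch_frac = 0.01,
                                 k = 25L, xdrop = 20L) {
  stopifnot(inherits(genome, "plastome"))
  if (max_mismatch_frac < 0 || max_mismatch_frac >= 0.1) {
    stop("max_mismatch_frac must be in [0, 0.1)")
  }
  L <- genome$length
  if (L < 2L * min_len) stop("genome shorter than twice min_len")
  no_hit <- structure(list(found = FALSE, min_len = min_len), class = "ir_hit")

  S <- Biostrings::DNAString(genome$residues)
  RC <- Biostrings::reverseComplement(S)
  chars <- strsplit(genome$residues, "", fixed = TRUE)[[1]]
  cchars <- comp_chars(chars)

  # stride-k seeds; skip seeds containing ambiguity codes
  starts <- seq.int(1L, L - k + 1L, by = k)
  seqs <- substring(genome$residues, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", seqs)
  starts <- starts[ok]; seqs <- seqs[ok]
  if (length(starts) == 0) return(no_hit)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs))
  hits <- Biostrings::matchPDict(pd, RC)

  # pair seed p (start in S) with the start p2 of its reverse-complemented
  # image in S coordinates; ungapped inverted pairs share d = p + p2 + k - 1,
  # i.e. position x in copy A pairs with position d - x in copy B
  pairs <- list()
  for (i in seq_along(hits)) {
    st <- BiocGenerics::start(hits[[i]])
    if (length(st) == 0) next
    p <- starts[i]
    p2 <- L - st - k + 2L
    keep <- p2 > p + k - 1L   # image strictly downstream: ordered, non-overlapping
    if (any(keep)) pairs[[length(pairs) + 1L]] <- cbind(p = p, p2 = p2[keep])
  }
  if (length(pairs) == 0) return(no_hit)
  pm <- do.call(rbind, pairs)
  d <- pm[, "p"] + pm[, "p2"] + k - 1L

  # score along one anti-diagonal: match vector over valid x range
  diag_match <- function(dd) {
    x_lo <- max(1L, dd - L)
    x_hi <- (dd - 1L) %/% 2L
    if (x_lo > x_hi) return(NULL)
    xs <- x_lo:x_hi
    list(xs = xs, m = chars[xs] == cchars[dd - xs])
  }

  xdrop_extend <- function(m, from, step) {
    # walk from index `from` in direction `step` over logical match vector m,
    # returning the index achieving the best running score (match +1,
    # mismatch -3: chance matches in flanking sequence, ~25% per position,
    # then score a steep downhill walk and do not drag the border outwards)
    best <- 0L; cur <- 0L; best_i <- from - step
    i <- from
    while (i >= 1L && i <= length(m)) {
      cur <- cur + if (m[i]) 1L else -3L
      if (cur > best) { best <- cur; best_i <- i }
      if (best - cur > xdrop) break
      i <- i + step
    }
    best_i
  }

  best <- NULL
  counts <- sort(table(d), decreasing = TRUE)
  cand_diags <- as.integer(names(counts))[seq_len(min(length(counts), 20L))]
  for (dd in cand_diags) {
    seed_p <- pm[d == dd, "p"]
    dm <- diag_match(dd)
    if (is.null(dm)) next
    core_lo <- match(min(seed_p), dm$xs)
    core_hi <- match(max(seed_p) + k - 1L, dm$xs)
    if (is.na(core_lo) || is.na(core_hi)) next
    # xdrop_extend returns the index achieving the best score (or the core
    # border itself when no outward step improves)
    lo <- xdrop_extend(dm$m, core_lo - 1L, -1L)
    hi <- xdrop_extend(dm$m, core_hi + 1L, +1L)
    # borders always sit on exact matches
    while (lo < hi && !dm$m[lo]) lo <- lo + 1L
    while (hi > lo && !dm$m[hi]) hi <- hi - 1L
    a1 <- dm$xs[lo]; a2 <- dm$xs[hi]
    b1 <- dd - a2; b2 <- dd - a1
    if (b1 <= a2) {  # extension ran into overlap: trim symmetrically
      over <- a2 - b1 + 1L
      cut <- (over + 1L) %/% 2L
      a2 <- a2 - cut; b1 <- b1 + cut
      hi <- hi - cut
      if (hi < lo) next
    }
    len <- a2 - a1 + 1L
    if (len < min_len) next
    mism <- sum(!dm$m[lo:hi])
    if (mism / len > max_mismatch_frac) {
      # trim mismatching flanks greedily and re-check
      mm <- dm$m[lo:hi]
      while (length(mm) >= min_len && sum(!mm) / length(mm) > max_mismatch_frac) {
        if (!mm[1]) mm <- mm[-1]
        else if (!mm[length(mm)]) mm <- mm[-length(mm)]
        else break
        if (!dm$m[lo]) { lo <- lo + 1L; a1 <- a1 + 1L; b2 <- b2 - 1L }
        else { hi <- hi - 1L; a2 <- a2 - 1L; b1 <- b1 + 1L }
      }
      len <- a2 - a1 + 1L
      mism <- sum(!dm$m[lo:hi])
      if (len < min_len || mism / len > max_mismatch_frac) next
    }
    cand <- list(found = TRUE, ira = c(a1, a2), irb = c(b1, b2),
                 length = len, mismatches = mism, mismatch_frac = mism / len)
    if (is.null(best) || cand$length > best$length ||
        (cand$length == best$length && cand$ira[1] < best$ira[1])) {
      best <- cand
    }
  }
  if (is.null(best)) return(no_hit)
  structure(best, class = "ir_hit")
}

#' @export
print.ir_hit <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("<ir_hit> no inverted repeat of >= %d bp found\n", x$min_len))
  } else {
    cat(sprintf("<ir_hit> IRa %s, IRb %s (%s bp, %d mismatches, %.3f%%)\n",
                fmt_iv(x$ira), fmt_iv(x$irb),
                format(x$length, big.mark = ","), x$mismatches,
                100 * x$mismatch_frac))
  }
  invisible(x)
}

#' Reconcile the borders of an inverted-repeat pair
#'
#' If the two intervals differ in length by at most `tol` bp the longer one
#' is trimmed symmetrically; a larger disagreement is an error. Ungapped
#' extension produces equal lengths by construction, so this is a guard for
#' externally supplied coordinates.
#'
#' @param ira,irb integer `c(start, end)` intervals.
#' @param tol maximum tolerated length difference in bp.
#' @return list with reconciled `ira` and `irb`.
#' @export
reconcile_ir_borders <- function(ira, irb, tol = 2L) {
  la <- ira[2] - ira[1] + 1L
  lb <- irb[2] - irb[1] + 1L
  if (abs(la - lb) > tol) {
    stop("inverted repeat copies differ in length by ", abs(la - lb),
         " bp (> ", tol, ")")
  }
  if (la > lb) {
    extra <- la - lb
    ira <- c(ira[1] + extra %/% 2L, ira[2] - (extra - extra %/% 2L))
  } else if (lb > la) {
    extra <- lb - la
    irb <- c(irb[1] + extra %/% 2L, irb[2] - (extra - extra %/% 2L))
  }
  list(ira = ira, irb = irb)
}

#' Partition a plastome into its quadripartite structure
#'
#' Given the two inverted-repeat intervals, the longer of the two arcs
#' between them is the large single-copy region (LSC) and the shorter the
#' small single-copy region (SSC). By convention IRa is the repeat copy
#' immediately following the LSC in circular order. When the two arcs are
#' exactly equal the arc containing position 1 is taken as LSC and a
#' warning is issued.
#'
#' @param genome a `"plastome"`.
#' @param ira,irb integer `c(start, end)` intervals (from
#'   [find_inverted_repeat()] or an `"ir_hit"` passed as `ira`).
#' @return an object of class `"quadripartite"`: list with intervals `lsc`,
#'   `ira`, `ssc`, `irb` (each `c(start, end)`; single-copy arcs that wrap
#'   the origin have `end < start`) and lengths `lsc_len`, `ir_len`,
#'   `ssc_len`, `total_len` satisfying
#'   `total_len == lsc_len + 2 * ir_len + ssc_len`.
#' @export
partition_quadripartite <- function(genome, ira, irb = NULL) {
  if (inherits(ira, "ir_hit")) {
    if (!ira$found) stop("no inverted repeat found; cannot partition")
    irb <- ira$irb; ira <- ira$ira
  }
  L <- genome$length
  rec <- reconcile_ir_borders(ira, irb)
  ira <- rec$ira; irb <- rec$irb
  if (ira[1] > irb[1]) { tmp <- ira; ira <- irb; irb <- tmp }
  if (ira[2] >= irb[1]) stop("inverted repeat intervals overlap")
  ir_len <- ira[2] - ira[1] + 1L

  arc_len <- function(s, e) if (s > e) (L - s + 1L) + e else e - s + 1L
  # inner arc between the copies, outer arc wrapping through the origin
  inner <- c(ira[2] + 1L, irb[1] - 1L)
  outer <- c((irb[2] %% L) + 1L, ira[1] - 1L)
  if (ira[1] == 1L) outer <- c((irb[2] %% L) + 1L, L)  # degenerate: arc ends at L
  inner_len <- if (inner[1] > irb[1] - 1L) 0L else arc_len(inner[1], inner[2])
  outer_len <- L - 2L * ir_len - inner_len
  if (inner_len == outer_len) {
    warning("single-copy arcs have equal length; taking the arc containing ",
            "position 1 as LSC")
  }
  outer_is_lsc <- outer_len > inner_len ||
    (outer_len == inner_len && (ira[1] > 1L || irb[2] < L))
  if (outer_is_lsc) {
    lsc <- outer; ssc <- inner
    lsc_len <- outer_len; ssc_len <- inner_len
    ira_iv <- ira; irb_iv <- irb   # IRa follows the LSC (which ends at ira[1]-1)
  } else {
    lsc <- inner; ssc <- outer
    lsc_len <- inner_len; ssc_len <- outer_len
    ira_iv <- irb; irb_iv <- ira   # LSC is the inner arc; the copy after it is IRa
  }
  structure(list(lsc = lsc, ira = ira_iv, ssc = ssc, irb = irb_iv,
                 lsc_len = lsc_len, ir_len = ir_len, ssc_len = ssc_len,
                 total_len = L),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  cat(sprintf(paste0("<quadripartite> LSC %s (%s bp) | IRa %s | SSC %s ",
                     "(%s bp) | IRb %s (IR %s bp); total %s bp\n"),
              fmt_iv(x$lsc), format(x$lsc_len, big.mark = ","),
              fmt_iv(x$ira), fmt_iv(x$ssc),
              format(x$ssc_len, big.mark = ","), fmt_iv(x$irb),
              format(x$ir_len, big.mark = ","),
              format(x$total_len, big.mark = ",")))
  invisible(x)
}

#' Quadripartite structure as a one-row report table
#'
#' @param structure a `"quadripartite"`.
#' @param species label for the row.
#' @return data frame with columns `species`, `lsc`, `ir`, `ssc`, `total`.
#' @export
structure_report <- function(structure, species = "reference") {
  data.frame(species = species, lsc = structure$lsc_len, ir = structure$ir_len,
              ssc = structure$ssc_len, total = structure$total_len,
              stringsAsFactors = FALSE)
}

## positions of one arc in circular order
arc_positions <- function(iv, L) {
  if (iv[1] > iv[2]) c(iv[1]:L, 1L:iv[2]) else iv[1]:iv[2]
}

#' Trim one inverted-repeat copy
#'
#' Returns the linearised LSC + IRa + SSC sequence of length
#' `total_len - ir_len`, the standard working sequence for variability
#' profiling (IR positions would otherwise be counted twice). The retained
#' copy is IRa, the one adjacent to the LSC end, which fixes reporting
#' coordinates deterministically. A coordinate map back to the full genome
#' is returned alongside.
#'
#' @param genome a `"plastome"`.
#' @param structure a `"quadripartite"`. With `ir_len == 0` the sequence is
#'   returned unchanged.
#' @return an object of class `"trimmed_plastome"`: list with `genome` (the
#'   linear trimmed `"plastome"`), `to_full` (integer vector mapping trimmed
#'   position i to its full-genome coordinate), and `structure` (the input).
#'   Use [trimmed_to_full()] and [full_to_trimmed()] to convert positions.
#' @export
trim_one_ir <- function(genome, structure) {
  L <- genome$length
  if (structure$ir_len == 0L) {
    to_full <- seq_len(L)
  } else {
    to_full <- c(arc_positions(structure$lsc, L),
                 arc_positions(structure$ira, L),
                 arc_positions(structure$ssc, L))
  }
  chars <- strsplit(genome$residues, "", fixed = TRUE)[[1]]
  trimmed <- plastome_sequence(paste0(genome$id, "_trimmed"),
                               paste(chars[to_full], collapse = ""),
                               circular = FALSE)
  structure(list(genome = trimmed, to_full = to_full, structure = structure),
            class = "trimmed_plastome")
}

#' Map trimmed coordinates to full-genome coordinates
#' @param trim a `"trimmed_plastome"`.
#' @param pos integer positions on the trimmed sequence.
#' @return full-genome positions.
#' @export
trimmed_to_full <- function(trim, pos) {
  stopifnot(all(pos >= 1L), all(pos <= trim$genome$length))
  trim$to_full[pos]
}

#' Map full-genome coordinates to trimmed coordinates
#'
#' Positions falling in the trimmed-off IR copy return `NA`.
#'
#' @param trim a `"trimmed_plastome"`.
#' @param pos integer positions on the full genome.
#' @return trimmed positions, `NA` where the position was trimmed away.
#' @export
full_to_trimmed <- function(trim, pos) {
  lut <- integer(0)
  lut[trim$to_full] <- seq_along(trim$to_full)
  out <- lut[pos]
  out[out == 0L] <- NA_integer_
  out
}

#' Collapse inverted-repeat duplicate positions
#'
#' A variable position inside the IR appears at two coordinates of the full
#' genome. For "each variable position counted once" semantics, positions
#' in the trimmed-off copy (IRb) are mapped to their mirror position in the
#' retained copy (IRa) and the set is deduplicated.
#'
#' @param positions integer positions on the full genome.
#' @param structure a `"quadripartite"`.
#' @return sorted unique positions with IRb mirrored into IRa.
#' @export
collapse_ir_duplicates <- function(positions, structure) {
  irb <- structure$irb; ira <- structure$ira
  in_irb <- positions >= irb[1] & positions <= irb[2]
  # IRb is the reverse complement of IRa: offset t from IRb start mirrors
  # to offset t from IRa end
  positions[in_irb] <- ira[2] - (positions[in_irb] - irb[1])
  sort(unique(positions))
}
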