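# Selection of variable single-copy target regions and construction of
# locus-specific primers with Illumina-complementary 5' tails.

#' Illumina adapter-complementary tail sequences
#'
#' Fixed 5' extensions appended to every locus-specific primer so that
#' sequencing libraries can be prepared directly from pooled amplicons.
#'
#' @format list with elements `fwd` and `rev`.
#' @export
tail_spec <- function() {
  list(fwd = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
       rev = "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG")
}

#' Select target anchor positions from filtered SNP calls
#'
#' Two selection rules, applied position by position and restricted to the
#' single-copy regions (LSC and SSC):
#'
#' 1. `ingroup_variant`: at least one ingroup taxon carries a non-reference
#'    allele — except where *every* ingroup taxon carries a non-reference
#'    allele (such positions separate the whole ingroup from the reference
#'    but are useless within the ingroup);
#' 2. `outgroup_pair_variant`: at least two outgroup taxa carry
#'    non-reference alleles.
#'
#' Missing genotypes never count as variant, and a missing genotype
#' prevents the "every taxon variant" exception from firing.
#'
#' @param snps a filtered `"snp_table"` of substitution calls.
#' @param clades a `"clade_map"`.
#' @param structure a `"quadripartite"`; positions inside either IR copy
#'   are excluded.
#' @return data frame with columns `position` and `rule` (positions
#'   matching rule 1 are labelled `ingroup_variant` even if rule 2 also
#'   applies). May be empty.
#' @export
select_targets <- function(snps, clades, structure) {
  in_taxa <- intersect(clade_taxa(clades, "ingroup"), snp_taxa(snps))
  out_taxa <- intersect(clade_taxa(clades, "outgroup"), snp_taxa(snps))
  if (nrow(snps) == 0L) {
    return(data.frame(position = integer(0), rule = character(0),
                      stringsAsFactors = FALSE))
  }
  is_alt <- function(taxa) {
    m <- as.matrix(snps[, taxa, drop = FALSE])
    alt <- !is.na(m) & m != snps$ref_allele
    miss <- is.na(m)
    list(n_alt = rowSums(alt), n_miss = rowSums(miss), n = length(taxa))
  }
  ing <- is_alt(in_taxa)
  outg <- is_alt(out_taxa)
  rule1 <- ing$n_alt >= 1L & !(ing$n_alt == ing$n & ing$n_miss == 0L)
  rule2 <- outg$n_alt >= 2L
  in_sc <- in_interval(snps$position, structure$lsc, structure$total_len) |
    in_interval(snps$position, structure$ssc, structure$total_len)
  sel <- (rule1 | rule2) & in_sc
  data.frame(position = snps$position[sel],
             rule = ifelse(rule1[sel], "ingroup_variant",
                           "outgroup_pair_variant"),
             stringsAsFactors = FALSE)
}

## is position inside a (possibly origin-wrapping) interval
in_interval <- function(pos, iv, L) {
  if (iv[1] > iv[2]) (pos >= iv[1] & pos <= L) | (pos >= 1 & pos <= iv[2])
  else pos >= iv[1] & pos <= iv[2]
}

#' Extract the flanked region around a target anchor
#'
#' Takes `flank` bp on either side of the anchor, clipped to the boundary
#' of the single-copy segment (LSC or SSC) containing it; target regions
#' must not extend into the duplicated IRs.
#'
#' @param anchor 1-based anchor position.
#' @param structure a `"quadripartite"`; an anchor inside an IR is an
#'   error.
#' @param flank flank width in bp (default 100).
#' @return data frame row with `start`, `end`, `anchors`, `rule`
#'   (`NA`), `merged_from`.
#' @export
extract_flanks <- function(anchor, structure, flank = 100L) {
  L <- structure$total_len
  seg <- if (in_interval(anchor, structure$lsc, L)) structure$lsc
         else if (in_interval(anchor, structure$ssc, L)) structure$ssc
         else stop("anchor ", anchor, " lies inside an inverted repeat; ",
                   "targets must be single-copy")
  # linear clipping within the arc; wrap-around arcs are clipped at the
  # origin on the side the anchor occupies
  lo <- if (seg[1] > seg[2] && anchor <= seg[2]) 1L else seg[1]
  hi <- if (seg[1] > seg[2] && anchor >= seg[1]) L else seg[2]
  data.frame(start = max(anchor - flank, lo, 1L),
             end = min(anchor + flank, hi, L),
             anchors = as.character(anchor), rule = NA_character_,
             merged_from = 1L, stringsAsFactors = FALSE)
}

#' Merge overlapping or book-ended target regions
#'
#' @param regions data frame with columns `start`, `end`, `anchors`
#'   (comma-separated anchor positions), sorted or not.
#' @return merged data frame; `merged_from` counts constituents and
#'   `anchors` concatenates their anchors.
#' @export
merge_targets <- function(regions) {
  if (nrow(regions) <= 1L) return(regions)
  regions <- regions[order(regions$start, regions$end), , drop = FALSE]
  out <- regions[1, , drop = FALSE]
  for (i in 2:nrow(regions)) {
    j <- nrow(out)
    if (regions$start[i] <= out$end[j] + 1L) {   # overlap or book-ended
      out$end[j] <- max(out$end[j], regions$end[i])
      out$anchors[j] <- paste(out$anchors[j], regions$anchors[i], sep = ",")
      out$merged_from[j] <- out$merged_from[j] + regions$merged_from[i]
    } else {
      out <- rbind(out, regions[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Build merged target regions from selected anchors
#'
#' Convenience composition of [extract_flanks()] and [merge_targets()].
#'
#' @param anchors data frame from [select_targets()].
#' @param structure a `"quadripartite"`.
#' @param flank flank width in bp.
#' @return merged target region data frame.
#' @export
build_targets <- function(anchors, structure, flank = 100L) {
  if (nrow(anchors) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      anchors = character(0), rule = character(0),
                      merged_from = integer(0), stringsAsFactors = FALSE))
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(anchors)), function(i) {
    r <- extract_flanks(anchors$position[i], structure, flank)
    r$rule <- anchors$rule[i]
    r
  }))
  merge_targets(rows)
}

## ---------------------------------------------------------------------------
## melting temperature

## nearest-neighbor thermodynamics, unified parameter set
## (dH kcal/mol, dS cal/(mol K)) per stacked dinucleotide
.nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature from nearest-neighbor stacking
#' thermodynamics with terminal initiation terms and a monovalent-salt
#' entropy correction (`0.368 * (N-1) * ln[Na+]`), at a stated total
#' strand concentration:
#' `Tm = 1000 * dH / (dS_corrected + R * ln(Ct/4)) - 273.15`.
#' Parameters are fixed in code so reported values are reproducible.
#'
#' @param seq DNA string of length >= 8; ambiguity codes are an error
#'   (their thermodynamics are undefined).
#' @param na_molar monovalent cation concentration in mol/L.
#' @param ct_molar total strand concentration in mol/L.
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, na_molar = 0.05, ct_molar = 5e-7) {
  seq <- toupper(seq)
  if (nchar(seq) < 8L) stop("sequence too short for a meaningful Tm (< 8 nt)")
  check_dna(seq, allowed = c("A", "C", "G", "T"), what = "primer sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  steps <- paste0(chars[-n], chars[-1])
  dh <- sum(.nn_dh[steps])
  ds <- sum(.nn_ds[steps])
  for (term in chars[c(1L, n)]) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1) * log(na_molar)
  1000 * dh / (ds + 1.987 * log(ct_molar / 4)) - 273.15
}

## ---------------------------------------------------------------------------
## primer picking

#' Primer design constraints
#'
#' @param min_len,max_len primer length bounds in nt.
#' @param opt_tm optimum melting temperature in degrees Celsius.
#' @param gc_min,gc_max hard GC-content bounds (fractions).
#' @param max_homopolymer longest tolerated homopolymer run (hard).
#' @param tm_weight penalty weight per degree of |Tm - opt_tm|.
#' @param tm_diff_weight penalty weight per degree of |Tm_fwd - Tm_rev|.
#' @param comp3_weight penalty weight per complementary base between the
#'   two primers' 3'-terminal pentamers (primer-dimer guard).
#' @param candidates_per_side number of best single-side candidates kept
#'   before pairing.
#' @return list of class `"primer_constraints"`.
#' @export
primer_constraints <- function(min_len = 18L, max_len = 27L, opt_tm = 68.5,
                               gc_min = 0.35, gc_max = 0.60,
                               max_homopolymer = 4L,
                               tm_weight = 1, tm_diff_weight = 0.5,
                               comp3_weight = 1,
                               candidates_per_side = 15L) {
  structure(as.list(environment()), class = "primer_constraints")
}

## candidate windows on one strand: data.frame(start, len, seq, tm)
.primer_candidates <- function(region_seq, lo, hi, reverse, cons) {
  # lo..hi are 1-based offsets within region_seq where the primer may sit
  out <- list()
  for (len in cons$min_len:cons$max_len) {
    starts <- lo:(hi - len + 1L)
    starts <- starts[starts >= lo & starts + len - 1L <= hi]
    for (s in starts) {
      core <- substr(region_seq, s, s + len - 1L)
      if (grepl("[^ACGT]", core)) next
      primer <- if (reverse) revcomp(core) else core
      gc <- gc_fraction(primer)
      if (is.na(gc) || gc < cons$gc_min || gc > cons$gc_max) next
      if (max_homopolymer(primer) > cons$max_homopolymer) next
      tm <- melting_temperature(primer)
      out[[length(out) + 1L]] <- data.frame(
        start = s, len = len, seq = primer, tm = tm,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(NULL)
  df <- do.call(rbind, out)
  df$pen <- cons$tm_weight * abs(df$tm - cons$opt_tm)
  df <- df[order(df$pen, df$start, df$len), , drop = FALSE]
  head(df, cons$candidates_per_side)
}

## complementarity between the 3'-terminal pentamers of two primers when
## annealed head-to-head
.comp3 <- function(fwd, rev) {
  f3 <- substr(fwd, nchar(fwd) - 4L, nchar(fwd))
  r3 <- substr(rev, nchar(rev) - 4L, nchar(rev))
  fc <- strsplit(f3, "")[[1]]
  rc <- rev(strsplit(r3, "")[[1]])
  sum(fc == comp_chars(rc))
}

#' Pick a primer pair for a target region
#'
#' Exhaustively scores forward-primer windows left of the leftmost anchor
#' and reverse-primer windows right of the rightmost anchor, subject to
#' hard constraints (length, GC content, homopolymer runs), then selects
#' the pair minimising a weighted penalty on Tm distance from the optimum,
#' Tm imbalance between the two primers, and 3'-end complementarity. Ties
#' break deterministically by leftmost forward primer, then shortest
#' product.
#'
#' @param region one target region row (`start`, `end`, `anchors`) in the
#'   coordinates of `genome`.
#' @param genome the `"plastome"` the coordinates refer to (typically the
#'   trimmed linearisation).
#' @param constraints a `"primer_constraints"`.
#' @param prefix name prefix; pairs are named `<prefix><anchor>F/R` after
#'   their first anchor.
#' @return an object of class `"primer_pair"` (fields `name`, `fwd_core`,
#'   `rev_core`, `fwd_tailed`, `rev_tailed`, `tm_fwd`, `tm_rev`,
#'   `product_span`, `found = TRUE`), or a `found = FALSE` result when no
#'   pair satisfies the hard constraints.
#' @export
pick_primers <- function(region, genome, constraints = primer_constraints(),
                         prefix = "Mint") {
  cons <- constraints
  anchors <- as.integer(strsplit(region$anchors, ",", fixed = TRUE)[[1]])
  rseq <- subseq_chr(genome$residues, region$start, region$end)
  a_lo <- min(anchors) - region$start + 1L
  a_hi <- max(anchors) - region$start + 1L
  rlen <- nchar(rseq)
  no_hit <- structure(list(found = FALSE, name = paste0(prefix, anchors[1])),
                      class = "primer_pair")
  if (a_lo - 1L < cons$min_len || rlen - a_hi < cons$min_len) return(no_hit)
  fwd <- .primer_candidates(rseq, 1L, a_lo - 1L, reverse = FALSE, cons)
  rev_ <- .primer_candidates(rseq, a_hi + 1L, rlen, reverse = TRUE, cons)
  if (is.null(fwd) || is.null(rev_)) return(no_hit)
  best <- NULL
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rev_))) {
      pen <- fwd$pen[i] + rev_$pen[j] +
        cons$tm_diff_weight * abs(fwd$tm[i] - rev_$tm[j]) +
        cons$comp3_weight * .comp3(fwd$seq[i], rev_$seq[j])
      prod_len <- (rev_$start[j] + rev_$len[j] - 1L) - fwd$start[i] + 1L
      key <- c(pen, fwd$start[i], prod_len)
      if (is.null(best) || pen < best$pen - 1e-12 ||
          (abs(pen - best$pen) <= 1e-12 &&
           (fwd$start[i] < best$f_start ||
            (fwd$start[i] == best$f_start && prod_len < best$prod_len)))) {
        best <- list(pen = pen, i = i, j = j, f_start = fwd$start[i],
                     prod_len = prod_len)
      }
    }
  }
  f <- fwd[best$i, ]; r <- rev_[best$j, ]
  tails <- append_tails(f$seq, r$seq)
  span <- c(region$start + f$start - 1L,
            region$start + r$start + r$len - 2L)
  structure(list(found = TRUE, name = paste0(prefix, anchors[1]),
                 fwd_core = f$seq, rev_core = r$seq,
                 fwd_tailed = tails$fwd_tailed, rev_tailed = tails$rev_tailed,
                 tm_fwd = f$tm, tm_rev = r$tm, product_span = span),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("<primer_pair> %s: no primer found\n", x$name))
  } else {
    cat(sprintf("<primer_pair> %s: F %s (Tm %.1f) / R %s (Tm %.1f), span %s\n",
                x$name, x$fwd_core, x$tm_fwd, x$rev_core, x$tm_rev,
                fmt_iv(x$product_span)))
  }
  invisible(x)
}

#' Append Illumina-complementary tails to primer cores
#'
#' Exact concatenation of the fixed tail constants with the locus-specific
#' cores, no separator. Cores may contain IUPAC ambiguity codes (degenerate
#' primers); anything else is an error.
#'
#' @param fwd_core,rev_core locus-specific primer sequences (the reverse
#'   core oriented as the primer is synthesised, i.e. reverse-complement
#'   relative to the reference).
#' @return list with `fwd_tailed` and `rev_tailed`.
#' @export
append_tails <- function(fwd_core, rev_core) {
  for (core in c(fwd_core, rev_core)) {
    if (nchar(core) > 0) check_dna(core, what = "primer core")
  }
  tails <- tail_spec()
  list(fwd_tailed = paste0(tails$fwd, fwd_core),
       rev_tailed = paste0(tails$rev, rev_core))
}
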