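# The PIC (potentially informative character) statistic and its three
# views: quality-filtered substitution calls, non-overlapping window
# profiles, and per-locus counts with %PICs.

#' Analysis parameters for variability profiling
#'
#' @param min_snp_quality phred-like quality threshold; records must have
#'   quality strictly greater than this (set `qual_inclusive = TRUE` for
#'   `>=`). Default 30.
#' @param qual_inclusive logical; see above.
#' @param window_width width of the non-overlapping windows in bp.
#' @param min_locus_len loci shorter than this are dropped from per-locus
#'   tables. Very short regions otherwise inflate percentage variability.
#' @param percent_decimals decimals for reported percentages and summary
#'   means/medians.
#' @param missing_as_reference logical; if `TRUE`, missing genotypes count
#'   as the reference allele when assessing within-clade variability. The
#'   conservative default treats a missing genotype as non-informative for
#'   that taxon.
#' @return a list of class `"analysis_params"`.
#' @export
analysis_params <- function(min_snp_quality = 30, qual_inclusive = FALSE,
                            window_width = 1000L, min_locus_len = 100L,
                            percent_decimals = 2L,
                            missing_as_reference = FALSE) {
  stopifnot(min_snp_quality > 0, window_width > 0, min_locus_len > 0,
            percent_decimals >= 0)
  structure(list(min_snp_quality = min_snp_quality,
                 qual_inclusive = qual_inclusive,
                 window_width = as.integer(window_width),
                 min_locus_len = as.integer(min_locus_len),
                 percent_decimals = as.integer(percent_decimals),
                 missing_as_reference = missing_as_reference),
            class = "analysis_params")
}

#' Filter a SNP table for PIC calling
#'
#' Keeps substitution records whose quality exceeds the threshold; indels
#' (and any non-substitution record) are removed regardless of quality,
#' since the PIC definition covers nucleotide substitutions only.
#'
#' @param snps a `"snp_table"`.
#' @param params an `"analysis_params"`.
#' @return the filtered `"snp_table"`.
#' @export
filter_snps <- function(snps, params = analysis_params()) {
  q <- snps$quality
  pass_q <- if (params$qual_inclusive) q >= params$min_snp_quality
            else q > params$min_snp_quality
  pass_q[is.na(pass_q)] <- FALSE
  keep <- pass_q & snps$variant_type == "substitution"
  out <- snps[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "taxa") <- attr(snps, "taxa")
  class(out) <- class(snps)
  out
}

#' Call potentially informative characters for one clade
#'
#' A reference position is a PIC for a clade when the clade's members show
#' at least two distinct non-missing allele states there. The reference
#' taxon counts as a member of its own clade, contributing the reference
#' allele at every position. Each qualifying position is counted once.
#'
#' @param snps a filtered `"snp_table"` (see [filter_snps()]).
#' @param clades a `"clade_map"`.
#' @param clade `"ingroup"` or `"outgroup"`.
#' @param params an `"analysis_params"`; controls whether missing genotypes
#'   count as reference alleles.
#' @param structure optional `"quadripartite"`; when given, positions in
#'   the IRb copy are mirrored into IRa so the IR duplicate is not counted
#'   twice.
#' @return an object of class `"pic_set"`: list with `clade` and sorted
#'   unique `positions`.
#' @export
call_pics <- function(snps, clades, clade = c("ingroup", "outgroup"),
                      params = analysis_params(), structure = NULL) {
  clade <- match.arg(clade)
  members <- clade_taxa(clades, clade)
  ref_taxon <- attr(clades, "reference_taxon")
  table_taxa <- snp_taxa(snps)
  explicit <- intersect(members, table_taxa)
  has_ref <- ref_taxon %in% members
  n_eff <- length(explicit) + as.integer(has_ref && !(ref_taxon %in% explicit))
  if (n_eff < 2L) {
    stop("clade '", clade, "' has fewer than 2 effective members; ",
         "within-clade variability is undefined")
  }
  if (nrow(snps) == 0L) {
    return(structure(list(clade = clade, positions = integer(0)),
                     class = "pic_set"))
  }
  al <- as.matrix(snps[, explicit, drop = FALSE])
  if (params$missing_as_reference) {
    ref <- matrix(snps$ref_allele, nrow(al), ncol(al))
    al[is.na(al)] <- ref[is.na(al)]
  }
  n_states <- vapply(seq_len(nrow(al)), function(i) {
    states <- al[i, ]
    states <- states[!is.na(states)]
    if (has_ref && !(ref_taxon %in% explicit)) {
      states <- c(states, snps$ref_allele[i])
    }
    length(unique(states))
  }, 0L)
  pos <- snps$position[n_states >= 2L]
  if (!is.null(structure)) pos <- collapse_ir_duplicates(pos, structure)
  structure(list(clade = clade, positions = sort(unique(pos))),
            class = "pic_set")
}

#' @export
print.pic_set <- function(x, ...) {
  cat(sprintf("<pic_set> %s: %d positions\n", x$clade, length(x$positions)))
  invisible(x)
}

#' Summary statistics in report style
#'
#' Computes the footer statistics used in variability reports: min, max,
#' exact total, and mean/median rounded half-up to `decimals` places (the
#' median of an even count is the mean of the middle two values).
#'
#' @param values non-empty numeric vector.
#' @param decimals decimals for mean and median.
#' @return a list of class `"summary_stats"` with fields `min`, `max`,
#'   `total`, `mean`, `median`, `n`.
#' @export
summarize_stats <- function(values, decimals = 2L) {
  if (length(values) == 0L) stop("cannot summarise an empty vector")
  stopifnot(is.numeric(values))
  sorted <- sort(values)
  n <- length(sorted)
  med <- if (n %% 2L == 1L) sorted[(n + 1L) %/% 2L]
         else (sorted[n %/% 2L] + sorted[n %/% 2L + 1L]) / 2
  structure(list(min = min(values), max = max(values), total = sum(values),
                 mean = round_half_up(sum(values) / n, decimals),
                 median = round_half_up(med, decimals), n = n),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("min %s  max %s  total %s  mean %s  median %s  (n = %d)\n",
              format(x$min), format(x$max), format(x$total),
              format(x$mean), format(x$median), x$n))
  invisible(x)
}

#' Non-overlapping window profile of PIC density
#'
#' Window i covers positions `[w*(i-1)+1, w*i]` of the analysed sequence
#' (by design the one-IR-trimmed linearisation, so IR positions enter
#' once); the last window may be partial but is reported with its full
#' nominal end coordinate. Counts are per clade, with one summary per
#' clade.
#'
#' @param picsets named list of `"pic_set"` objects (typically
#'   `list(outgroup = ..., ingroup = ...)`), positions on the analysed
#'   sequence's coordinates.
#' @param analysed_length length in bp of the analysed sequence.
#' @param params an `"analysis_params"`.
#' @return an object of class `"window_profile"`: a data frame with columns
#'   `begin`, `end` and one `count_<clade>` column per PIC set, with a
#'   `summary` attribute (list of `"summary_stats"` per clade).
#' @export
window_profile <- function(picsets, analysed_length,
                           params = analysis_params()) {
  if (analysed_length < 1) stop("analysed_length must be positive")
  w <- params$window_width
  n_win <- as.integer(ceiling(analysed_length / w))
  begin <- w * (seq_len(n_win) - 1L) + 1L
  out <- data.frame(begin = begin, end = begin + w - 1L)
  summaries <- list()
  for (nm in names(picsets)) {
    pos <- picsets[[nm]]$positions
    pos <- pos[pos >= 1 & pos <= analysed_length]
    idx <- (pos - 1L) %/% w + 1L
    cnt <- tabulate(idx, nbins = n_win)
    out[[paste0("count_", nm)]] <- cnt
    summaries[[nm]] <- summarize_stats(cnt, params$percent_decimals)
  }
  attr(out, "summary") <- summaries
  attr(out, "analysed_length") <- analysed_length
  class(out) <- c("window_profile", "data.frame")
  out
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf("<window_profile> %d windows over %s bp\n", nrow(x),
              format(attr(x, "analysed_length"), big.mark = ",")))
  print.data.frame(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  for (nm in names(attr(x, "summary"))) {
    cat(nm, ": "); print(attr(x, "summary")[[nm]])
  }
  invisible(x)
}

#' Percent PICs per locus
#'
#' `100 * count / length`, rounded half-up.
#'
#' @param count number of PICs in the locus.
#' @param length locus length in bp; must be positive.
#' @param decimals decimals to round to.
#' @return the percentage as a numeric scalar (vectorised over inputs).
#' @export
percent_pics <- function(count, length, decimals = 2L) {
  if (any(length <= 0)) stop("locus length must be positive")
  if (any(count < 0)) stop("PIC count must be non-negative")
  round_half_up(100 * count / length, decimals)
}

## locus regions of one class, as a data.frame(region, start, end)
locus_regions <- function(annotation, region_class) {
  feats <- annotation$features
  if (region_class == "coding_exon") {
    f <- feats[feats$feature_class %in% c("coding_exon", "tRNA", "rRNA"), ,
               drop = FALSE]
    if (nrow(f) == 0) return(NULL)
    multi <- names(which(tapply(f$name, f$name, length) > 1))
    region <- ifelse(f$name %in% multi,
                     paste0(f$name, " Exon", f$exon_index), f$name)
    data.frame(region = region, start = f$start, end = f$end,
               stringsAsFactors = FALSE)
  } else if (region_class == "intron") {
    f <- feats[feats$feature_class == "intron", , drop = FALSE]
    if (nrow(f) == 0) return(NULL)
    # genes nested inside an intron (matK inside the trnK-UUU intron) split
    # it into separately reported segments
    nested <- feats[feats$feature_class %in% c("coding_exon", "tRNA", "rRNA"), ,
                    drop = FALSE]
    segs <- list()
    for (i in seq_len(nrow(f))) {
      s <- f$start[i]; e <- f$end[i]
      inside <- nested[nested$start > s & nested$end < e &
                         nested$name != f$name[i], , drop = FALSE]
      if (nrow(inside) == 0) {
        segs[[length(segs) + 1L]] <- data.frame(
          name = f$name[i], idx = f$exon_index[i], start = s, end = e,
          stringsAsFactors = FALSE)
      } else {
        cuts <- inside[order(inside$start), , drop = FALSE]
        bounds_s <- c(s, cuts$end + 1L)
        bounds_e <- c(cuts$start - 1L, e)
        keep <- bounds_s <= bounds_e
        part <- data.frame(name = f$name[i], idx = f$exon_index[i],
                           start = bounds_s[keep], end = bounds_e[keep],
                           stringsAsFactors = FALSE)
        part$seg <- seq_len(nrow(part))
        segs[[length(segs) + 1L]] <- part
      }
    }
    segdf <- do.call(rbind, lapply(segs, function(p) {
      if (is.null(p$seg)) p$seg <- NA_integer_
      p
    }))
    n_introns <- tapply(f$name, f$name, length)
    region <- ifelse(!is.na(segdf$seg),
                     paste0(segdf$name, "-", segdf$seg),
                     ifelse(n_introns[segdf$name] > 1,
                            paste0(segdf$name, "-", segdf$idx), segdf$name))
    data.frame(region = region, start = segdf$start, end = segdf$end,
               stringsAsFactors = FALSE)
  } else if (region_class == "igs_or_pseudogene") {
    f <- feats[feats$feature_class %in% c("intergenic_spacer", "pseudogene"), ,
               drop = FALSE]
    if (nrow(f) == 0) return(NULL)
    region <- ifelse(f$feature_class == "intergenic_spacer",
                     gsub("_", "-", f$name, fixed = TRUE), f$name)
    data.frame(region = region, start = f$start, end = f$end,
               wraps = f$wraps_origin, stringsAsFactors = FALSE)
  } else {
    stop("unknown region class: ", region_class)
  }
}

#' Per-locus variability table
#'
#' One row per region of the requested class: exons of coding, tRNA and
#' rRNA genes (multi-exon genes get one row per exon, named
#' `"<gene> ExonN"`); introns (multi-intron genes numbered `"<gene>-N"`,
#' and intron segments flanking a nested gene reported separately); or
#' intergenic spacers pooled with pseudogenes. Regions shorter than
#' `min_locus_len` are dropped, as are regions with no PIC in either clade
#' ("conserved among all analysed taxa") when `conserved_filter` is set.
#' Wrap-around spacers stored as two records are reported once with their
#' combined length.
#'
#' @param picsets named list of `"pic_set"` objects; the names become
#'   count/percentage column suffixes.
#' @param annotation an `"annotation_set"` with derived introns and spacers.
#' @param region_class `"coding_exon"`, `"intron"` or `"igs_or_pseudogene"`.
#' @param params an `"analysis_params"`.
#' @param conserved_filter drop fully conserved regions (default `TRUE`).
#' @return a data frame of class `"locus_variability"` with columns
#'   `region`, `length`, then `pics_<clade>` and `pct_<clade>` per PIC set.
#' @export
locus_table <- function(picsets, annotation,
                        region_class = c("coding_exon", "intron",
                                         "igs_or_pseudogene"),
                        params = analysis_params(), conserved_filter = TRUE) {
  region_class <- match.arg(region_class)
  regs <- locus_regions(annotation, region_class)
  empty <- data.frame(region = character(), length = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(regs) || nrow(regs) == 0) {
    for (nm in names(picsets)) {
      empty[[paste0("pics_", nm)]] <- integer(0)
      empty[[paste0("pct_", nm)]] <- numeric(0)
    }
    class(empty) <- c("locus_variability", "data.frame")
    return(empty)
  }
  regs$length <- regs$end - regs$start + 1L
  # wrap-around spacers: two records share a name; merge into one row
  if (!is.null(regs$wraps) && any(regs$wraps)) {
    wr <- regs[regs$wraps, , drop = FALSE]
    for (nm in unique(wr$region)) {
      idx <- which(regs$region == nm & regs$wraps)
      if (length(idx) == 2) {
        regs$length[idx[1]] <- sum(regs$length[idx])
        regs$start2 <- regs$start2 %||% NA_integer_
        regs$end2 <- regs$end2 %||% NA_integer_
        regs$start2[idx[1]] <- regs$start[idx[2]]
        regs$end2[idx[1]] <- regs$end[idx[2]]
        regs <- regs[-idx[2], , drop = FALSE]
      }
    }
  }
  counts <- lapply(picsets, function(ps) {
    pos <- ps$positions
    vapply(seq_len(nrow(regs)), function(i) {
      n <- sum(pos >= regs$start[i] & pos <= regs$end[i])
      if (!is.null(regs$start2) && !is.na(regs$start2[i])) {
        n <- n + sum(pos >= regs$start2[i] & pos <= regs$end2[i])
      }
      n
    }, 0L)
  })
  out <- data.frame(region = regs$region, length = regs$length,
                    stringsAsFactors = FALSE)
  for (nm in names(picsets)) {
    out[[paste0("pics_", nm)]] <- counts[[nm]]
    out[[paste0("pct_", nm)]] <- percent_pics(counts[[nm]], regs$length,
                                              params$percent_decimals)
  }
  keep <- out$length >= params$min_locus_len
  if (conserved_filter) {
    total <- Reduce(`+`, counts)
    keep <- keep & total > 0
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("locus_variability", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
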