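# Shared low-level helpers: rounding, base-level sequence ops, validation.

IUPAC_CODES <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "U")

#' Round half away from zero
#'
#' Commercial ("round half up") rounding at a fixed number of decimals, the
#' convention used throughout the package for reported means, medians and
#' percentages. Base R's `round()` rounds half to even, which disagrees with
#' printed two-decimal tables on exact .xx5 boundaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.915, 2)   # 0.92
#' round(0.915, 2)           # 0.92 or 0.91 depending on representation
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # tiny epsilon shields values that sit just under a .5 boundary after
  # binary representation of count/length ratios
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## complement lookup covering ambiguity codes
.comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
               R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
               B = "V", D = "H", H = "D", V = "B", U = "A")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around character vectors; accepts IUPAC ambiguity codes.
#'
#' @param seq single character string of IUPAC DNA.
#' @return reverse complement as a character string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(.comp_map))
  if (length(bad) > 0) {
    stop("non-IUPAC character(s) in sequence: ", paste(bad, collapse = ", "))
  }
  paste(rev(unname(.comp_map[chars])), collapse = "")
}

## complement of a character vector of bases (no reversal)
comp_chars <- function(chars) unname(.comp_map[chars])

## validate a DNA string, returning position of first offending character
check_dna <- function(seq, allowed = IUPAC_CODES, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% allowed)
  if (length(bad) > 0) {
    stop(sprintf("invalid character '%s' at position %d in %s",
                 chars[bad[1]], bad[1], what))
  }
  invisible(TRUE)
}

## substring by 1-based inclusive coordinates
subseq_chr <- function(seq, start, end) substr(seq, start, end)

## fraction of G/C in a sequence (strict ACGT; ambiguity codes excluded
## from numerator and denominator)
gc_fraction <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  acgt <- chars[chars %in% c("A", "C", "G", "T")]
  if (length(acgt) == 0) return(NA_real_)
  sum(acgt %in% c("G", "C")) / length(acgt)
}

## longest homopolymer run length
max_homopolymer <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(chars) == 0) return(0L)
  r <- rle(chars)
  max(r$lengths)
}

## internal: format an interval for messages
fmt_iv <- function(iv) sprintf("%d-%d", iv[1], iv[2])
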