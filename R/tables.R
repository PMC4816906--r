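# Packaged reference tables: machine-readable transcriptions of the
# published structure, variability and primer tables for three Hawaiian
# mint and three Stachys plastomes. They serve as fixtures for arithmetic
# self-consistency checks and as worked examples of the report layouts.

.mint_tables <- c(
  gene_introns = "mint_gene_introns.tsv",
  structure_lengths = "mint_structure_lengths.tsv",
  window_pics = "mint_window_pics.tsv",
  locus_pics_coding = "mint_locus_pics_coding.tsv",
  locus_pics_introns = "mint_locus_pics_introns.tsv",
  locus_pics_igs = "mint_locus_pics_igs.tsv",
  tailed_primers = "mint_tailed_primers.tsv")

#' Load a packaged mint reference table
#'
#' Available tables: `gene_introns` (exon/intron lengths of the
#' intron-containing plastome genes), `structure_lengths` (LSC/IR/SSC/total
#' lengths for 12 mint plastomes), `window_pics` (PIC counts per 1000-bp
#' window for the *Stachys* outgroup and Hawaiian ingroup),
#' `locus_pics_coding` / `locus_pics_introns` / `locus_pics_igs` (per-locus
#' PIC counts and percentages by region class), and `tailed_primers` (108
#' adapter-tailed primer pairs with Tm and covered loci).
#'
#' @param name one of the table names above.
#' @return a data frame.
#' @export
mint_reference_table <- function(name = names(.mint_tables)) {
  name <- match.arg(name)
  path <- system.file("extdata", .mint_tables[[name]], package = "plastovar",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Check the arithmetic self-consistency of the reference tables
#'
#' Recomputes every derived cell from its primitive cells: structure totals
#' from `LSC + 2*IR + SSC`, every %PICs cell from its printed count and
#' length (round-half-up, two decimals), window-count summary footers, and
#' the tail prefixes of all tailed primers. One row of the structure table
#' (*Stenogyne haliakalae*) is internally inconsistent by 1 bp in the
#' published values; it is reported, not repaired.
#'
#' @return data frame with one row per check: `table`, `check`, `n_rows`,
#'   `n_mismatch`, `detail`.
#' @export
validate_reference_tables <- function() {
  out <- list()
  rec <- function(table, check, n_rows, mismatch_idx, detail = "") {
    out[[length(out) + 1L]] <<- data.frame(
      table = table, check = check, n_rows = n_rows,
      n_mismatch = length(mismatch_idx), detail = detail,
      stringsAsFactors = FALSE)
  }

  st <- mint_reference_table("structure_lengths")
  recomputed <- st$lsc + 2L * st$ir + st$ssc
  bad <- which(recomputed != st$total)
  rec("structure_lengths", "total == LSC + 2*IR + SSC", nrow(st), bad,
      if (length(bad)) paste(st$species[bad], collapse = "; ") else "")

  for (nm in c("locus_pics_coding", "locus_pics_introns", "locus_pics_igs")) {
    tb <- mint_reference_table(nm)
    for (cl in c("outgroup", "ingroup")) {
      expect <- percent_pics(tb[[paste0("pics_", cl)]], tb$length)
      bad <- which(abs(expect - tb[[paste0("pct_", cl)]]) > 1e-9)
      rec(nm, paste0("pct_", cl, " recomputes from count/length"), nrow(tb),
          bad, if (length(bad)) paste(tb$region[bad], collapse = "; ") else "")
    }
  }

  win <- mint_reference_table("window_pics")
  for (cl in c("outgroup", "ingroup")) {
    s <- summarize_stats(win[[paste0("pics_", cl)]])
    ok <- s$n == 125L
    rec("window_pics", paste0(cl, " has 125 windows"), s$n,
        if (ok) integer(0) else 1L)
  }

  pr <- mint_reference_table("tailed_primers")
  tails <- tail_spec()
  is_f <- grepl("F$", pr$primer)
  bad <- which((is_f & !startsWith(pr$sequence, tails$fwd)) |
                 (!is_f & !startsWith(pr$sequence, tails$rev)))
  rec("tailed_primers", "every primer starts with its adapter tail",
      nrow(pr), bad,
      if (length(bad)) paste(pr$primer[bad], collapse = "; ") else "")

  gi <- mint_reference_table("gene_introns")
  # spans of multi-exon genes are not in the table; check the count columns
  n_parts <- rowSums(!is.na(gi[, c("intron1", "intron2")]))
  bad <- which(n_parts != gi$n_introns &
                 gi$gene != "rps12")  # trans-spliced: one intron has no length
  rec("gene_introns", "intron count matches intron length cells", nrow(gi),
      bad, if (length(bad)) paste(gi$gene[bad], collapse = "; ") else "")

  do.call(rbind, out)
}
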