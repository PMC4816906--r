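# End-to-end pipeline: structure -> filter -> PICs -> windows -> loci ->
# targets -> primers, with TSV/BED report writers mirroring the standard
# variability-table layouts.

#' Pipeline run configuration
#'
#' @param fasta,gff,vcf,clades input paths (reference FASTA, GFF3
#'   annotation, multi-sample VCF, clade-map TSV).
#' @param reference_taxon name of the reference taxon.
#' @param out_dir output directory.
#' @param params an `"analysis_params"`.
#' @param min_ir_len,max_ir_mismatch_frac structure-detection parameters.
#' @param flank target flank width in bp.
#' @param constraints a `"primer_constraints"`.
#' @param primer_prefix prefix for primer pair names.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(fasta, gff, vcf, clades, reference_taxon,
                       out_dir = "plastovar_out",
                       params = analysis_params(),
                       min_ir_len = 1000L, max_ir_mismatch_frac = 0.01,
                       flank = 100L,
                       constraints = primer_constraints(),
                       primer_prefix = "Mint") {
  structure(as.list(environment()), class = "run_config")
}

.stage <- function(name, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  res
}

.write_tsv <- function(df, path, version_comment = TRUE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (version_comment) {
    writeLines(sprintf("# plastovar %s",
                       as.character(utils::packageVersion("plastovar"))), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full variability and target-design pipeline
#'
#' Executes, in order: quadripartite structure detection and one-IR
#' trimming; SNP quality filtering; clade-wise PIC calling (IR duplicates
#' collapsed); window profiling over the trimmed extent; per-locus tables
#' for coding exons, introns, and intergenic spacers/pseudogenes; target
#' selection and merging; primer picking with adapter tailing. Writes
#' `structure.tsv`, `windows.tsv`, `loci_coding.tsv`, `loci_introns.tsv`,
#' `loci_igs.tsv`, `targets.bed`, `pics_<clade>.bed` and `primers.tsv`
#' into the output directory and logs record counts per stage.
#'
#' @param config a `"run_config"`.
#' @param quiet suppress per-stage messages.
#' @return (invisibly) a list with all intermediate objects and the table
#'   of written files.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  log_ <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- .stage("read_fasta", read_plastome_fasta(config$fasta))
  annotation <- .stage("read_annotation",
                       read_annotation(config$gff, genome))
  annotation <- .stage("derive_features",
                       derive_intergenic_spacers(derive_introns(annotation)))
  clades <- .stage("read_clades",
                   read_clade_map(config$clades, config$reference_taxon))
  snps <- .stage("read_snps", read_snps(config$vcf, clades))
  log_("inputs: %d bp genome, %d features, %d SNP records, %d taxa",
       genome$length, nrow(annotation$features), nrow(snps),
       nrow(clades))

  hit <- .stage("find_inverted_repeat",
                find_inverted_repeat(genome, min_len = config$min_ir_len,
                                     max_mismatch_frac = config$max_ir_mismatch_frac))
  if (!hit$found) stop("pipeline stage 'find_inverted_repeat' failed: no ",
                       "inverted repeat of >= ", config$min_ir_len, " bp")
  st <- .stage("partition_quadripartite",
               partition_quadripartite(genome, hit))
  trim <- .stage("trim_one_ir", trim_one_ir(genome, st))
  log_("structure: LSC %d, IR %d, SSC %d, total %d (trimmed %d)",
       st$lsc_len, st$ir_len, st$ssc_len, st$total_len, trim$genome$length)
  .write_tsv(structure_report(st, genome$id),
             file.path(config$out_dir, "structure.tsv"))
  write_bed(c(st$lsc[1], st$ira[1], st$ssc[1], st$irb[1]),
            c(st$lsc[2], st$ira[2], st$ssc[2], st$irb[2]),
            c("LSC", "IRa", "SSC", "IRb"), genome$id,
            file.path(config$out_dir, "structure.bed"))

  filtered <- .stage("filter_snps", filter_snps(snps, config$params))
  log_("filter: %d of %d records pass (substitutions, quality %s %s)",
       nrow(filtered), nrow(snps),
       if (config$params$qual_inclusive) ">=" else ">",
       config$params$min_snp_quality)

  picsets <- .stage("call_pics", list(
    outgroup = call_pics(filtered, clades, "outgroup", config$params,
                         structure = st),
    ingroup = call_pics(filtered, clades, "ingroup", config$params,
                        structure = st)))
  log_("PICs: %d outgroup, %d ingroup",
       length(picsets$outgroup$positions), length(picsets$ingroup$positions))
  for (nm in names(picsets)) {
    pos <- picsets[[nm]]$positions
    if (length(pos)) {
      write_bed(pos, pos, paste0("PIC_", nm), genome$id,
                file.path(config$out_dir, paste0("pics_", nm, ".bed")))
    }
  }

  windows <- .stage("window_profile",
                    window_profile(picsets, trim$genome$length, config$params))
  .write_tsv(as.data.frame(windows), file.path(config$out_dir, "windows.tsv"))
  log_("windows: %d of width %d", nrow(windows), config$params$window_width)

  loci <- list()
  for (spec in list(c("coding_exon", "loci_coding.tsv"),
                    c("intron", "loci_introns.tsv"),
                    c("igs_or_pseudogene", "loci_igs.tsv"))) {
    tb <- .stage(paste0("locus_table_", spec[1]),
                 locus_table(picsets, annotation, spec[1], config$params))
    loci[[spec[1]]] <- tb
    .write_tsv(as.data.frame(tb), file.path(config$out_dir, spec[2]))
    log_("loci (%s): %d regions", spec[1], nrow(tb))
  }

  anchors <- .stage("select_targets", select_targets(filtered, clades, st))
  targets <- .stage("build_targets",
                    build_targets(anchors, st, flank = config$flank))
  log_("targets: %d anchors -> %d merged regions (%d bp)",
       nrow(anchors), nrow(targets),
       if (nrow(targets)) sum(targets$end - targets$start + 1L) else 0L)
  if (nrow(targets)) {
    write_bed(targets$start, targets$end,
              paste0("target_", seq_len(nrow(targets))), genome$id,
              file.path(config$out_dir, "targets.bed"))
  }

  primers <- .stage("pick_primers", lapply(seq_len(nrow(targets)), function(i) {
    pick_primers(targets[i, ], genome, config$constraints,
                 prefix = config$primer_prefix)
  }))
  found <- Filter(function(p) p$found, primers)
  log_("primers: %d pairs designed, %d regions without admissible pair",
       length(found), length(primers) - length(found))
  primer_df <- do.call(rbind, lapply(found, function(p) {
    data.frame(primer = c(paste0(p$name, "F"), paste0(p$name, "R")),
               sequence = c(p$fwd_tailed, p$rev_tailed),
               tm = round_half_up(c(p$tm_fwd, p$tm_rev), 1),
               product_start = p$product_span[1],
               product_end = p$product_span[2],
               stringsAsFactors = FALSE)
  }))
  if (is.null(primer_df)) {
    primer_df <- data.frame(primer = character(), sequence = character(),
                            tm = numeric(), product_start = integer(),
                            product_end = integer(), stringsAsFactors = FALSE)
  }
  .write_tsv(primer_df, file.path(config$out_dir, "primers.tsv"))

  invisible(list(genome = genome, annotation = annotation, clades = clades,
                 snps = snps, filtered = filtered, structure = st,
                 trimmed = trim, picsets = picsets, windows = windows,
                 loci = loci, anchors = anchors, targets = targets,
                 primers = primers, primer_table = primer_df,
                 out_dir = config$out_dir))
}
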