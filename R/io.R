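# Readers/writers for the standard formats the pipeline touches, and the
# in-memory annotation model: typed features (exon/intron/IGS/pseudogene) on
# a circular 1-based coordinate system.

#' Construct a plastome sequence object
#'
#' @param id sequence identifier.
#' @param residues IUPAC DNA string (will be uppercased).
#' @param circular logical; plastomes are circular molecules, but linearised
#'   views (e.g. after IR trimming) are not.
#' @return an object of class `"plastome"`: a list with fields `id`,
#'   `residues`, `circular` and `length`.
#' @export
plastome_sequence <- function(id, residues, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  check_dna(residues, what = paste0("sequence '", id, "'"))
  structure(list(id = id, residues = residues, circular = circular,
                 length = nchar(residues)),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %s bp (%s)\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a single-record FASTA file as a plastome
#'
#' @param path path to a FASTA file containing exactly one sequence.
#' @param circular logical, passed to [plastome_sequence()].
#' @return a `"plastome"` object with uppercased residues.
#' @export
read_plastome_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  if (length(set) > 1L) stop("expected exactly one sequence, found ", length(set))
  id <- sub("\\s.*$", "", names(set)[1])
  plastome_sequence(id, as.character(set[[1]]), circular = circular)
}

#' Write a plastome to FASTA
#'
#' @param genome a `"plastome"` object.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_plastome_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(genome$residues)
  names(set) <- genome$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

## ---------------------------------------------------------------------------
## clade map

#' Construct a clade map
#'
#' Assigns each taxon to the `ingroup` or `outgroup` clade and records which
#' taxon is the mapping reference (the genome the SNPs are called against).
#' The reference taxon counts as a member of its own clade and implicitly
#' carries the reference allele at every position.
#'
#' @param taxon character vector of taxon names.
#' @param clade character vector, each `"ingroup"` or `"outgroup"`.
#' @param reference_taxon name of the reference taxon; must appear exactly
#'   once in `taxon`.
#' @return a data frame of class `"clade_map"` with attributes
#'   `reference_taxon` and `reference_clade`.
#' @export
clade_map <- function(taxon, clade, reference_taxon) {
  stopifnot(length(taxon) == length(clade))
  if (anyDuplicated(taxon)) stop("duplicated taxon names in clade map")
  bad <- setdiff(unique(clade), c("ingroup", "outgroup"))
  if (length(bad)) stop("unknown clade label(s): ", paste(bad, collapse = ", "))
  if (sum(taxon == reference_taxon) != 1L) {
    stop("reference taxon '", reference_taxon,
         "' must appear exactly once in the clade map")
  }
  for (cl in c("ingroup", "outgroup")) {
    if (!any(clade == cl)) stop("clade '", cl, "' has no members")
  }
  out <- data.frame(taxon = taxon, clade = clade, stringsAsFactors = FALSE)
  attr(out, "reference_taxon") <- reference_taxon
  attr(out, "reference_clade") <- clade[taxon == reference_taxon]
  class(out) <- c("clade_map", "data.frame")
  out
}

#' Read a clade map from TSV
#'
#' Expects a two-column tab-separated file with header `taxon<TAB>clade`.
#'
#' @param path path to the TSV file.
#' @param reference_taxon name of the reference taxon.
#' @return a `"clade_map"` object.
#' @export
read_clade_map <- function(path, reference_taxon) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "clade") %in% names(df))) {
    stop("clade map must have columns 'taxon' and 'clade'")
  }
  clade_map(df$taxon, df$clade, reference_taxon)
}

#' Taxa belonging to one clade
#'
#' @param clades a `"clade_map"`.
#' @param clade `"ingroup"` or `"outgroup"`.
#' @return character vector of taxon names (including the reference taxon if
#'   it belongs to the clade).
#' @export
clade_taxa <- function(clades, clade) clades$taxon[clades$clade == clade]

## ---------------------------------------------------------------------------
## annotation model

.feature_classes <- c("coding_exon", "intron", "tRNA", "rRNA",
                      "intergenic_spacer", "pseudogene")

empty_features <- function() {
  data.frame(name = character(), feature_class = character(),
             start = integer(), end = integer(), strand = character(),
             parent_gene = character(), in_inverted_repeat = logical(),
             exon_index = integer(), wraps_origin = logical(),
             stringsAsFactors = FALSE)
}

#' Construct an annotation set
#'
#' Bundles a plastome with a table of typed features. Features are kept
#' sorted by `(start, end)`. Wrap-around features on the circular genome are
#' stored split into two records sharing a name, both flagged
#' `wraps_origin = TRUE`.
#'
#' @param genome a `"plastome"`.
#' @param features data frame with columns `name`, `feature_class`, `start`,
#'   `end`, `strand`, `parent_gene`, `in_inverted_repeat`, `exon_index`,
#'   `wraps_origin`. Missing optional columns are filled.
#' @param genes optional gene-level table (columns `gene`, `start`, `end`,
#'   `strand`, `gene_class`) used for spacer derivation.
#' @return an object of class `"annotation_set"`.
#' @export
annotation_set <- function(genome, features, genes = NULL) {
  stopifnot(inherits(genome, "plastome"))
  defaults <- list(parent_gene = NA_character_, in_inverted_repeat = FALSE,
                   exon_index = NA_integer_, wraps_origin = FALSE,
                   strand = "+")
  for (col in names(defaults)) {
    if (is.null(features[[col]])) {
      features[[col]] <- rep(defaults[[col]], nrow(features))
    }
  }
  bad <- setdiff(unique(features$feature_class), .feature_classes)
  if (length(bad)) stop("unknown feature class(es): ", paste(bad, collapse = ", "))
  if (nrow(features) > 0) {
    if (any(features$start < 1 | features$end > genome$length)) {
      stop("feature coordinates outside genome (1-", genome$length, ")")
    }
    if (any(features$end < features$start)) {
      i <- which(features$end < features$start)[1]
      stop("feature '", features$name[i], "' has end < start")
    }
    has_idx <- features$feature_class %in% c("coding_exon", "intron")
    if (any(has_idx & is.na(features$exon_index))) {
      stop("coding_exon/intron features require exon_index")
    }
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(genome = genome, features = features, genes = genes),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s (%s bp): %d features\n", x$genome$id,
              format(x$genome$length, big.mark = ","), nrow(x$features)))
  if (nrow(x$features) > 0) print(table(x$features$feature_class))
  invisible(x)
}

#' Read a GFF3 annotation
#'
#' Reads `gene`, `exon` and `pseudogene` records. Features are identified by
#' `ID`/`Parent` attributes; gene names come from `Name`, falling back to
#' `ID`. A `gene_class` attribute on gene records (`coding`, `tRNA`, `rRNA`;
#' default `coding`) determines the class of the gene's exons. Exon indices
#' are assigned in genomic order within each gene record, so trans-spliced
#' genes represented as two gene records get independent exon numbering.
#'
#' @param path path to a GFF3 file.
#' @param genome the `"plastome"` the coordinates refer to.
#' @return an `"annotation_set"` containing exon-level and pseudogene
#'   features plus a gene-level table used for spacer derivation.
#' @export
read_annotation <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$type <- as.character(df$type)
  df$strand <- ifelse(as.character(df$strand) == "-", "-", "+")
  if (any(df$end > genome$length | df$start < 1)) {
    stop("GFF3 coordinates outside genome (1-", genome$length, ")")
  }
  get_attr <- function(d, what) {
    if (is.null(d[[what]])) rep(NA_character_, nrow(d)) else {
      v <- d[[what]]
      if (is.list(v)) v <- vapply(v, function(x) if (length(x)) x[[1]] else NA_character_, "")
      as.character(v)
    }
  }
  genes_df <- df[df$type == "gene", , drop = FALSE]
  ps_df <- df[df$type == "pseudogene", , drop = FALSE]
  ex_df <- df[df$type == "exon", , drop = FALSE]
  gid <- get_attr(genes_df, "ID")
  gname <- get_attr(genes_df, "Name")
  gname[is.na(gname)] <- gid[is.na(gname)]
  gclass <- get_attr(genes_df, "gene_class")
  gclass[is.na(gclass)] <- "coding"
  genes <- data.frame(id = gid, gene = gname, start = genes_df$start,
                      end = genes_df$end, strand = genes_df$strand,
                      gene_class = gclass, stringsAsFactors = FALSE)

  feats <- empty_features()
  if (nrow(ex_df) > 0) {
    parent <- get_attr(ex_df, "Parent")
    if (anyNA(parent)) stop("exon record without Parent attribute")
    unknown <- setdiff(unique(parent), genes$id)
    if (length(unknown)) stop("exon Parent(s) without gene record: ",
                              paste(unknown, collapse = ", "))
    rows <- lapply(genes$id, function(g) {
      ex <- ex_df[parent == g, , drop = FALSE]
      if (nrow(ex) == 0) return(NULL)
      grow <- genes[genes$id == g, ]
      if (any(ex$start < grow$start | ex$end > grow$end)) {
        stop("exon outside span of gene '", grow$gene, "'")
      }
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
        stop("overlapping exons in gene '", grow$gene, "'")
      }
      fclass <- switch(grow$gene_class, tRNA = "tRNA", rRNA = "rRNA",
                       "coding_exon")
      data.frame(name = grow$gene, feature_class = fclass,
                 start = ex$start, end = ex$end, strand = grow$strand,
                 parent_gene = g, in_inverted_repeat = FALSE,
                 exon_index = seq_len(nrow(ex)), wraps_origin = FALSE,
                 stringsAsFactors = FALSE)
    })
    feats <- do.call(rbind, c(list(feats), rows))
  }
  if (nrow(ps_df) > 0) {
    pname <- get_attr(ps_df, "Name")
    pid <- get_attr(ps_df, "ID")
    pname[is.na(pname)] <- pid[is.na(pname)]
    feats <- rbind(feats, data.frame(
      name = pname, feature_class = "pseudogene",
      start = ps_df$start, end = ps_df$end, strand = ps_df$strand,
      parent_gene = NA_character_, in_inverted_repeat = FALSE,
      exon_index = NA_integer_, wraps_origin = FALSE,
      stringsAsFactors = FALSE))
  }
  annotation_set(genome, feats, genes = genes)
}

#' Write an annotation set to GFF3
#'
#' Emits gene records (with `Name` and `gene_class` attributes), their exons
#' (`Parent`), and pseudogenes. Derived introns and spacers are not written;
#' they are recomputed on read.
#'
#' @param annotation an `"annotation_set"` with a gene-level table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  genome <- annotation$genome
  genes <- annotation$genes
  if (is.null(genes)) stop("annotation has no gene-level table to write")
  feats <- annotation$features
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", genome$id, genome$length))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, sprintf(
      "%s\tplastovar\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;gene_class=%s",
      genome$id, g$start, g$end, g$strand, g$id, g$gene, g$gene_class))
    ex <- feats[!is.na(feats$parent_gene) & feats$parent_gene == g$id &
                  feats$feature_class %in% c("coding_exon", "tRNA", "rRNA"), ]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf(
        "%s\tplastovar\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        genome$id, ex$start[j], ex$end[j], g$strand, g$id, j, g$id))
    }
  }
  ps <- feats[feats$feature_class == "pseudogene", ]
  for (j in seq_len(nrow(ps))) {
    lines <- c(lines, sprintf(
      "%s\tplastovar\tpseudogene\t%d\t%d\t.\t%s\t.\tID=ps%d;Name=%s",
      genome$id, ps$start[j], ps$end[j], ps$strand[j], j, ps$name[j]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Derive introns from exon records
#'
#' For each gene record with k exons, inserts k-1 intron records filling the
#' inter-exon gaps exactly. Adjacent exons with zero gap produce no intron.
#' Because exon indices are scoped to a gene record, trans-spliced genes
#' stored as two records yield introns only between co-located exons.
#'
#' @param annotation an `"annotation_set"` whose exons carry `exon_index`.
#' @return the annotation with intron features added.
#' @export
derive_introns <- function(annotation) {
  feats <- annotation$features
  feats <- feats[feats$feature_class != "intron", , drop = FALSE]
  ex <- feats[feats$feature_class %in% c("coding_exon", "tRNA", "rRNA") &
                !is.na(feats$parent_gene), , drop = FALSE]
  introns <- list()
  for (g in unique(ex$parent_gene)) {
    e <- ex[ex$parent_gene == g, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (is.unsorted(e$exon_index, strictly = TRUE)) {
      stop("exon indices of gene record '", g, "' not ordered by position")
    }
    if (nrow(e) < 2) next
    for (i in seq_len(nrow(e) - 1)) {
      s <- e$end[i] + 1L
      t <- e$start[i + 1L] - 1L
      if (s > t) next  # abutting exons: no intron
      introns[[length(introns) + 1L]] <- data.frame(
        name = e$name[1], feature_class = "intron", start = s, end = t,
        strand = e$strand[1], parent_gene = g,
        in_inverted_repeat = e$in_inverted_repeat[1],
        exon_index = i, wraps_origin = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(introns)) feats <- rbind(feats, do.call(rbind, introns))
  annotation_set(annotation$genome, feats, genes = annotation$genes)
}

#' Derive intergenic spacers
#'
#' Emits one `intergenic_spacer` feature per gap between consecutive gene or
#' pseudogene spans on the circular genome, named `"<left>_<right>"` after
#' its flanking loci. The gap spanning the origin is emitted wrap-aware: two
#' records sharing a name, both flagged `wraps_origin`. Zero-length gaps
#' produce no spacer.
#'
#' @param annotation an `"annotation_set"` with a gene-level table (from
#'   [read_annotation()] or the synthetic generator); pseudogene features
#'   also delimit spacers.
#' @return the annotation with spacer features added.
#' @export
derive_intergenic_spacers <- function(annotation) {
  genome <- annotation$genome
  feats <- annotation$features
  feats <- feats[feats$feature_class != "intergenic_spacer", , drop = FALSE]
  genes <- annotation$genes
  spans <- data.frame(name = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (!is.null(genes) && nrow(genes) > 0) {
    spans <- rbind(spans, data.frame(name = genes$gene, start = genes$start,
                                     end = genes$end, stringsAsFactors = FALSE))
  }
  ps <- feats[feats$feature_class == "pseudogene", , drop = FALSE]
  if (nrow(ps) > 0) {
    spans <- rbind(spans, data.frame(name = ps$name, start = ps$start,
                                     end = ps$end, stringsAsFactors = FALSE))
  }
  if (nrow(spans) < 1) return(annotation)
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  n <- nrow(spans)
  sp <- list()
  add <- function(left, right, s, t, wraps = FALSE) {
    data.frame(name = paste0(left, "_", right), feature_class = "intergenic_spacer",
               start = s, end = t, strand = "+", parent_gene = NA_character_,
               in_inverted_repeat = FALSE, exon_index = NA_integer_,
               wraps_origin = wraps, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n - 1)) {
    s <- spans$end[i] + 1L
    t <- spans$start[i + 1L] - 1L
    if (s > t) next
    sp[[length(sp) + 1L]] <- add(spans$name[i], spans$name[i + 1L], s, t)
  }
  # gap between last span and first span, possibly across the origin
  if (genome$circular) {
    s <- spans$end[n] + 1L
    t <- spans$start[1L] - 1L
    if (s <= genome$length && t >= 1L) {
      # wraps the origin: split into two records sharing a name
      nm_l <- spans$name[n]; nm_r <- spans$name[1L]
      sp[[length(sp) + 1L]] <- add(nm_l, nm_r, s, genome$length, wraps = TRUE)
      sp[[length(sp) + 1L]] <- add(nm_l, nm_r, 1L, t, wraps = TRUE)
    } else if (s <= genome$length && t < 1L) {
      sp[[length(sp) + 1L]] <- add(spans$name[n], spans$name[1L], s, genome$length)
    } else if (s > genome$length && t >= 1L) {
      sp[[length(sp) + 1L]] <- add(spans$name[n], spans$name[1L], 1L, t)
    }
  }
  if (length(sp)) feats <- rbind(feats, do.call(rbind, sp))
  annotation_set(genome, feats, genes = annotation$genes)
}

## ---------------------------------------------------------------------------
## SNP tables

#' Construct a SNP table
#'
#' @param position integer vector of 1-based reference positions.
#' @param ref_allele reference allele strings.
#' @param quality phred-like variant quality scores.
#' @param variant_type `"substitution"` or `"indel"` per record.
#' @param alleles data frame (one column per taxon) of allele strings;
#'   `NA` denotes a missing genotype.
#' @return a data frame of class `"snp_table"` with attribute `taxa`.
#' @export
snp_table <- function(position, ref_allele, quality, variant_type, alleles) {
  stopifnot(is.data.frame(alleles))
  bad <- setdiff(unique(variant_type), c("substitution", "indel"))
  if (length(bad)) stop("unknown variant type(s): ", paste(bad, collapse = ", "))
  sub <- variant_type == "substitution"
  if (any(nchar(ref_allele[sub]) != 1L)) {
    stop("substitution records must have single-base reference alleles")
  }
  out <- cbind(data.frame(position = as.integer(position),
                          ref_allele = ref_allele,
                          quality = as.numeric(quality),
                          variant_type = variant_type,
                          stringsAsFactors = FALSE),
               alleles)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "taxa") <- names(alleles)
  class(out) <- c("snp_table", "data.frame")
  out
}

#' Taxa covered by a SNP table
#' @param snps a `"snp_table"`.
#' @return character vector of taxon names.
#' @export
snp_taxa <- function(snps) attr(snps, "taxa")

#' Read a multi-sample VCF into a SNP table
#'
#' One record per VCF row. Genotypes must be haploid or homozygous diploid
#' (plastomes are effectively haploid); heterozygous calls raise an error
#' with the offending row number. Missing genotypes are preserved as `NA`.
#' A row is classed `"indel"` when the REF and any ALT allele differ in
#' length.
#'
#' @param path path to a VCF 4.x file.
#' @param clades a `"clade_map"`; every VCF sample must appear in it.
#' @return a `"snp_table"`.
#' @export
read_snps <- function(path, clades) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) {
    samples <- setdiff(colnames(vcf@gt), "FORMAT")
    unknown <- setdiff(samples, clades$taxon)
    if (length(unknown)) {
      stop("VCF sample(s) not in clade map: ", paste(unknown, collapse = ", "))
    }
    alleles <- as.data.frame(setNames(rep(list(character(0)), length(samples)),
                                      samples), check.names = FALSE)
    return(snp_table(integer(0), character(0), numeric(0), character(0),
                     alleles))
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  unknown <- setdiff(samples, clades$taxon)
  if (length(unknown)) {
    stop("VCF sample(s) not in clade map: ", paste(unknown, collapse = ", "))
  }
  n <- nrow(fix)
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  alt_list <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  vtype <- vapply(seq_len(n), function(i) {
    alts <- alt_list[[i]]
    if (length(alts) && any(nchar(alts) != nchar(ref[i]))) "indel" else "substitution"
  }, "")
  # substitution rows with multi-base but equal-length alleles (MNPs) are
  # rare in bcftools output; treat length>1 equal-length REF as indel-like
  vtype[nchar(ref) != 1L & vtype == "substitution"] <- "indel"
  alleles <- as.data.frame(setNames(rep(list(rep(NA_character_, n)), length(samples)),
                                    samples), check.names = FALSE)
  for (s in samples) {
    g <- gt[, s]
    for (i in seq_len(n)) {
      gi <- g[i]
      if (is.na(gi) || gi %in% c(".", "./.", ".|.")) next
      parts <- strsplit(gi, "[/|]")[[1]]
      if (length(unique(parts)) != 1L) {
        stop("heterozygous genotype '", gi, "' for sample ", s, " at row ", i)
      }
      idx <- suppressWarnings(as.integer(parts[1]))
      if (is.na(idx)) stop("malformed genotype '", gi, "' at row ", i)
      alleles[i, s] <- if (idx == 0L) ref[i] else {
        alts <- alt_list[[i]]
        if (idx > length(alts)) stop("allele index out of range at row ", i)
        alts[idx]
      }
    }
  }
  snp_table(pos, ref, qual, vtype, alleles)
}

#' Write a SNP table as a multi-sample VCF
#'
#' @param snps a `"snp_table"`.
#' @param genome the reference `"plastome"` (for the header contig line).
#' @param path output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_snps_vcf <- function(snps, genome, path) {
  taxa <- snp_taxa(snps)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", genome$id, genome$length),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", taxa), collapse = "\t"))
  rows <- vapply(seq_len(nrow(snps)), function(i) {
    obs <- unlist(snps[i, taxa], use.names = FALSE)
    alts <- setdiff(unique(obs[!is.na(obs)]), snps$ref_allele[i])
    if (length(alts) == 0) alts <- character(0)
    gt <- vapply(obs, function(a) {
      if (is.na(a)) "." else if (a == snps$ref_allele[i]) "0"
      else as.character(match(a, alts))
    }, "")
    paste(c(genome$id, snps$position[i], ".", snps$ref_allele[i],
            if (length(alts)) paste(alts, collapse = ",") else ".",
            format(snps$quality[i]), "PASS", ".", "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Export features or positions to BED
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param name record names.
#' @param chrom chromosome/sequence id.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(start, end, name, chrom, path) {
  df <- data.frame(chrom = chrom, start = as.integer(start) - 1L,
                   end = as.integer(end), name = name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
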