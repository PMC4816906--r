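# Synthetic plastome generator: quadripartite reference, gene/intron
# annotation, two clades of diverged taxa, and a VCF with a full truth
# table, so that every pipeline stage can be validated without external
# data.

#' Configuration for the synthetic plastome generator
#'
#' Defaults emulate the quadripartite geometry of a mint plastome (LSC
#' 81,364 bp, IR 25,436 bp, SSC 17,499 bp) with two clades of three taxa,
#' the first ingroup taxon serving as the mapping reference. Substitution
#' rates are per site per taxon and class-specific, with intergenic
#' spacers evolving fastest and coding exons slowest; the outgroup clade
#' diverges five times faster than the ingroup, matching the contrast
#' between a recent island radiation and its continental relatives.
#'
#' @param seed integer seed; every generator output is a pure function of
#'   the configuration.
#' @param lsc_len,ir_len,ssc_len region lengths in bp.
#' @param n_genes named list: genes to place in `lsc`, `ssc` and `ir`
#'   (IR genes are mirrored into both copies).
#' @param n_pseudogenes pseudogenes placed in the SSC.
#' @param intron_frac fraction of single-copy genes receiving introns
#'   (one or two, split evenly).
#' @param gene_len_range,gap_range,exon_len_range,intron_len_range
#'   sampling ranges in bp for gene models and intergenic gaps.
#' @param rates list with `ingroup` and `outgroup`, each a named vector of
#'   per-site per-taxon substitution probabilities for classes `coding`,
#'   `intron`, `igs`.
#' @param indel_rate per-site deletion probability (deletions of 1-4 bp;
#'   indels never overlap substitutions).
#' @param quality_model `c(mean, sd)` of emitted variant QUAL scores.
#' @param qual_below30_frac fraction of variant rows assigned a QUAL below
#'   30 to exercise quality filtering.
#' @param n_ingroup,n_outgroup clade sizes.
#' @return a list of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L,
                         lsc_len = 81364L, ir_len = 25436L, ssc_len = 17499L,
                         n_genes = list(lsc = 42L, ssc = 8L, ir = 3L),
                         n_pseudogenes = 1L,
                         intron_frac = 0.25,
                         gene_len_range = c(300L, 1500L),
                         gap_range = c(100L, 400L),
                         exon_len_range = c(100L, 600L),
                         intron_len_range = c(400L, 900L),
                         rates = list(
                           ingroup = c(coding = 0.0002, intron = 0.0004,
                                       igs = 0.0006),
                           outgroup = c(coding = 0.001, intron = 0.002,
                                        igs = 0.003)),
                         indel_rate = 1e-4,
                         quality_model = c(mean = 80, sd = 20),
                         qual_below30_frac = 0.05,
                         n_ingroup = 3L, n_outgroup = 3L) {
  stopifnot(lsc_len > 0, ir_len >= 0, ssc_len > 0,
            all(unlist(rates) >= 0), all(unlist(rates) <= 0.1),
            indel_rate >= 0, n_ingroup >= 2, n_outgroup >= 2)
  structure(as.list(environment()), class = "synth_config")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## place n gene models in [lo, hi]; returns list(genes, exons)
.place_genes <- function(lo, hi, n, prefix, config, with_introns = TRUE) {
  genes <- list(); exons <- list()
  pos <- lo
  for (i in seq_len(n)) {
    pos <- pos + sample(config$gap_range[1]:config$gap_range[2], 1L)
    n_introns <- if (with_introns && runif(1) < config$intron_frac) {
      sample(1:2, 1L)
    } else 0L
    if (n_introns == 0L) {
      len <- sample(config$gene_len_range[1]:config$gene_len_range[2], 1L)
      parts <- data.frame(kind = "exon", len = len)
    } else {
      ex <- sample(config$exon_len_range[1]:config$exon_len_range[2],
                   n_introns + 1L, replace = TRUE)
      intr <- sample(config$intron_len_range[1]:config$intron_len_range[2],
                     n_introns, replace = TRUE)
      kind <- character(0); len <- integer(0)
      for (k in seq_len(n_introns)) {
        kind <- c(kind, "exon", "intron"); len <- c(len, ex[k], intr[k])
      }
      kind <- c(kind, "exon"); len <- c(len, ex[n_introns + 1L])
      parts <- data.frame(kind = kind, len = len)
    }
    g_start <- pos
    g_end <- pos + sum(parts$len) - 1L
    if (g_end > hi) {
      stop("requested gene lengths exceed region capacity (",
           prefix, ": gene ", i, " would end at ", g_end, " > ", hi, ")")
    }
    id <- sprintf("%s%02d", prefix, i)
    strand <- sample(c("+", "-"), 1L)
    genes[[i]] <- data.frame(id = id, gene = id, start = g_start, end = g_end,
                             strand = strand, gene_class = "coding",
                             stringsAsFactors = FALSE)
    p <- g_start; idx <- 0L
    for (k in seq_len(nrow(parts))) {
      if (parts$kind[k] == "exon") {
        idx <- idx + 1L
        exons[[length(exons) + 1L]] <- data.frame(
          name = id, feature_class = "coding_exon", start = p,
          end = p + parts$len[k] - 1L, strand = strand, parent_gene = id,
          in_inverted_repeat = FALSE, exon_index = idx, wraps_origin = FALSE,
          stringsAsFactors = FALSE)
      }
      p <- p + parts$len[k]
    }
    pos <- g_end + 1L
  }
  list(genes = do.call(rbind, genes), exons = do.call(rbind, exons))
}

#' Generate a synthetic plastome with annotation and known structure
#'
#' Builds a circular genome of `lsc_len + 2*ir_len + ssc_len` bp in
#' canonical orientation (LSC from position 1, then IRa, SSC, IRb) with
#' IRb the exact reverse complement of IRa, places non-overlapping gene
#' models (a configurable fraction with introns) in the single-copy
#' regions and the IR, and returns the ground-truth quadripartite
#' structure alongside.
#'
#' @param config a `"synth_config"`.
#' @return list with `genome` (a `"plastome"`), `annotation` (an
#'   `"annotation_set"` of exon and pseudogene features plus gene table),
#'   `structure` (the truth `"quadripartite"`), and `config`.
#' @export
generate_plastome <- function(config = synth_config()) {
  set.seed(config$seed)
  L <- config$lsc_len + 2L * config$ir_len + config$ssc_len
  lsc_seq <- .rand_dna(config$lsc_len)
  ira_seq <- .rand_dna(config$ir_len)
  ssc_seq <- .rand_dna(config$ssc_len)
  # the planted IR must be maximal: if the first and last SSC bases happen
  # to be complementary, seed-and-extend would legitimately grow the repeat
  # across the SSC border, so force a mismatch there
  if (config$ir_len > 0 && config$ssc_len >= 2) {
    first <- substr(ssc_seq, 1L, 1L)
    last <- substr(ssc_seq, config$ssc_len, config$ssc_len)
    if (comp_chars(last) == first) {
      repl <- setdiff(c("A", "C", "G", "T"), comp_chars(first))[1]
      substr(ssc_seq, config$ssc_len, config$ssc_len) <- repl
    }
  }
  residues <- paste0(lsc_seq, ira_seq, ssc_seq,
                     if (config$ir_len > 0) revcomp(ira_seq) else "")
  genome <- plastome_sequence("synth_plastome", residues, circular = TRUE)

  lsc_iv <- c(1L, config$lsc_len)
  ira_iv <- c(config$lsc_len + 1L, config$lsc_len + config$ir_len)
  ssc_iv <- c(ira_iv[2] + 1L, ira_iv[2] + config$ssc_len)
  irb_iv <- c(ssc_iv[2] + 1L, L)
  truth_structure <- structure(
    list(lsc = lsc_iv, ira = ira_iv, ssc = ssc_iv, irb = irb_iv,
         lsc_len = config$lsc_len, ir_len = config$ir_len,
         ssc_len = config$ssc_len, total_len = L),
    class = "quadripartite")

  margin <- 200L
  lsc_g <- .place_genes(lsc_iv[1] + margin, lsc_iv[2] - margin,
                        config$n_genes$lsc, "gl", config)
  ssc_g <- .place_genes(ssc_iv[1] + margin, ssc_iv[2] - margin,
                        config$n_genes$ssc, "gs", config)
  genes <- rbind(lsc_g$genes, ssc_g$genes)
  exons <- rbind(lsc_g$exons, ssc_g$exons)
  if (config$ir_len > 0 && config$n_genes$ir > 0) {
    ir_g <- .place_genes(ira_iv[1] + margin, ira_iv[2] - margin,
                         config$n_genes$ir, "gi", config,
                         with_introns = FALSE)
    ir_g$genes$gene_class <- "rRNA"
    ir_g$exons$feature_class <- "rRNA"
    ir_g$exons$in_inverted_repeat <- TRUE
    # mirror each IR gene into IRb (reverse-complement copy)
    mirror <- function(s, e) c(irb_iv[1] + (ira_iv[2] - e),
                               irb_iv[1] + (ira_iv[2] - s))
    mg <- ir_g$genes; me <- ir_g$exons
    for (r in seq_len(nrow(mg))) {
      iv <- mirror(mg$start[r], mg$end[r])
      mg$start[r] <- iv[1]; mg$end[r] <- iv[2]
      mg$id[r] <- paste0(mg$id[r], "_irb")
      mg$strand[r] <- if (mg$strand[r] == "+") "-" else "+"
    }
    for (r in seq_len(nrow(me))) {
      iv <- mirror(me$start[r], me$end[r])
      me$start[r] <- iv[1]; me$end[r] <- iv[2]
      me$parent_gene[r] <- paste0(me$parent_gene[r], "_irb")
      me$strand[r] <- if (me$strand[r] == "+") "-" else "+"
    }
    genes <- rbind(genes, ir_g$genes, mg)
    exons <- rbind(exons, ir_g$exons, me)
  }
  feats <- exons
  if (config$n_pseudogenes > 0) {
    # pseudogenes occupy part of the gap after the last SSC gene
    anchor <- max(ssc_g$genes$end)
    for (i in seq_len(config$n_pseudogenes)) {
      s <- anchor + 60L * i + 150L * (i - 1L)
      e <- s + 149L
      if (e > ssc_iv[2] - 50L) break
      feats <- rbind(feats, data.frame(
        name = paste0("psi", i), feature_class = "pseudogene", start = s,
        end = e, strand = "+", parent_gene = NA_character_,
        exon_index = NA_integer_, in_inverted_repeat = FALSE,
        wraps_origin = FALSE, stringsAsFactors = FALSE))
    }
  }
  annotation <- annotation_set(genome, feats, genes = genes)
  list(genome = genome, annotation = annotation,
       structure = truth_structure, config = config)
}

#' Simulate divergence of two clades from a synthetic reference
#'
#' Star-phylogeny model: each non-reference taxon draws independent
#' per-site Bernoulli substitutions with class-specific rates (coding
#' exon, intron, intergenic/pseudogene) over the one-IR-trimmed extent of
#' the genome; substitutions falling in IRa are mirrored into IRb in the
#' taxon sequences so both repeat copies stay identical. Short deletions
#' (1-4 bp) occur at `indel_rate` and never overlap substitutions
#' (rejection). Variant quality scores follow the configured normal model
#' with a set fraction pushed below 30.
#'
#' @param bundle output of [generate_plastome()] (reference, annotation
#'   and truth structure).
#' @param config a `"synth_config"` (defaults to the bundle's).
#' @return list with `snps` (a `"snp_table"` over the five non-reference
#'   taxa), `clades` (a `"clade_map"`), `taxa_sequences` (named character
#'   vector of full-length taxon genomes), and `truth`: `events` (one row
#'   per taxon/position/class), `picsets` (truth PIC positions per clade,
#'   computed directly from the simulated alleles), and `anchors` (truth
#'   target positions per selection rule).
#' @export
simulate_divergence <- function(bundle, config = bundle$config) {
  set.seed(config$seed + 1000L)
  genome <- bundle$genome
  st <- bundle$structure
  ann <- bundle$annotation
  if (!any(ann$features$feature_class == "intron")) ann <- derive_introns(ann)
  trimmed_len <- st$total_len - st$ir_len

  cls <- rep("igs", trimmed_len)
  f <- ann$features
  for (i in seq_len(nrow(f))) {
    if (f$start[i] > trimmed_len) next
    e <- min(f$end[i], trimmed_len)
    cl <- switch(f$feature_class[i],
                 coding_exon = "coding", tRNA = "coding", rRNA = "coding",
                 intron = "intron", NA_character_)
    if (!is.na(cl)) cls[f$start[i]:e] <- cl
  }

  ingroup <- sprintf("hawaii_%d", seq_len(config$n_ingroup))
  outgroup <- sprintf("stachys_%d", seq_len(config$n_outgroup))
  reference <- ingroup[1]
  clades <- clade_map(c(ingroup, outgroup),
                      c(rep("ingroup", length(ingroup)),
                        rep("outgroup", length(outgroup))),
                      reference_taxon = reference)
  vcf_taxa <- setdiff(c(ingroup, outgroup), reference)

  ref_chars <- strsplit(genome$residues, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  events <- list()
  sub_pos_all <- integer(0)
  for (tx in vcf_taxa) {
    rate <- config$rates[[clades$clade[clades$taxon == tx]]]
    p_site <- unname(rate[cls])
    sites <- which(runif(trimmed_len) < p_site)
    sites <- sites[ref_chars[sites] %in% bases]
    if (length(sites)) {
      alt <- vapply(sites, function(p) {
        sample(setdiff(bases, ref_chars[p]), 1L)
      }, "")
      events[[length(events) + 1L]] <- data.frame(
        taxon = tx, position = sites, ref = ref_chars[sites], alt = alt,
        class = "substitution", site_class = cls[sites],
        stringsAsFactors = FALSE)
      sub_pos_all <- c(sub_pos_all, sites)
    }
  }
  sub_pos_all <- sort(unique(sub_pos_all))

  # deletions, rejected where they would touch any substitution or each other
  occupied <- sub_pos_all
  for (tx in vcf_taxa) {
    cand <- which(runif(trimmed_len) < config$indel_rate)
    for (p in cand) {
      len <- sample(1:4, 1L)
      if (p + len > trimmed_len) next
      span <- p:(p + len)
      if (any(span %in% occupied)) next
      events[[length(events) + 1L]] <- data.frame(
        taxon = tx, position = p, ref = paste(ref_chars[span], collapse = ""),
        alt = ref_chars[p], class = "indel", site_class = cls[p],
        stringsAsFactors = FALSE)
      occupied <- c(occupied, span)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(taxon = character(), position = integer(), ref = character(),
               alt = character(), class = character(),
               site_class = character(), stringsAsFactors = FALSE)

  # one VCF row per variant position
  all_pos <- sort(unique(events$position))
  n <- length(all_pos)
  alleles <- as.data.frame(setNames(rep(list(rep(NA_character_, n)),
                                        length(vcf_taxa)), vcf_taxa),
                           check.names = FALSE)
  ref_al <- character(n); vtype <- character(n)
  for (i in seq_len(n)) {
    p <- all_pos[i]
    ev <- events[events$position == p, , drop = FALSE]
    vtype[i] <- ev$class[1]
    ref_al[i] <- ev$ref[1]
    for (tx in vcf_taxa) {
      row <- ev[ev$taxon == tx, , drop = FALSE]
      alleles[i, tx] <- if (nrow(row)) row$alt[1] else ref_al[i]
    }
  }
  qual <- numeric(n)
  if (n > 0) {
    low <- runif(n) < config$qual_below30_frac
    qual[low] <- runif(sum(low), 15, 29.9)
    qual[!low] <- pmax(30.01, rnorm(sum(!low), config$quality_model["mean"],
                                    config$quality_model["sd"]))
    qual <- round(qual, 2)
  }
  snps <- snp_table(all_pos, ref_al, qual, vtype, alleles)

  # taxon sequences: substitutions (mirrored into IRb), then deletions
  taxa_sequences <- setNames(vector("character", length(c(ingroup, outgroup))),
                             c(ingroup, outgroup))
  for (tx in names(taxa_sequences)) {
    chars <- ref_chars
    ev <- events[events$taxon == tx, , drop = FALSE]
    subs <- ev[ev$class == "substitution", , drop = FALSE]
    if (nrow(subs)) {
      chars[subs$position] <- subs$alt
      in_ira <- subs$position >= st$ira[1] & subs$position <= st$ira[2]
      if (any(in_ira)) {
        mp <- st$irb[1] + (st$ira[2] - subs$position[in_ira])
        chars[mp] <- comp_chars(subs$alt[in_ira])
      }
    }
    dels <- ev[ev$class == "indel", , drop = FALSE]
    if (nrow(dels)) {
      drop_idx <- unlist(lapply(seq_len(nrow(dels)), function(k) {
        (dels$position[k] + 1L):(dels$position[k] + nchar(dels$ref[k]) - 1L)
      }))
      chars <- chars[-drop_idx]
    }
    taxa_sequences[tx] <- paste(chars, collapse = "")
  }

  truth <- list(
    events = events,
    picsets = .truth_picsets(events, clades, vcf_taxa),
    anchors = .truth_anchors(events, clades, vcf_taxa, st))
  list(snps = snps, clades = clades, taxa_sequences = taxa_sequences,
       truth = truth, structure = st)
}

## truth PIC sets straight from the event list: a position is a truth PIC
## for a clade when clade members (reference included, carrying the
## reference allele) show >= 2 allele states among the true substitutions
.truth_picsets <- function(events, clades, vcf_taxa) {
  subs <- events[events$class == "substitution", , drop = FALSE]
  out <- list()
  for (cl in c("outgroup", "ingroup")) {
    members <- intersect(clade_taxa(clades, cl), vcf_taxa)
    ref_member <- attr(clades, "reference_taxon") %in% clade_taxa(clades, cl)
    pos <- sort(unique(subs$position[subs$taxon %in% members]))
    is_pic <- vapply(pos, function(p) {
      ev <- subs[subs$position == p & subs$taxon %in% members, , drop = FALSE]
      states <- ev$alt
      # members without an event carry the reference allele
      if (ref_member || length(states) < length(members)) {
        states <- c(states, ev$ref[1])
      }
      length(unique(states)) >= 2L
    }, TRUE)
    out[[cl]] <- structure(list(clade = cl, positions = pos[is_pic]),
                           class = "pic_set")
  }
  out
}

## truth target anchors per selection rule, from the event list
.truth_anchors <- function(events, clades, vcf_taxa, st) {
  subs <- events[events$class == "substitution", , drop = FALSE]
  in_members <- intersect(clade_taxa(clades, "ingroup"), vcf_taxa)
  out_members <- intersect(clade_taxa(clades, "outgroup"), vcf_taxa)
  pos <- sort(unique(subs$position))
  single_copy <- in_interval(pos, st$lsc, st$total_len) |
    in_interval(pos, st$ssc, st$total_len)
  rule1 <- vapply(pos, function(p) {
    n_alt <- sum(subs$position == p & subs$taxon %in% in_members)
    n_alt >= 1L && n_alt < length(in_members)
  }, TRUE)
  rule2 <- vapply(pos, function(p) {
    sum(subs$position == p & subs$taxon %in% out_members) >= 2L
  }, TRUE)
  list(rule1 = pos[rule1 & single_copy], rule2 = pos[rule2 & single_copy])
}

#' Write a synthetic bundle to disk
#'
#' Emits the standard file set consumed by the pipeline: reference FASTA,
#' GFF3 annotation, multi-sample VCF, clade map TSV, and the truth event
#' table.
#'
#' @param bundle output of [generate_plastome()].
#' @param sim output of [simulate_divergence()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_synth_bundle <- function(bundle, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "reference.fa"),
             gff = file.path(dir, "annotation.gff3"),
             vcf = file.path(dir, "calls.vcf"),
             clades = file.path(dir, "clades.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_plastome_fasta(bundle$genome, paths["fasta"])
  write_annotation_gff3(bundle$annotation, paths["gff"])
  write_snps_vcf(sim$snps, bundle$genome, paths["vcf"])
  write.table(as.data.frame(sim$clades), paths["clades"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$events, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}
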