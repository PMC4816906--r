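# Quality filtering, PIC calling, window profiles, summary statistics and
# per-locus variability tables.

# independent per-position oracle used against call_pics: loops over rows
# and collects allele states by hand
oracle_pics <- function(snps, clades, clade) {
  members <- clade_taxa(clades, clade)
  ref_taxon <- attr(clades, "reference_taxon")
  explicit <- intersect(members, snp_taxa(snps))
  hits <- integer(0)
  for (i in seq_len(nrow(snps))) {
    states <- character(0)
    for (tx in explicit) {
      a <- snps[[tx]][i]
      if (!is.na(a)) states <- c(states, a)
    }
    if (ref_taxon %in% members && !(ref_taxon %in% explicit)) {
      states <- c(states, snps$ref_allele[i])
    }
    if (length(unique(states)) >= 2) hits <- c(hits, snps$position[i])
  }
  sort(unique(hits))
}

test_that("the quality filter is strict and drops indels", {
  cm <- two_clade_map()
  snps <- make_snps(c(10L, 20L, 30L, 40L),
                    c("A", "C", "G", "T"),
                    c(29, 30, 31, 99),
                    c("substitution", "substitution", "substitution", "indel"),
                    list(h2 = c("G", "T", "A", "T"),
                         s1 = c("A", "C", "G", "T")))
  f <- filter_snps(snps)
  expect_equal(f$position, 30L)      # only quality 31 survives strict > 30
  f2 <- filter_snps(snps, analysis_params(qual_inclusive = TRUE))
  expect_equal(f2$position, c(20L, 30L))
  # the quality-99 indel is always removed
  expect_false(40L %in% f2$position)
})

test_that("filtering matches a brute-force record scan", {
  set.seed(55)
  for (rep in 1:10) {
    n <- 50
    snps <- make_snps(sort(sample(1e4, n)),
                      sample(c("A", "C", "G", "T"), n, TRUE),
                      runif(n, 10, 90),
                      sample(c("substitution", "indel"), n, TRUE,
                             prob = c(0.8, 0.2)),
                      list(h2 = sample(c("A", "G", NA), n, TRUE)))
    f <- filter_snps(snps)
    keep <- logical(n)
    for (i in 1:n) {
      keep[i] <- snps$quality[i] > 30 && snps$variant_type[i] == "substitution"
    }
    expect_equal(f$position, snps$position[keep])
  }
})

test_that("PICs require two allele states within the clade", {
  cm <- two_clade_map()
  # position 10: only the outgroup varies; 20: outgroup two states (G,G,T);
  # 30: one ingroup taxon differs from the reference
  snps <- make_snps(c(10L, 20L, 30L),
                    c("A", "C", "A"),
                    c(50, 50, 50), rep("substitution", 3),
                    list(h2 = c("A", "C", "G"), h3 = c("A", "C", "A"),
                         s1 = c("G", "G", "A"), s2 = c("G", "G", "A"),
                         s3 = c("G", "T", "A")))
  ing <- call_pics(snps, cm, "ingroup")
  outg <- call_pics(snps, cm, "outgroup")
  expect_equal(ing$positions, 30L)  # reference allele vs h2's G
  # at 10 the outgroup is monomorphic (G,G,G) and, lacking a reference
  # member, shows a single state: divergence from the reference alone is
  # not a within-clade PIC; at 20 it shows two states (G,G,T)
  expect_equal(outg$positions, 20L)
})

test_that("a clade with fewer than two effective members is an error", {
  cm <- clade_map(c("h1", "s1", "s2"), c("ingroup", "outgroup", "outgroup"),
                  reference_taxon = "h1")
  snps <- make_snps(10L, "A", 50, "substitution",
                    list(s1 = "G", s2 = "A"))
  expect_error(call_pics(snps, cm, "ingroup"), "fewer than 2")
  expect_silent(call_pics(snps, cm, "outgroup"))
})

test_that("PIC calling equals the brute-force oracle on simulations", {
  for (seed in 1:5) {
    b <- small_bundle(seed = seed)
    sim <- simulate_divergence(b)
    f <- filter_snps(sim$snps)
    for (cl in c("ingroup", "outgroup")) {
      got <- call_pics(f, sim$clades, cl)$positions
      expect_equal(got, oracle_pics(f, sim$clades, cl), info = paste(seed, cl))
    }
  }
})

test_that("missing genotypes are non-informative by default", {
  cm <- two_clade_map()
  snps <- make_snps(10L, "A", 50, "substitution",
                    list(h2 = NA_character_, h3 = "A",
                         s1 = "G", s2 = NA_character_, s3 = "G"))
  # ingroup: states {ref A, A} -> conserved; outgroup: {G, G} -> one state
  expect_length(call_pics(snps, cm, "ingroup")$positions, 0)
  expect_length(call_pics(snps, cm, "outgroup")$positions, 0)
  # with missing-as-reference the outgroup gains a reference state
  p <- analysis_params(missing_as_reference = TRUE)
  expect_equal(call_pics(snps, cm, "outgroup", p)$positions, 10L)
})

test_that("raising the quality threshold never increases PIC counts", {
  for (seed in 1:3) {
    b <- small_bundle(seed = seed)
    sim <- simulate_divergence(b)
    prev <- Inf
    for (q in c(20, 30, 50, 80)) {
      f <- filter_snps(sim$snps, analysis_params(min_snp_quality = q))
      n <- length(call_pics(f, sim$clades, "outgroup")$positions)
      expect_lte(n, prev)
      prev <- n
    }
  }
})

test_that("window counts are conserved and placed correctly", {
  ps <- structure(list(clade = "outgroup", positions = sort(sample(999, 10))),
                  class = "pic_set")
  wp <- window_profile(list(outgroup = ps), 3000)
  expect_equal(wp$count_outgroup, c(10L, 0L, 0L))
  expect_equal(wp$begin, c(1L, 1001L, 2001L))
  expect_equal(wp$end, c(1000L, 2000L, 3000L))

  set.seed(66)
  for (rep in 1:100) {
    L <- sample(2000:30000, 1)
    n <- sample(0:300, 1)
    pos <- sort(sample(L, min(n, L)))
    ps <- structure(list(clade = "x", positions = pos), class = "pic_set")
    wp <- window_profile(list(x = ps), L)
    expect_equal(sum(wp$count_x), length(pos))
    expect_equal(nrow(wp), ceiling(L / 1000))
  }
  expect_error(window_profile(list(), 0), "positive")
})

test_that("summary statistics match a sort-based oracle", {
  s <- summarize_stats(7)
  expect_equal(c(s$min, s$max, s$total, s$mean, s$median), c(7, 7, 7, 7, 7))
  expect_error(summarize_stats(numeric(0)), "empty")

  set.seed(77)
  for (rep in 1:50) {
    v <- sample(0:20, sample(1:40, 1), replace = TRUE)
    s <- summarize_stats(v)
    sv <- sort(v); n <- length(sv)
    med <- if (n %% 2) sv[(n + 1) / 2] else (sv[n / 2] + sv[n / 2 + 1]) / 2
    expect_equal(s$min, min(v))
    expect_equal(s$max, max(v))
    expect_equal(s$total, sum(v))
    expect_equal(s$mean, round_half_up(mean(v), 2))
    expect_equal(s$median, round_half_up(med, 2))
  }
})

test_that("round-half-up differs from banker's rounding where it should", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(0.135, 2), 0.14)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(percent_pics(14, 1530), 0.92)
  expect_equal(percent_pics(0, 500), 0)
  expect_error(percent_pics(1, 0), "positive")
  expect_error(percent_pics(-1, 10), "non-negative")
})

test_that("locus tables count PICs per region with exclusion rules", {
  g <- plastome_sequence("t", random_dna(10000))
  feats <- data.frame(
    name = c("gA", "gA", "gB", "psX"),
    feature_class = c("coding_exon", "coding_exon", "coding_exon",
                      "pseudogene"),
    start = c(1000L, 2000L, 3000L, 6000L),
    end = c(1499L, 2399L, 3098L, 6499L),
    strand = "+",
    parent_gene = c("gA", "gA", "gB", NA),
    exon_index = c(1L, 2L, 1L, NA),
    stringsAsFactors = FALSE)
  genes <- data.frame(id = c("gA", "gB"), gene = c("gA", "gB"),
                      start = c(1000L, 3000L), end = c(2399L, 3098L),
                      strand = "+", gene_class = "coding",
                      stringsAsFactors = FALSE)
  ann <- derive_intergenic_spacers(derive_introns(
    annotation_set(g, feats, genes = genes)))
  ps_out <- structure(list(clade = "outgroup",
                           positions = c(1100L, 1200L, 2100L, 3050L, 6100L)),
                      class = "pic_set")
  ps_in <- structure(list(clade = "ingroup", positions = c(1100L, 1700L)),
                     class = "pic_set")
  picsets <- list(outgroup = ps_out, ingroup = ps_in)

  cod <- locus_table(picsets, ann, "coding_exon")
  # gB (99 bp) excluded by the minimum-length rule despite its PIC
  expect_false(any(grepl("gB", cod$region)))
  expect_setequal(cod$region, c("gA Exon1", "gA Exon2"))
  expect_equal(cod$pics_outgroup[cod$region == "gA Exon1"], 2L)
  expect_equal(cod$pct_outgroup[cod$region == "gA Exon1"],
               round_half_up(100 * 2 / 500, 2))

  intr <- locus_table(picsets, ann, "intron")
  expect_equal(intr$region, "gA")
  expect_equal(intr$pics_ingroup, 1L)  # position 1700 in the 1500-1999 gap

  igs <- locus_table(picsets, ann, "igs_or_pseudogene")
  expect_true("psX" %in% igs$region)
  # fully conserved spacers are excluded by default but kept on request
  igs_all <- locus_table(picsets, ann, "igs_or_pseudogene",
                         conserved_filter = FALSE)
  expect_gt(nrow(igs_all), nrow(igs))
  expect_error(locus_table(picsets, ann, "promoter"))
})

test_that("locus PIC counts match a brute-force interval scan", {
  for (seed in 1:3) {
    b <- small_bundle(seed = seed)
    sim <- simulate_divergence(b)
    f <- filter_snps(sim$snps)
    picsets <- list(outgroup = call_pics(f, sim$clades, "outgroup"),
                    ingroup = call_pics(f, sim$clades, "ingroup"))
    ann <- derive_intergenic_spacers(derive_introns(b$annotation))
    for (rc in c("coding_exon", "intron", "igs_or_pseudogene")) {
      tb <- locus_table(picsets, ann, rc, conserved_filter = FALSE)
      for (i in seq_len(nrow(tb))) {
        # brute force re-count from the feature table by region span
        # (regions are unique per class in the synthetic annotation)
        cls <- switch(rc, coding_exon = c("coding_exon", "tRNA", "rRNA"),
                      intron = "intron",
                      c("intergenic_spacer", "pseudogene"))
        fset <- ann$features[ann$features$feature_class %in% cls, ]
        nm <- tb$region[i]
        base <- sub(" Exon[0-9]+$", "", sub("-[0-9]+$", "", nm))
        rows <- fset[gsub("_", "-", fset$name) == gsub("_", "-", base) |
                       fset$name == base | fset$name == nm, ]
        expect_gt(nrow(rows), 0)
        brute <- sum(vapply(seq_len(nrow(rows)), function(r) {
          sum(picsets$outgroup$positions >= rows$start[r] &
                picsets$outgroup$positions <= rows$end[r])
        }, 0L))
        total_tb <- sum(tb$pics_outgroup[
          sub(" Exon[0-9]+$", "", sub("-[0-9]+$", "", tb$region)) == base |
            tb$region == nm])
        expect_equal(total_tb, brute, info = paste(seed, rc, nm))
      }
    }
  }
})

test_that("intron segments around a nested gene are reported separately", {
  g <- plastome_sequence("t", random_dna(6000))
  # trnK-like host gene: exons 1-36 and 2581-2614, matK-like gene nested
  # inside the intron at 301-2000
  feats <- data.frame(
    name = c("trnK", "trnK", "matK"),
    feature_class = c("tRNA", "tRNA", "coding_exon"),
    start = c(1L, 2581L, 301L), end = c(36L, 2614L, 2000L),
    strand = "-", parent_gene = c("gK", "gK", "gM"),
    exon_index = c(1L, 2L, 1L), stringsAsFactors = FALSE)
  genes <- data.frame(id = c("gK", "gM"), gene = c("trnK", "matK"),
                      start = c(1L, 301L), end = c(2614L, 2000L),
                      strand = "-", gene_class = c("tRNA", "coding"),
                      stringsAsFactors = FALSE)
  ann <- derive_introns(annotation_set(g, feats, genes = genes))
  ps <- structure(list(clade = "outgroup", positions = c(100L, 2100L, 2200L)),
                  class = "pic_set")
  tb <- locus_table(list(outgroup = ps), ann, "intron")
  expect_setequal(tb$region, c("trnK-1", "trnK-2"))
  expect_equal(tb$length[tb$region == "trnK-1"], 264L)  # 37..300
  expect_equal(tb$length[tb$region == "trnK-2"], 580L)  # 2001..2580
  expect_equal(tb$pics_outgroup[tb$region == "trnK-1"], 1L)
  expect_equal(tb$pics_outgroup[tb$region == "trnK-2"], 2L)
})
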