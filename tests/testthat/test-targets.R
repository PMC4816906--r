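# Target selection rules, flank extraction, interval merging, primer
# picking, melting temperature and adapter tailing.

toy_structure <- function(L = 10000L, lsc = 6000L, ir = 1500L) {
  ssc <- L - lsc - 2L * ir
  structure(list(lsc = c(1L, lsc), ira = c(lsc + 1L, lsc + ir),
                 ssc = c(lsc + ir + 1L, lsc + ir + ssc),
                 irb = c(L - ir + 1L, L),
                 lsc_len = lsc, ir_len = ir, ssc_len = ssc, total_len = L),
            class = "quadripartite")
}

test_that("selection rule 1 admits ingroup variants except all-alternative", {
  cm <- two_clade_map()
  st <- toy_structure()
  snps <- make_snps(c(100L, 200L, 300L),
                    c("A", "A", "A"), c(50, 50, 50),
                    rep("substitution", 3),
                    list(h2 = c("G", "G", "A"), h3 = c("A", "G", "A"),
                         s1 = c("A", "A", "G"), s2 = c("A", "A", "A"),
                         s3 = c("A", "A", "A")))
  sel <- select_targets(snps, cm, st)
  # 100: one ingroup variant -> rule 1; 200: every ingroup taxon carries an
  # alternative allele -> excluded; 300: a single outgroup variant -> not
  # enough for rule 2
  expect_equal(sel$position, 100L)
  expect_equal(sel$rule, "ingroup_variant")
})

test_that("selection rule 2 needs two variant outgroup taxa", {
  cm <- two_clade_map()
  st <- toy_structure()
  snps <- make_snps(c(100L, 200L),
                    c("C", "C"), c(50, 50), rep("substitution", 2),
                    list(h2 = c("C", "C"), h3 = c("C", "C"),
                         s1 = c("T", "T"), s2 = c("C", "T"),
                         s3 = c("C", "C")))
  sel <- select_targets(snps, cm, st)
  expect_equal(sel$position, 200L)
  expect_equal(sel$rule, "outgroup_pair_variant")
})

test_that("positions inside the inverted repeats are never selected", {
  cm <- two_clade_map()
  st <- toy_structure()
  ir_pos <- st$ira[1] + 100L
  snps <- make_snps(c(500L, ir_pos), c("A", "A"), c(50, 50),
                    rep("substitution", 2),
                    list(h2 = c("G", "G"), h3 = c("A", "A"),
                         s1 = c("A", "A"), s2 = c("A", "A"),
                         s3 = c("A", "A")))
  sel <- select_targets(snps, cm, st)
  expect_equal(sel$position, 500L)
})

test_that("a missing genotype blocks the all-alternative exception", {
  cm <- two_clade_map()
  st <- toy_structure()
  snps <- make_snps(100L, "A", 50, "substitution",
                    list(h2 = "G", h3 = NA_character_,
                         s1 = "A", s2 = "A", s3 = "A"))
  sel <- select_targets(snps, cm, st)
  expect_equal(sel$position, 100L)
})

test_that("flank extraction clips at single-copy boundaries", {
  st <- toy_structure()
  r <- extract_flanks(771L, st)
  expect_equal(c(r$start, r$end), c(671L, 871L))
  expect_equal(r$end - r$start + 1L, 201L)
  # near the sequence start
  r <- extract_flanks(50L, st)
  expect_equal(c(r$start, r$end), c(1L, 150L))
  # near the LSC/IRa border the region stops at the LSC edge
  r <- extract_flanks(st$lsc[2] - 10L, st)
  expect_equal(r$end, st$lsc[2])
  # SSC anchors clip at SSC borders
  r <- extract_flanks(st$ssc[1] + 5L, st)
  expect_equal(r$start, st$ssc[1])
  expect_error(extract_flanks(st$ira[1] + 10L, st), "inverted repeat")
})

test_that("random flank sizes follow the clipping arithmetic", {
  st <- toy_structure()
  set.seed(88)
  anchors <- sample(c(st$lsc[1]:st$lsc[2], st$ssc[1]:st$ssc[2]), 200)
  for (a in anchors) {
    r <- extract_flanks(a, st)
    seg <- if (a <= st$lsc[2]) st$lsc else st$ssc
    expect_equal(r$end - r$start + 1L,
                 min(a + 100L, seg[2]) - max(a - 100L, seg[1]) + 1L)
  }
})

test_that("overlapping and book-ended regions merge; disjoint do not", {
  regs <- data.frame(start = c(100L, 250L), end = c(300L, 450L),
                     anchors = c("200", "350"), rule = "ingroup_variant",
                     merged_from = c(1L, 1L), stringsAsFactors = FALSE)
  m <- merge_targets(regs)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100L, 450L))
  expect_equal(m$merged_from, 2L)
  expect_equal(m$anchors, "200,350")

  disj <- data.frame(start = c(100L, 500L), end = c(200L, 600L),
                     anchors = c("150", "550"), rule = "x",
                     merged_from = c(1L, 1L), stringsAsFactors = FALSE)
  expect_equal(merge_targets(disj), disj)
  # book-ended (end + 1 == next start) merges
  be <- data.frame(start = c(100L, 201L), end = c(200L, 300L),
                   anchors = c("a", "b"), rule = "x",
                   merged_from = c(1L, 1L), stringsAsFactors = FALSE)
  expect_equal(nrow(merge_targets(be)), 1L)
})

test_that("merging matches a sweep-line oracle on random interval sets", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(1:25, 1)
    s <- sample(1:500, n, replace = TRUE)
    e <- s + sample(0:80, n, replace = TRUE)
    regs <- data.frame(start = s, end = e, anchors = as.character(s),
                       rule = "x", merged_from = 1L, stringsAsFactors = FALSE)
    m <- merge_targets(regs)
    # oracle: mark covered positions (book-ended intervals fuse, so pad
    # each interval by half a unit via doubling coordinates)
    covered <- rep(FALSE, 2L * (max(e) + 2L))
    for (i in seq_len(n)) covered[(2 * s[i]):(2 * e[i] + 1L)] <- TRUE
    runs <- rle(covered)
    expect_equal(nrow(m), sum(runs$values))
    expect_equal(sum(m$merged_from), n)
    expect_true(all(m$start[-1] > m$end[-nrow(m)] + 1L))
  }
})

test_that("tail concatenation is exact and tolerant of degenerate bases", {
  tails <- tail_spec()
  got <- append_tails("CCATGAGCGGCTACGATATT", "CAGGCTGAGCACAACATTCT")
  expect_identical(got$fwd_tailed,
                   "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAGCCATGAGCGGCTACGATATT")
  expect_identical(got$rev_tailed, paste0(tails$rev, "CAGGCTGAGCACAACATTCT"))
  # empty core: the bare tail comes back (flagged invalid downstream)
  expect_identical(append_tails("", "")$fwd_tailed, tails$fwd)
  # IUPAC degenerate bases are legitimate in primers
  expect_identical(append_tails("GGAAGACACGGAWACAAAGG", "ACGT")$fwd_tailed,
                   paste0(tails$fwd, "GGAAGACACGGAWACAAAGG"))
  expect_error(append_tails("ACGT-ACGT", "ACGT"), "invalid character")
})

test_that("melting temperature behaves like a duplex model", {
  s <- strrep("ACGT", 5)
  expect_equal(melting_temperature(s), melting_temperature(revcomp(s)))
  expect_lt(melting_temperature(strrep("AT", 10)),
            melting_temperature(strrep("GC", 10)))
  expect_error(melting_temperature("ACGTN"), "invalid character|too short")
  expect_error(melting_temperature("ACGTACGTNN"), "invalid character")
  expect_error(melting_temperature("ACGT"), "too short")

  set.seed(111)
  for (rep in 1:20) {
    s <- random_dna(sample(15:25, 1))
    expect_gte(melting_temperature(paste0(s, "GC")),
               melting_temperature(s) - 1e-9)
  }
})

test_that("primer picking respects hard constraints", {
  # flanks of pure A: GC content and homopolymer rules forbid any primer
  g <- plastome_sequence("t", paste0(strrep("A", 100), "G", strrep("A", 100)))
  region <- data.frame(start = 1L, end = 201L, anchors = "101",
                       stringsAsFactors = FALSE)
  p <- pick_primers(region, g, primer_constraints())
  expect_false(p$found)
})

test_that("a uniquely admissible window pair is found exhaustively", {
  # one 20-nt admissible island per all-A flank: the island passes GC and
  # homopolymer rules, while any window shifted off it gains a >= 5 A run
  # (island edges are 4 A's) or falls below the GC floor, so exactly one
  # window per side is admissible
  island <- paste0("AAAA", "GCTGCATGCCGT", "AAAA")
  left <- paste0(strrep("A", 30), island, strrep("A", 50))
  right <- paste0(strrep("A", 50), island, strrep("A", 30))
  g <- plastome_sequence("t", paste0(left, "G", right))
  region <- data.frame(start = 1L, end = nchar(g$residues), anchors = "101",
                       stringsAsFactors = FALSE)
  cons <- primer_constraints(min_len = 20L, max_len = 20L)
  p <- pick_primers(region, g, cons)
  expect_true(p$found)
  expect_identical(p$fwd_core, substr(left, 31, 50))
  expect_identical(p$rev_core, revcomp(substr(g$residues, 152, 171)))
  expect_identical(p$fwd_tailed, paste0(tail_spec()$fwd, p$fwd_core))
})

test_that("picked primers flank the anchors and report their span", {
  b <- small_bundle(seed = 5)
  sim <- simulate_divergence(b)
  f <- filter_snps(sim$snps)
  sel <- select_targets(f, sim$clades, b$structure)
  tg <- build_targets(sel, b$structure)
  found <- 0
  for (i in seq_len(min(nrow(tg), 10))) {
    p <- pick_primers(tg[i, ], b$genome)
    if (!p$found) next
    found <- found + 1
    anchors <- as.integer(strsplit(tg$anchors[i], ",")[[1]])
    expect_lte(p$product_span[1], min(anchors) - nchar(p$fwd_core))
    expect_gte(p$product_span[2], max(anchors) + nchar(p$rev_core))
    # the cores really are the reference subsequences at the span ends
    expect_identical(p$fwd_core,
                     substr(b$genome$residues, p$product_span[1],
                            p$product_span[1] + nchar(p$fwd_core) - 1L))
    expect_identical(p$rev_core,
                     revcomp(substr(b$genome$residues,
                                    p$product_span[2] - nchar(p$rev_core) + 1L,
                                    p$product_span[2])))
  }
  expect_gt(found, 0)
})
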