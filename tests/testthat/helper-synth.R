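# Small, fast synthetic configurations used across tests.

small_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed,
                   lsc_len = 9000L, ir_len = 2000L, ssc_len = 6000L,
                   n_genes = list(lsc = 5L, ssc = 2L, ir = 1L),
                   n_pseudogenes = 1L,
                   gene_len_range = c(300L, 800L),
                   exon_len_range = c(100L, 400L),
                   intron_len_range = c(400L, 700L))
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

small_bundle <- function(seed = 1L, ...) {
  generate_plastome(small_config(seed = seed, ...))
}

# build a snp_table by hand from a compact spec:
# alleles: named list taxon -> character vector (NA = missing)
make_snps <- function(position, ref, quality, type, alleles) {
  snp_table(position, ref, quality, type,
            as.data.frame(alleles, stringsAsFactors = FALSE))
}

two_clade_map <- function() {
  clade_map(c("h1", "h2", "h3", "s1", "s2", "s3"),
            c("ingroup", "ingroup", "ingroup",
              "outgroup", "outgroup", "outgroup"),
            reference_taxon = "h1")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

no_features <- function() {
  data.frame(name = character(), feature_class = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}
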