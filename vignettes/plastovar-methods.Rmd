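---
title: "Profiling plastome variability and designing tailed amplicon panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling plastome variability and designing tailed amplicon panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastovar)
```

## Scope and model

`plastovar` compares a small set of complete chloroplast genomes split into
two clades — an *ingroup* (typically a recent radiation) and an *outgroup*
of closer relatives — against a single mapping reference, and turns the
comparison into (i) a ranked list of variable loci and (ii) an
adapter-tailed primer panel over the most variable single-copy regions.
The package assumes variants have already been called against the
reference (a multi-sample VCF from, e.g., `samtools`/`bcftools`); it does
not map reads or assemble genomes.

The unit of variability is the *potentially informative character* (PIC):
a reference position at which a clade's members show at least two distinct
nucleotide states. Three modelling choices define it precisely:

* **The reference taxon is a clade member.** It contributes the reference
  allele at every position. A clade that is monomorphic for an allele
  *different* from the reference is therefore variable only if the
  reference belongs to that clade. This is an assumption — one could
  instead treat the reference as external — and it is surfaced through the
  clade map rather than hidden.
* **Substitutions only.** Indels and rearrangements are excluded from the
  statistic (they are retained in the SNP table and classed `indel`, so a
  different analysis could use them).
* **Missing genotypes are non-informative.** A missing call contributes no
  allele state. The alternative reading — missing means "same as
  reference" — is available as `analysis_params(missing_as_reference =
  TRUE)`, but the default is conservative: an absence of evidence of
  variation is not evidence of the reference allele.

## Quadripartite structure and the analysed extent

Plastomes carry two near-identical inverted repeats; any position inside
them exists twice per molecule. All variability statistics therefore run
on the one-IR-trimmed linearisation `LSC + IRa + SSC`
(`trim_one_ir()`), and PIC positions reported in the trimmed-off copy are
mirrored onto the retained copy (`collapse_ir_duplicates()`), so each
variable site is counted once. The retained copy is always IRa — the copy
adjacent to the LSC end — which fixes reporting coordinates
deterministically.

`find_inverted_repeat()` is a seed-and-extend search: exact k-mer seeds
(k = 25, one per 25 bp stride) are matched against the reverse complement
of the genome; because an ungapped inverted match at positions x and y
satisfies x + y = constant, seeds chain on anti-diagonals; the best-
populated diagonals are extended outwards base by base under an X-drop
rule and the resulting pair is accepted if it is at least `min_len`
(default 1000 bp) long with a mismatch fraction at most
`max_mismatch_frac` (default 1 %). Numerical choices that matter:

* extension scores match +1 / mismatch −3 with X-drop 20. A mismatch
  penalty of −1 lets chance matches in the flanking single-copy sequence
  (25 % per base) drag the border outwards roughly a third of the time;
  the steeper penalty makes border recovery exact on repeats without
  terminal mismatches, and the final borders are always trimmed back to
  exact-match columns;
* ties between equally long candidate pairs break towards the smaller
  start coordinate;
* if two supplied IR intervals differ in length by ≤ 2 bp the longer is
  trimmed symmetrically (`reconcile_ir_borders()`); a larger disagreement
  is an error, not silently repaired.

Defaults are deliberately permissive: plastid IRs are ~25 kb and
near-identical, so `min_len = 1000` and a 1 % mismatch budget cost
nothing while tolerating annotation-grade imperfection.

When the two single-copy arcs have exactly equal length, the arc
containing position 1 is declared the LSC and a warning is raised — a
degenerate case that only arises in constructed inputs.

## Windows, loci and rounding

Windows are uniform, non-overlapping and 1000 bp wide: window *i* covers
`[1000(i−1)+1, 1000i]` of the trimmed sequence, the last window being
partial but reported with its nominal end. (Published tables of this form
sometimes print the first window as 1–999 and subsequent ones as
1000–1999 etc.; the package uses uniform windows and leaves the first
coordinate convention to the reader — the counts and footers are
unaffected.)

Per-locus tables come in three region classes, mirroring how plastome
annotation is usually organised:

* `coding_exon` — exons of protein-coding, tRNA and rRNA genes; each exon
  of a multi-exon gene is a separate row (`"<gene> ExonN"`), because its
  exons can sit kilobases apart and differ sharply in variability;
* `intron` — derived, not annotated: for a gene record with k exons the
  k−1 inter-exon gaps are introns (`derive_introns()`). Genes nested
  inside another gene's intron (the classic case is matK inside the
  trnK-UUU intron) split that intron into separately reported segments.
  Trans-spliced genes represented as two gene records get introns only
  within each record, never across the genome between them;
* `igs_or_pseudogene` — intergenic spacers, derived as the gaps between
  consecutive gene/pseudogene spans on the circle
  (`derive_intergenic_spacers()`), pooled with pseudogenes. The gap
  spanning the origin is stored as two records sharing a name and
  reported once with its combined length.

Two exclusion rules keep the tables honest: regions shorter than 100 bp
are dropped (a single variable site in a 50-bp spacer would otherwise
look like 2 % divergence), and regions with no PIC in either clade
("conserved among all analysed taxa") are dropped by default.

All reported percentages, means and medians use **round-half-up at two
decimals** (`round_half_up()`), not R's default round-half-even — this is
the convention printed variability tables follow, and the packaged
reference tables recompute cell-for-cell only under this rule
(`validate_reference_tables()`). The quality threshold is **strictly**
`> 30` by default; the inclusive reading `>= 30` is a documented toggle
(`qual_inclusive`), since variant callers' conventions differ.

## Target selection and primer design

Anchors are selected position-wise from the filtered substitution table,
restricted to LSC and SSC (IR targets would amplify twice):

* **rule 1** — at least one ingroup taxon carries a non-reference allele,
  *except* when every ingroup taxon does: such positions separate the
  whole ingroup from the reference but cannot resolve anything within it;
* **rule 2** — at least two outgroup taxa carry non-reference alleles,
  adding positions informative for the outgroup backbone.

A missing genotype never counts as variant, and also blocks the rule-1
exception (one cannot assert "every taxon is non-reference" with a
missing call). Whether a "region" means a position or the locus
containing it is ambiguous in this kind of protocol; the package selects
at SNP-position level, takes ±100 bp flanks clipped at single-copy
borders, and merges overlapping or book-ended regions, which reproduces
the observed behaviour that one amplicon may cover several loci.

Primer picking is an exhaustive scored search within the flanks, with the
anchors always between the primers. Hard constraints: length 18–27 nt, GC
35–60 %, no homopolymer of 5+. Soft penalties: distance of each primer's
Tm from the 68.5 °C optimum, Tm imbalance between the pair, and
complementarity of the two 3'-terminal pentamers (a primer-dimer guard).
Ties break deterministically (leftmost forward primer, then shortest
product). The 68.5 °C optimum is the midpoint of the operating band
(≈67–71 °C) typical for tailed multiplex panels of this kind; the package
makes no claim of equivalence with any specific primer-design program.

Melting temperatures come from nearest-neighbor thermodynamics (the
unified dinucleotide ΔH/ΔS set with terminal initiation terms), a
monovalent-salt entropy correction `0.368·(N−1)·ln[Na+]`, and
`Tm = 1000·ΔH / (ΔS + R·ln(Ct/4)) − 273.15` at Na⁺ = 50 mM and total
strand concentration 500 nM. The parameters are fixed in code, so
reported Tm values are reproducible; they are self-consistent rather than
calibrated to any external program's output, and published Tm columns are
deliberately *not* used as test oracles — the formula behind such columns
is rarely stated, nor whether tails were included. Degenerate IUPAC bases
are accepted in primer *cores* (degenerate primers are legitimate;
adapter tailing is pure concatenation) but are an error in `melting_temperature()`,
whose thermodynamics are defined for unambiguous duplexes.

## What the synthetic generator does and does not emulate

`generate_plastome()` builds a canonical-orientation plastome (LSC from
position 1, then IRa, SSC, IRb = exact reverse complement of IRa) with
non-overlapping gene models, a configurable fraction of them carrying one
or two introns, a few rRNA genes mirrored into both IR copies, and
pseudogenes in the SSC. One subtlety: the planted IR must be the *maximal*
inverted repeat for truth comparisons to be exact, so the generator forces
a mismatch at the single border the linear search could otherwise extend
across (if the first and last SSC bases happen to be complementary, the
repeat genuinely continues — in random sequence that happens 25 % of the
time).

`simulate_divergence()` is a star phylogeny: each non-reference taxon
draws independent per-site Bernoulli substitutions, with class-specific
rates (intergenic > intron > coding exon) and clade-specific magnitude
(outgroup 5× ingroup by default), over the one-IR-trimmed extent;
substitutions landing in IRa are mirrored into IRb in the emitted taxon
sequences so the repeat stays homogenised. Deletions of 1–4 bp occur at
`indel_rate` and are rejection-sampled never to touch a substitution,
keeping VCF semantics simple. Variant QUAL scores follow a configurable
normal model with a set fraction pushed below 30 so the quality filter is
actually exercised. Every output is a pure function of the configuration
(`seed` included), and a full truth table — per-taxon events, truth PIC
sets computed directly from the event list, truth anchors per selection
rule — accompanies the data.

Default geometry and rates emulate the conditions of a mint-type
radiation study: LSC 81,364 / IR 25,436 / SSC 17,499 bp, two clades of
three taxa with the mapping reference inside the ingroup, and rates
chosen so a full-scale run yields PIC totals of the same order as that
study's (hundreds in the outgroup, ~100 in the ingroup). The test suite
runs the same generator at ~19 kb (LSC 9 kb, IR 2 kb, SSC 6 kb) so the
full suite finishes in about a minute; the statistics under test are
scale-free.

What the generator deliberately does **not** emulate: phylogenetic
correlation within clades (a star tree has none, so tests cannot detect
errors that only matter under shared branches), sequencing error and DNA
damage, alignment artefacts near indels, heterogeneous rates along the
genome beyond the three annotation classes, and structural rearrangements.
Green tests therefore certify the bookkeeping — filtering, counting,
coordinates, rounding, selection logic, tailing — not the biological
realism of any rate estimate on real data.

## Degenerate inputs and edge rules

* An empty (zero-variant) VCF is valid: all tables are emitted with zero
  counts and no targets, exit status success.
* Zero-length gaps produce no spacer; abutting exons produce no intron.
* `find_inverted_repeat()` returns an explicit `found = FALSE` result
  rather than throwing when no repeat of `min_len` exists.
* Heterozygous-looking VCF genotypes are an error (plastomes are
  effectively haploid); only haploid or homozygous-diploid calls are
  accepted, and missing calls are preserved.
* `percent_pics()` refuses non-positive lengths; `summarize_stats()`
  refuses empty input.

## Known limitations

* The IR search is ungapped; an IR pair differing by an indel would be
  recovered only up to the indel (dispersed small repeats and
  gapped-alignment detection are out of scope).
* Intron derivation trusts the exon annotation; mis-annotated exon
  boundaries propagate into intron and spacer coordinates unchanged.
* Primer scoring is intentionally simple (no secondary-structure
  prediction, no cross-pair multiplex compatibility); it reproduces the
  *shape* of a curated panel, not any specific tool's output.
* Tm values are model-based estimates; absolute accuracy depends on the
  parameter set and salt model, which is why they are documented
  constants rather than tuned values.
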