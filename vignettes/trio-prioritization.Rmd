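---
title: "Methods: trio exome candidate-gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio exome candidate-gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioprio)
```

This vignette is the package's account of its science: the screening
procedure it implements, the assumptions behind each rule, the parameters
that matter, what the synthetic cohort generator does and does not
emulate, and the numerical decisions taken where the design was open.

## The analysis model

The package targets the standard trio design for rare structural birth
defects: an affected proband and both healthy parents, jointly genotyped,
with per-allele annotations (population frequency, CADD, consequence,
gene) supplied by an upstream annotation run. The analysis makes three
structural assumptions:

* **Parents are unaffected.** Inheritance-mode logic treats any variant
  pattern compatible with an unaffected carrier parent as recessive-type
  evidence, and a proband-only allele as de novo. Incomplete penetrance
  in a parent would be misread; the package does not model it.
* **Genotypes are hard calls.** There are no genotype likelihoods, so no
  probabilistic de novo calling and no read-backed phasing. Compound-het
  phase is inferred purely from parental transmission, which is the only
  phasing a trio genotype table supports.
* **Variants arrive normalized.** One alternate allele per record,
  already left-aligned; multi-allelic sites are split on reading, with
  alleles equal to the record's alternate counted as carried and every
  other called allele as not carried. This conserves allele observations
  across the split. The annotation join key is the exact
  (chrom, pos, ref, alt); no indel re-normalization is attempted.

## Filter parameters

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 8 (reads) | minimum depth in *every* trio member |
| `af_threshold` | 0.001 | rarity cutoff on reference allele frequency |
| `cadd_threshold` | 20 (PHRED) | DNS cutoff for missense variants |
| `lof_classes` | stopgain, stoploss, frameshift, splicing | LOF set |

Both frequency and CADD comparisons are **strict** ("below 0.001",
"greater than 20"): a variant at exactly the boundary fails. An
undocumented frequency counts as rare — absence from a large reference
population is itself evidence of rarity — while a missing CADD never
makes a variant DNS, because deleteriousness must be positively
evidenced. A missing depth fails the depth filter: the depth rule exists
for specificity, and an unknown depth cannot support a call.

Stoploss is included in the default LOF set; annotation pipelines
disagree on whether it belongs there, so the set is a plain configuration
field. "Splicing" means the annotation's splicing consequence class; no
distance-from-junction logic is applied because none is defined at this
level of annotation.

## Inheritance-mode rules

Calls require non-missing genotypes in all three members; a record with
any missing genotype is silently uncallable rather than guessed.

* **De novo**: proband 0/1 (or hemizygous alt on male X) with both
  parents carrying no alternate allele. A proband 1/1 with 0/0×0/0
  parents would require two independent mutations or a genotyping error;
  it is labeled a Mendelian conflict and excluded, trading recall for
  specificity.
* **AR homozygous**: autosomal proband 1/1 with both parents exactly
  0/1 — the classical segregation pattern. A homozygous parent is not a
  conflict but is not called either.
* **Compound het**: within a (trio, gene), every pair of one paternally
  and one maternally transmitted het. A proband het carried by *both*
  parents is phase-ambiguous and unusable for pairing; excluding it is a
  convention, and the conservative one available without read data.
* **X-linked recessive**: male proband hemizygous alt, father hemizygous
  ref, mother 0/1. Male X genotypes are haploidized on reading (a
  diploid-written het male X call becomes missing — it cannot exist on a
  haploid chromosome). A female X homozygote with a hemizygous-alt father
  and carrier mother is emitted as AR-homozygous-on-X with a warning,
  since the X-linked recessive definition used here is male-hemizygous.
  Male X de novo patterns are labeled de novo, not X-linked recessive.
  Pseudoautosomal regions are not modeled.

Mendelian-inconsistent records are counted, reported, and excluded from
calls. Identical (trio, gene, mode, variant) calls are deduplicated, and
output order is deterministic, so permuting input rows cannot change a
report.

## Gene-level stages

The LOF ∩ disease-list intersection keeps distinct flagged genes with at
least one LOF variant carried by a proband; symbols are compared
upper-cased. LOEUF sorting is ascending with missing scores last and ties
broken by symbol — the constraint scores are continuous metrics, so the
full ranked list is always returned and the 0.6 cutoff (strict) only
flags the prioritized subset. The cilia fraction is a plain proportion,
reported to one decimal.

Only three ACMG evidence codes are auto-assignable from the data this
pipeline carries: PM2 (rare or undocumented, and absent from the supplied
control table), PP3 (CADD strictly above the threshold), and PM1 (inside
a user-supplied critical-domain interval file; without such a file PM1 is
never assigned, because domain knowledge cannot be derived from a variant
table). The evidence combiner implements the full standard rule set
including the benign arms — sets matching both arms, or neither, are
VUS — so externally supplied codes combine correctly too. Published
candidate tables of this design are not always internally consistent in
when they applied PP3/PM2; both auto-assignments are toggleable, but no
single policy reproduces every published evidence string simultaneously.

Per-proband burden counts distinct implicated genes over inheritance-mode
candidates plus retained disease-list LOF genes, so a compound-het pair
counts its gene once; categories are none / single (1) / multiple (≥ 2),
with percentages over all probands to two decimals.

## Allele-count statistics

Cohort allele numbers follow trio arithmetic: `2n` proband and `4n`
parental alleles per autosomal locus; per male proband one X allele, per
female two, and `3n` parental X alleles. The reference side of the 2×2
table uses the database allele count/number when the locus is documented;
otherwise a fallback allele number (defaults 10,904 and 5,998 for the two
bundled database configurations — opaque extract sizes, configurable, not
derivable from the displayed rows).

The test is the one-sided (enrichment in probands) Fisher exact test,
computed as the hypergeometric upper tail with `lchoose` sums in log
space; p-values are reported to four decimals with full precision
retained. Two-sided mode is available behind a flag. Parental alleles can
be pooled into the reference side (`include_parents = TRUE`); the default
is off because the only published p-value with an unambiguous
reproduction path — the de novo row, 1/104 vs 1/19,954 — reproduces
exactly *without* parental alleles (0.0103 vs 0.0102 with them). The
annotated report always displays the parental addition in the published
"AC + parental/(AN + parental)" style regardless of the tested table.
The remaining published rows of that table are not exactly reproducible
under any single test variant we identified (the closest systematic
choice — pooling parents — lands within ~0.0005 of each printed value);
the package therefore asserts printed digits only for the de novo row and
verifies the machinery itself against exact enumeration. The
`inst/extdata/published_allele_counts.tsv` fixture carries the published
counts so every row's computation can be rerun.

The chi-square helper is Pearson without continuity correction and flags
any table with an expected count below 10 as better served by the Fisher
test. No multiple-testing correction is applied anywhere, matching the
post-hoc, hypothesis-generating character of the analysis.

## The synthetic cohort generator

`synthetic_spec()` defaults encode the emulated study conditions: 52
trios with 31 male probands; one planted call per inheritance mode; 48
LOF variants across 46 disease-listed genes, 12 cilia-flagged; a
1786-gene disease list with 134 cilia flags; 100 common background
variants; and a 20/16/16 single/multiple/none burden split. These margins
are mutually consistent by construction — 4 inheritance trios plus 16
single-LOF trios plus 16 two-LOF trios gives exactly 48 LOF variants —
and the generator refuses inconsistent requests instead of adjusting
them.

Design choices worth knowing:

* **Determinism**: each file type draws from its own sub-seeded RNG
  stream, so regenerating with the same seed is byte-identical and
  adding a plant does not reshuffle unrelated draws.
* **Exact margins**: proband sexes and phenotype flags are assigned by
  deterministic count, not Bernoulli draws, so descriptive summaries hit
  their configured margins exactly on every seed.
* **Positions** are sampled collision-free on two synthetic contigs (an
  autosome-like `chr1` and `chrX`); no reference FASTA is involved, and
  REF/ALT are single bases.
* **Background realism is limited**: background variants are common
  (frequency 1.5× the rarity threshold up to 0.5), low-CADD, and
  Mendelian-consistent via transmission sampling, which suffices to make
  the rarity filter's behaviour observable. There is no linkage
  structure, no sequencing-error model, no mosaicism, no population
  stratification, and indels/multi-allelic sites are not planted. Passing
  the planted-truth tests therefore demonstrates correctness of the
  *logic* under clean conditions, not robustness to real-data artifacts —
  the `degrade_cohort()` noise model (genotype dropout, depth collapse,
  injected Mendelian conflicts, each logged cell by cell) probes the
  failure modes the filters are designed to absorb, but only those.

Problem sizes used by the shipped tests: the default 52-trio cohort
(153 variants × 52 trios) for margin checks over 50 seeds, and an
8-trio cohort exercising all four modes for truth-recovery checks over
50 seeds — small enough that the whole suite runs in a couple of
minutes while still covering every planted pattern.

## Known limitations

* No genotype-likelihood models: borderline de novo calls that a
  probabilistic caller would rescue or reject are taken at face value.
* Trio-only phasing: compound hets with a double-carrier parent are
  systematically excluded, an undercount relative to read-backed phasing.
* The X model is binary (haploid male / diploid female) with no
  pseudoautosomal regions and no X-inactivation reasoning.
* ACMG automation is deliberately minimal (PM1/PM2/PP3); every other
  code requires curation and must be supplied externally.
* The Fisher fallback denominators are configuration constants; results
  for database-absent loci are only as meaningful as those extracts.
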