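---
title: "Methods: cohort pharmacogenomic landscape analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort pharmacogenomic landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmscape)
```

# The analysis

`pharmscape` surveys how a sequenced cohort differs from reference
populations at a curated panel of drug-response variants. The pipeline has
five statistical stages, each exposed as ordinary functions and chained by
`run_pipeline()`. This vignette records the model behind each stage, the
parameters that matter, and the design decisions taken where several
reasonable conventions exist.

## Catalog curation

The variant catalog is the unit of input curation: one row per
variant-drug association with a consequence class and an explicit
`is_hla_haplotype` flag.

* **Duplicate key.** Duplicates are defined on
  (chrom, pos, ref, alt, drug-set), not on rsid: rsids can be absent or
  merged across dbSNP builds, while coordinates plus the association set are
  stable. The same locus associated with two different drugs is two
  associations, not a duplicate. `dedupe_catalog()` keeps first occurrences
  and reports the removed count, so curation arithmetic (e.g. an input of
  400 rows collapsing to 161 distinct entries, then 151 after the HLA
  screen) is fully auditable.
* **HLA haplotype rows.** Haplotype-defining entries (multi-locus alleles
  such as classical HLA types) cannot be treated as biallelic sites. They
  are removed purely on the explicit flag. Inferring them from gene names
  would silently misclassify legitimate single-nucleotide variants inside
  the HLA region, so that inference is deliberately not offered.
* **"multiple" associations.** Entries tagged `multiple` match every
  specific drug query by default (`multiple_matches_all = TRUE`), because a
  pan-class association is evidence for each member drug; the flag exists
  because the opposite convention (treating them as their own panel) is also
  coherent for reporting.

## Frequencies from VCF

Parsing relies on `VariantAnnotation::readVcf()`; genotype decoding is done
against the catalog allele:

* Multiallelic records are decomposed per alt allele; a genotype carrying a
  *different* alt counts as dosage 0 for the catalog allele but remains a
  called genotype.
* Half-calls (`./1`) and any genotype containing `.` are treated as missing
  — the conservative reading.
* Missing genotypes reduce AN (pairwise-complete per site); no imputation.
* All samples are treated as diploid, including X/Y loci. This is a known
  limitation: a sex-aware AN would change AF at non-autosomal sites.
* Chromosome dialects (`chr6` vs `6`) are normalized for matching only.

A singleton is AC = 1 on the whole cohort; `rare` means AF strictly below
the `rare_threshold` (default 0.01, the conventional rare-variant cutoff).

## Population comparison

The reference table provides frequencies, but the three tests need counts,
so the reference alt count is reconstructed as `round(AF × AN)` (half-up).
The table therefore must carry AN (a per-run default can be supplied); this
is the one place where the analysis depends on a quantity the reference
source sometimes omits.

Per locus the package computes all three classical tests — Pearson
chi-square, Fisher's exact, pooled two-proportion Z — and adjusts one
configurable *primary* p-value over the whole tested family. The default
primary test is the Z-test: it is the test whose statistic carries the sign
of the frequency difference, and its square is exactly the uncorrected
chi-square (an identity the tests assert to 1e-9). The chi-square
continuity correction defaults off to preserve that identity; Yates
correction is available by flag. The Fisher two-sided p-value uses the
standard point-probability rule with a 1e-7 relative tie tolerance.

Both Benjamini–Hochberg (default) and Bonferroni adjustments are available
because both conventions are common in published frequency-comparison
panels; the adjustment family is all loci tested in the run.

Significance bands follow the three-tier scheme `*` (p < 0.05),
`**` (p < 10⁻²⁰), `***` (p ≤ 10⁻⁵⁰). The published scheme leaves the
intervals (10⁻²⁰, 0.05) and (10⁻⁵⁰, 10⁻⁴⁹) unassigned; the defaults close
them so every p-value gets a band (`ns` above 0.05). Thresholds are
configurable.

Odds ratios use the Haldane–Anscombe 0.5 correction when any cell is zero
(on by default); with the correction disabled a zero-cell table yields a
flagged undefined OR rather than an error, so batch runs complete.

## Linkage disequilibrium

LD is re-implemented rather than delegated to an external tool so the
estimator is fully specified: two-locus haplotype frequencies by EM on
unphased genotype dosage pairs, then

* D = p_AB − p·q,
* D′ = D / Dmax with Dmax = min(p(1−q), (1−p)q) for D > 0 and
  min(pq, (1−p)(1−q)) for D < 0,
* r² = D² / (p(1−p)q(1−q)).

Only double heterozygotes have ambiguous phase; the E-step splits them
between AB/ab and Ab/aB by the current relative haplotype-frequency
products, the M-step re-estimates. Numerical choices:

* **Initialization** at linkage equilibrium (p_AB = p·q): deterministic, no
  seed dependence. The symmetric double-het likelihood ridge (data with
  *only* double heterozygotes) is broken by homozygote classes whenever any
  exist; on the pure ridge the estimate stays at the equilibrium point.
* **Convergence**: max absolute frequency change < 1e-8, cap 1000
  iterations; non-convergence is reported (`converged = FALSE`) with the
  result still returned. The log-likelihood trace is recorded and is
  non-decreasing by EM construction (asserted in tests).
* **Missingness**: pairwise-complete per pair.
* Monomorphic loci give a flagged undefined result (`r2 = NA`), not an
  exception, so `ld_matrix()` runs to completion like batch LD tools.
* No small-sample bias correction is applied to r²; the plain composite
  estimator is reported.

EM allele-frequency margins equal the observed sample allele frequencies by
construction; the tests verify the estimator against direct haplotype
counting (no-double-het data), against truth haplotypes retained by the
simulator, and against a brute-force grid-likelihood oracle at tiny n.

## CAP burden

CAP(g) = 1 − ∏(1 − AF(a))² over the gene's variant set of a class, i.e. the
probability a diploid individual carries at least one variant allele,
assuming inter-locus independence and Hardy–Weinberg proportions. Loci in
LD therefore make CAP an upper-bound approximation — the same assumption the
score's definition makes.

"Variants per participant" has no formulaic definition in common usage, so
the package defines it as the expected variant-allele count per diploid
participant, Σ 2·AF(a) = Σ AC / N. This normalizes observed allele counts
by cohort size, which is the most natural reading of "per participant"; the
per-site alternative Σ AF is available via `per = "site"`. The choice is
isolated in `variants_per_participant()`.

Variants with undefined AF (no called genotypes) are excluded from the
allele set and returned in an excluded-loci report. The diploid exponent is
used for all loci including X-chromosome ones (limitation, as above).

## The synthetic cohort generator

The generator emulates exactly the statistical structure the pipeline
assumes:

* unlinked loci: genotype ~ Binomial(2, AF), i.e. Hardy–Weinberg;
* LD blocks: two haplotypes per sample drawn from the frequencies returned
  by `haplotype_freqs_from_targets(p, q, r)` (D = r·√(p(1−p)q(1−q))),
  with infeasible (p, q, r) combinations rejected with the feasible r
  range; haplotype draws are retained in the truth table so phase-level
  oracles are possible;
* singletons: exactly one heterozygous carrier, chosen uniformly;
* missingness: independent Bernoulli per genotype, applied last.

Default scales in the tests (hundreds to thousands of samples, tens of
loci) are chosen so binomial sampling error is small relative to the
quantities asserted; the emulated study's own scale is ~14,000 genomes and
the generator handles that size, but tests run smaller for speed.

What the generator does **not** emulate: demographic structure and
relatedness, sex chromosomes, locus- or sample-biased dropout, genotyping
error, multi-locus haplotype blocks beyond pairs, and selection. A green
test therefore establishes that the estimators recover the stated
generative model — not that real WGS data meet that model's assumptions.

Reproducibility: the VCF writer uses a fixed `##fileDate` under the
default reproducibility flag, so identical configurations (including seed)
give byte-identical files; the whole pipeline downstream of the VCF is
deterministic.

## Error handling conventions

Schema violations (missing columns, unparseable coordinates) raise
classed conditions (`pharmscape_schema_error`, `pharmscape_row_error`)
naming the offending column or row. Statistical degeneracies inside batch
runs (monomorphic LD, zero-cell OR, zero-called-sample AF) are flagged
results, not exceptions, so one pathological locus never aborts a
landscape run.

## Known limitations

* No sex-aware ploidy; AF and CAP at X/Y loci assume diploidy.
* Reference alt counts are reconstructed from rounded AFs; for very small
  reference AN the rounding is visible in the tests' p-values.
* CAP assumes inter-locus independence within a gene; genes whose variants
  sit in strong LD have overstated CAP.
* The LD module handles pairs only — no multi-locus phasing, pruning or
  decay modelling.
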