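---
title: "Gene-set variant-burden analysis with affburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-set variant-burden analysis with affburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affburden)
```

## The scientific question

Atypical femoral fractures (AFF) are rare, low-trauma fractures of the
femoral shaft associated with prolonged anti-resorptive therapy. Single
pathogenic variants explain only a minority of cases, which motivates a
polygenic view: do affected patients *accumulate* more variants across
bone-related genes than comparable osteoporotic controls? With cohorts of
a dozen to a few dozen exomes, single-variant association is hopeless;
the signal, if any, lives at the gene and gene-set level.

`affburden` implements that comparison as a reusable pipeline over three
aggregation levels:

1. **variant level** — per-site 2×2 (allele) and 2×3 (genotype) Fisher
   exact tests;
2. **gene level** — the same tests on tables pooled over all variants in
   a gene;
3. **gene-set level** — a χ² linear-trend test on binned per-individual
   variant burdens across the whole panel.

Benjamini–Hochberg FDR is applied within each test family, and gene-level
findings can be re-tested against an external reference-panel cohort
(e.g. a 1000-Genomes-style population sample).

## Data model and filtering cascade

Genotypes are held as a variants × samples dosage matrix (0/1/2 copies of
the alternative allele, `NA` for missing). Multi-allelic VCF records are
split into biallelic rows; phased separators are collapsed — the analysis
is entirely unphased. Cohorts are merged by a *full join* over variant
keys `chrom:pos:ref:alt`.

A variant absent from one cohort's call set is imputed as homozygous
reference after the join, not as missing. Both cohorts are assumed to be
called on the same capture, so an uncalled locus usually is reference;
the *shared-presence filter* (below) then removes exactly the sites where
this assumption is untestable. This choice is exposed in the
configuration rather than hard-coded deep in the join.

The cascade runs in a fixed order, and the `filter_report` ledger records
each stage:

1. **region filter** — keep variants inside panel gene intervals. VCF
   positions are 1-based; panel files use BED 0-based half-open
   intervals; the containment rule is `pos − 1 ∈ [start, end)`, applied
   only at this boundary. A variant overlapping two genes stays once in
   the matrix but contributes to both genes' pooled tests.
2. **shared-presence filter** — drop variants with no called carrier in
   one of the two compared groups. Group-exclusive sites are where
   between-cohort calling artifacts masquerade as association signal.
3. **Hardy–Weinberg filter** — drop variants whose exact HWE p-value
   falls below `hwe_alpha` (default 0.05). The test population defaults
   to all case + control samples and can be switched to either cohort.
   Missing genotypes are dropped per site (complete-case per variant).

The ledger identity `n_final = n_after_shared − n_hwe_excluded` holds by
construction and is asserted on every run.

## Exact tests

**HWE.** The package uses the exact conditional test: given the observed
allele counts, the heterozygote count has a known distribution over
configurations of matching parity, and the two-sided p-value sums the
probabilities of all configurations no more probable than the observed
one. At 40 samples the χ² approximation is unreliable; the exact test is
not. Probabilities are computed from log-factorials and normalized in a
single pass; ties at the observed probability are included using a
relative tolerance of 1e-7.

**Fisher 2×2 and 2×3.** The 2×2 test sums hypergeometric tail
probabilities under the probability-mass criterion (the same two-sided
convention as `stats::fisher.test`, which the test suite uses as an
independent cross-check). The 2×3 test is a Freeman–Halton enumeration:
all tables with the observed margins are visited on a grid indexed by the
two columns with the smallest support, with probabilities computed from a
precomputed log-factorial table. This keeps pooled gene-level tables with
thousands of observations tractable (the grid is bounded by the smaller
row margin and the two smallest column margins). Degenerate tables — a
zero row or a single occupied column — return p = 1 with a flag and are
excluded from FDR families rather than erroring.

**Multiplicity.** q-values are BH step-up with monotonicity enforcement
(`stats::p.adjust`). Four families are corrected separately:
variant-allele, variant-genotype, gene-allele, gene-genotype. A family
contains only testable units (genes with at least one surviving variant;
non-degenerate tables) — family sizes are recorded on the result so users
can see the denominator.

## The burden trend test

Per-individual burden defaults to *carrier counting* — the number of
variant sites with dosage ≥ 1 — matching the intuitive "number of
variants in each individual"; total allele counting is available as an
option. Burdens are binned into K equal-width intervals (default K = 5)
spanning the observed range, or user-supplied edges. The trend statistic
is the Cochran–Armitage-type score test on the 2×K table: with group
indicator g and column score s, `chi2 = N·r²` where r is the Pearson
correlation of (g, s) over all N individuals, referred to χ² with 1 df.
Default scores are bin midpoints, which approximate a trend test on the
underlying counts while operating on the binned table; integer ranks or
custom scores are accepted, and the statistic is invariant to affine
score changes. A Wilcoxon rank-sum test on the raw unbinned burdens is
reported alongside as a sensitivity check, not as the headline statistic.

## Replication against a reference panel

Genes significant in *either* the allele or the genotype family enter the
candidate set (published gene lists contain genes significant in only one
of the two, so the union rule is the faithful carry-forward; `"allele"`
and `"genotype"` rules are available). Candidate variants present in at
least one panel individual (dosage ≥ 1) are retained, and the identical
pooled gene-level machinery re-tests case vs panel over that restricted
set, with BH applied within the candidate-gene family only. Two
invariants pin the construction down: replication results depend only on
panel-present variants, and running replication with the discovery
control cohort as the "panel" reproduces the discovery gene-level
p-values exactly.

## The synthetic-data generator

Patient-level exomes from the motivating study are not publicly
deposited, so the package carries a first-class simulator whose defaults
encode the study conditions: 13 cases vs 27 controls, a 107-sample
reference panel, and a 457-gene bone panel (shipped as a synthetic
fixture; the 12 published effect genes carry their reported per-group
allele frequencies and variant counts, the remaining genes get 3 variants
each with base frequencies uniform on [0.05, 0.5]). Defaults further
inject 176 HWE-distorted variants (inbreeding parameterization with
F = 0.6 — one scalar controls the excess-homozygosity departure, and
F = 0 recovers the null), 50 group-exclusive variants per cohort, 2%
missing genotypes, and a 1.06 multiplicative case-frequency shift on
non-effect variants. The burden shift is sized so that the case excess at
13 vs 27 is of the order implied by the published trend test; the
exclusive and missing rates are unreported in the study and were chosen
once as realistic values.

Null genotypes are binomial(2, f) draws per sample (HWE); effect genes
shift the case-group frequency only. Cohort VCFs contain only sites with
at least one called carrier in that cohort, so reading and joining them
exercises the homozygous-reference imputation path. With
`ensure_shared = TRUE` the generator guarantees one called carrier per
cohort for every non-exclusive variant, which makes the simulator's truth
table match the shared-presence filter key-for-key — useful for ledger
tests, at the cost of a slight upward bias in the rarest frequencies. The
canned null and power scenarios therefore switch it off.

What the simulator does *not* emulate: linkage disequilibrium between
sites, haplotype structure, sequencing error and depth-dependent
missingness, population stratification, and genotype-level-only effects
(group-specific departures from HWE at equal allele frequency — several
published genes show exactly that pattern). Passing tests demonstrate
correctness of the machinery under the stated generative model, not
robustness to these real-data features.

## Numerical choices and degenerate inputs

- Tie handling in all exact tests uses a relative tolerance of 1e-7 when
  comparing table probabilities to the observed one.
- Frequencies are fractions internally; the table writers round to
  integer percent (the published table format). Counts round-trip
  bit-exactly; p-values to 6 significant digits.
- Shifted simulation frequencies are clipped to [0.001, 0.999];
  infeasible absolute effect frequencies are a configuration error.
- All-identical burdens collapse into the first bin; explicit bin edges
  that do not cover an observed burden assign it to the nearest terminal
  bin with a warning.
- Variants monomorphic after missing-data removal get HWE p = 1 and are
  retained.

## Test problem sizes

The package's statistical guarantees are exercised at these scales,
chosen to make each check decisive while keeping the default suite quick:
exhaustive exact-test sweeps (all HWE triples with total ≤ 50, all 2×2
tables with N ≤ 60, 1000 random 2×3 tables with N ≤ 40, tolerance
1e-10); 200 null replicates at 13 vs 27 with 2000 variants over 50 genes
for type-I error; 100 replicates at 200 vs 200 with control f = 0.2 vs
case f = 0.4 over 5 variants/gene for gene recovery; 100 replicates with
a 1.2 burden shift and 500 null replicates for the trend test's power and
uniformity.

One property deserves a note: Fisher's exact test is *conservative* by
construction. At 26 vs 54 alleles the attainable significance levels are
coarse, and the measured raw rejection rate under the null sits
noticeably below the nominal 0.05 (the type-I suite documents this).
This is a property of exact conditional inference at small samples, not
an implementation artifact; it implies the variant-level analysis loses
some power but never inflates the false-positive rate.

## Known limitations

- No covariate adjustment, kinship correction, or weighted burden
  kernels (SKAT-style); the design is the published one: exact tests on
  pooled counts.
- The gene-level genotype test pools 2×3 counts across variants
  (stacking variant × sample observations), mirroring the allele
  pooling. Combining per-variant p-values is an alternative the source
  design leaves open; pooling was chosen for symmetry and testability.
- Gene-level families contain only genes with testable variants, not the
  full panel; family sizes are reported so the denominator is explicit.
- The trend test's binning (K, edges, scores) is exposed because the
  published figure does not pin it down; conclusions should be checked
  against the unbinned Wilcoxon sensitivity statistic.
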