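---
title: "Simulating ancestry effects on unrelated-donor HLA match probability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ancestry effects on unrelated-donor HLA match probability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A patient needing an allogeneic stem-cell transplant without a
compatible relative depends on finding an unrelated donor whose HLA
genotype matches theirs at the classical transplantation loci (HLA-A,
-B, -C, -DRB1, -DQB1). Because African populations carry more HLA
diversity than non-African ones, and because admixed registries
under-represent African ancestry, patients with greater African
ancestry face systematically lower match probabilities. hlamatchr
provides a complete, seeded simulation-and-analysis pipeline for
studying that inequity: a synthetic admixed cohort and donor registry
emulating the Brazilian setting, a supervised ancestry estimator, an
indexed registry search engine, and the statistics used to quantify
the effect of self-identification, genome-wide ancestry and
MHC-segment local ancestry on the chance of finding a donor.

```{r setup}
library(hlamatchr)
```

## Matching model

Donor searches compare patient and donor genotypes at three loci sets
— 6/6 (A, B, DRB1), 8/8 (adds C) and 10/10 (adds DQB1) — at two
resolutions. At *low* resolution only the allele-group field is
compared: a patient's `A*34:02` is compatible with any donor variant
of `A*34`. At *medium* resolution both fields must agree: only
variants of `A*34:02` (for example `A*34:02:01G`, compared by its
two-field prefix) are compatible, as is any NMDP-style multiple-allele
code whose expansion contains `A*34:02`. A search with allowance 1
(5/6, 7/8, 9/10) tolerates one mismatched allele in total, counted by
the best pairing of the unordered allele pairs at each locus.

Two rules are deliberate package decisions where registry practice is
heterogeneous and no single convention exists:

* **One-field donor typings at a medium-resolution search never
  match.** A donor typed only as `A*34` cannot be confirmed as
  `A*34:02` without re-typing; treating them as compatible would
  overstate medium-resolution match rates. The conservative rule
  mirrors clinical confirmatory-typing practice.
* **Donors untyped at a required locus are excluded from that
  search** (and reported in `excluded_untyped`) rather than treated as
  wildcards; only the typed subset of a registry is queryable at 8/8
  or 10/10.

The indexed engine (`build_match_index()`) stores, per locus and
resolution, a genotype-key table (zero mismatches) and an allele-key
table (at most one mismatch); exact searches intersect genotype sets
across loci and single-mismatch searches relax one locus at a time.
Donors carrying codes are indexed under every expansion member. A
vectorised naive scan (`find_matches_naive()`) implements the same
contract directly from the compatibility definition and serves as the
oracle the index is tested against.

## The synthetic population

The generator is the package's study design, not a test fixture, and
its defaults are the study conditions.

**Haplotype pools.** Five-locus HLA haplotypes are drawn per ancestry:
an African pool of 400 distinct haplotypes and a European pool of 150,
with haplotype frequencies from symmetric Dirichlet distributions
(concentration 0.6 and 0.5). The African pool spans every allele group
at each locus (15/20/10/10/6 groups at A/B/C/DRB1/DQB1, up to three
protein-level variants each); the European pool uses about half the
groups with at most two variants. This encodes the empirical premise
that African populations have more HLA variability — the African pool
always has more distinct haplotypes and higher expected heterozygosity
— without attempting to reproduce any real frequency catalogue.

**Admixture.** Each individual draws African ancestry `q_AFR` from a
cohort-specific Beta distribution: the default merged sample is
two-thirds a general admixed cohort (mean 0.20, concentration 1.0 — a
long-tailed distribution with many nearly fully European individuals,
as in Brazilian population cohorts) and one-third an SCD cohort (mean
0.52, concentration 5.0, matching the elevated African ancestry of
transplant-eligible sickle-cell-disease patients). Native American
ancestry is drawn as a small fraction (mean 0.061) of the non-African
remainder; it has no dedicated haplotype pool and its MHC segments
draw from the European pool, since Native American effects are outside
the analysis scope.

**MHC local ancestry.** Each of the two MHC haplotypes is African with
probability `q_AFR`, independently. By default the segment delimited
by HLA-A and HLA-DQB1 is inherited as a single block (`mhc_afr` is 0
or 1), reflecting segment-level local-ancestry analysis; an optional
recombination switch splices the five locus blocks with a per-gap
switch probability `1 - exp(-g * L / 4)` derived from `g = 8`
generations since admixture and a segment length of about 0.027
Morgan, producing mixed fractions in fifths. The African MHC *dosage*
(0, 1 or 2 chromosomes) rounds each haplotype's African fraction to
the nearest integer, halves rounding up (toward African) — a fixed
convention required for reproducibility, applied per chromosome
because the class is defined as a count of chromosomes.

**Self-identification.** Census-style labels are an ordered-threshold
readout of African ancestry: `z = q_AFR + noise`, with thresholds 0.20
("White"/"Mixed") and 0.45 ("Mixed"/"Black") and normal noise whose
scale is calibrated by bisection so that the three main categories
explain a target share of the ancestry variance — 0.64 by default for
the merged sample, with 0.31 achievable in the high-admixture (SCD
only) regime. "Indigenous" and "Yellow" labels are sprinkled at small
census-like rates and excluded from contrasts.

**Registry.** 20,000 donors by default, with the published
registry composition (54.64% "White", 23.44% "Mixed", 7.17% "Black",
0.46% "Indigenous", 3.31% "Yellow", 10.97% "NonInformed") and
donor ancestry drawn from self-ID-conditional Betas (means 0.10 /
0.30 / 0.55 for White / Mixed / Black). Typing is heterogeneous: all
donors typed at A, B and DRB1; 30% typed at C and at DQB1; half the
donors typed at low resolution; 20% of medium-resolution donors carry
one NMDP-style code covering their true allele. The real registry's C
and DQB1 coverage is proportionally far smaller, but at a 20,000-donor
desk scale that would leave 8/8 and 10/10 searches with almost no
eligible donors; 30% keeps those searches statistically meaningful
while preserving the qualitative structure (a large drop from 6/6 to
8/8 and 10/10 rates).

**SNP panel.** 2,000 unlinked biallelic SNPs under a Balding–Nichols
model: an ancestral frequency per SNP uniform on (0.05, 0.95), then
per-ancestry frequencies with an F_ST-like divergence of 0.15,
typical of continental-scale differentiation. Dosages are binomial in
the individual's ancestry-weighted frequency.

What the generator does *not* emulate: real HLA allele and haplotype
frequency catalogues, linkage disequilibrium between SNPs, genotyping
or imputation error, coalescent demography, and donor
availability/attrition. Passing tests therefore demonstrate that the
*methods* behave correctly and that the qualitative ancestry gradients
follow from the diversity-and-composition mechanism — not that any
particular real-registry match rate is predicted.

## Ancestry estimation

Given fixed parental allele frequencies, the supervised K = 3 model
treats each dosage as `Binomial(2, sum_k q_k f_kj)` and maximises the
likelihood over the simplex by EM (the supervised special case of the
ADMIXTURE model). The EM update is multiplicative and monotone in the
log-likelihood; iteration stops when the gain drops below `1e-7` or
after 1,000 iterations, frequencies are clamped to
`[1e-6, 1 - 1e-6]`, missing dosages are skipped, and a flat
likelihood (identical frequencies across ancestries) returns uniform
proportions flagged as not converged. Estimates start from uniform
proportions; individuals whose true Native American component is
essentially zero converge slowly along the simplex boundary and may
reach the iteration cap with accurate estimates but `converged =
FALSE` — the flag reports the stopping rule, not estimate quality. On
the default panel the estimator recovers African ancestry with RMSE
below 0.03. The paper-scale machinery for real arrays (LD pruning,
bootstrap standard errors) is out of scope because the synthetic SNPs
are generated unlinked.

African-ancestry quartiles are rank-based with stable tie-breaking
(Q1 least African); in the pipeline they are computed from the
*estimated* ancestry, mirroring an analysis in which true ancestry is
unobservable.

## Statistics

* **Grouped match rates**: share of patients with at least one donor,
  by self-ID, quartile, MHC dosage or SCD status.
* **Odds ratios**: closed-form 2x2 cross-product with a Woolf CI and
  Wald p-value, cross-checked against a logistic fit (`stats::glm`,
  IRLS); zero cells get the Haldane–Anscombe 0.5 correction and skip
  the logistic cross-check. Wald p-values are reported (the choice
  between Wald and likelihood-ratio is unstated in common practice;
  Wald matches the closed form).
* **Percent decrease** in the chance of a match, `100 (r_ref -
  r_cmp) / r_ref`, rounded half-away-from-zero to integer percent.
  With matched group sizes the larger group is subsampled to the
  smaller one's size and rates averaged over 200 seeded repetitions
  before the ratio — repeated subsampling is the package's protocol
  choice (a single subsample is available for sensitivity) because it
  removes subsample luck while keeping the estimator unbiased.
* **Donor composition**: per patient, the frequency of each donor
  self-ID category among their matches; per group, the unweighted mean
  of the per-patient vectors (the average of individual averages,
  which weights patients equally instead of pooling donors).
* **Donor-count comparison**: two-sided Mann–Whitney U among patients
  with at least one match (normal approximation with tie correction
  for groups of 20 or more, exact below).
* **Two-proportion z test** with pooled variance, for the SCD
  contrast.
* **Sibling match probability** `1 - (3/4)^k` for `k` siblings, from
  Mendelian inheritance of parental haplotypes.

## Pipeline, sizes and reproducibility

`run_pipeline()` chains simulate → ancestry → match → analyze →
report, writing CSV artifacts with schema-version headers, a stats
JSON, a markdown report and a manifest of MD5 checksums. One global
seed is expanded into independent per-stage streams, so re-running a
stage or adding one never perturbs another stage's draws; identical
config and seed give identical artifact checksums. The default run —
2,000 patients, 20,000 donors, all twelve search specifications —
completes in a few minutes on one CPU; unit tests use scaled-down
cohorts (hundreds of patients, hundreds to a thousand donors), which
are large enough for the seeded gradient checks to separate groups by
several standard errors.

```{r, eval = FALSE}
cfg <- sim_config(seed = 20260101)
manifest <- run_pipeline(cfg, "hlamatchr_run", verbose = TRUE)
```

## Numerical choices and degenerate inputs

* Canonical allele formatting zero-pads fields (`A*07:02`); parsing
  accepts unpadded input.
* G-suffixed names are compared by their two-field prefix; full
  G-group equivalence tables are out of scope.
* Quartile and dosage boundaries: ties broken by stable input order;
  degenerate (collapsed) quartile boundaries are flagged rather than
  silently accepted.
* Rounding: rates to one decimal, percent decreases to integer
  percent, both half-away-from-zero, matching printed-report
  precision; MHC dosage halves round up.
* Degenerate statistics (a group with no variation in outcome, an
  empty contrast cell in a tiny run) are reported as `NA` rows in the
  pipeline's tables instead of aborting the run.
* The printed registry composition sums to 0.9999; compositions are
  renormalised when within 1e-3 of 1 and rejected otherwise.

## Known limitations

The synthetic pools are not real HLA frequency data, so absolute match
rates are calibrated only qualitatively; the block-inheritance default
makes every MHC haplotype purely African or European unless
recombination is switched on; registry typing resolution is per-donor
rather than per-locus (one knob for historical heterogeneity); and the
search engine does not model a screening workflow in which
higher-resolution typing is conditioned on an initial low-resolution
match, nor donor availability after identification.
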