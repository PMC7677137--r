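# hlamatchr

Simulation and analysis of HLA match probability in unrelated stem-cell
donor registries for admixed populations.

## The problem

Allogeneic hematopoietic stem-cell transplantation requires a donor
whose HLA genotype matches the patient's at the classical loci
(HLA-A, -B, -C, -DRB1, -DQB1). When no relative is compatible —
each sibling has only a 1/4 chance of being HLA-genoidentical, so
with *k* siblings the probability that at least one matches is
`1 − (3/4)^k` — the search moves to volunteer registries. Registry
searches compare genotypes at three loci sets (6/6 = A, B, DRB1;
8/8 adds C; 10/10 adds DQB1), at low (one-field, allele group) or
medium (two-field, protein) resolution, optionally allowing a single
mismatched allele (5/6, 7/8, 9/10).

African populations carry more HLA diversity than non-African ones,
and admixed registries under-represent African ancestry, so patients
with greater African ancestry — measured by self-identification,
genome-wide ancestry proportions, or the local ancestry of the MHC
segment itself — have systematically lower chances of finding a
donor. `hlamatchr` is a seeded, end-to-end pipeline for studying this
inequity on synthetic data emulating the Brazilian setting, for
population geneticists and registry analysts. It provides:

* an HLA nomenclature layer: parsing, canonical formatting,
  resolution truncation, G-group prefixes, NMDP-style multiple-allele
  codes, and allele-level mismatch counting;
* a synthetic-population generator: ancestry-specific haplotype pools
  with higher African diversity, admixed cohorts (including a
  sickle-cell-disease cohort), census-style self-identification
  calibrated to a target ancestry–label R², and a registry with
  heterogeneous typing;
* a supervised ancestry estimator: the K = 3 binomial likelihood
  `g_j ~ Bin(2, Σ_k q_k f_kj)` maximised over the simplex by EM
  (compiled core), plus African-ancestry quartiles and the African
  MHC dosage classes 0/1/2;
* an indexed match engine verified against a naive scan, and
* the analysis statistics: grouped match rates, odds ratios (2×2
  closed form cross-checked by logistic regression),
  matched-subsample percent decreases, donor-composition averages,
  Mann–Whitney donor-count tests, and the two-proportion z test.

## Worked example

Simulate a 600-patient cohort against a 4,000-donor registry and
quantify the effect of African MHC ancestry on the chance of a 6/6
low-resolution match:

```r
library(hlamatchr)

cfg <- sim_config(seed = 42,
  admixture = list(cohorts = list(
    general = list(n = 400, afr_mean = 0.20, afr_conc = 1.0, scd = FALSE),
    scd     = list(n = 200, afr_mean = 0.52, afr_conc = 5.0, scd = TRUE))),
  registry = list(n = 4000))

pools    <- generate_pools(cfg)
cohort   <- generate_cohort(cfg, pools)
registry <- generate_registry(cfg, pools)

matches <- batch_match(cohort, registry,
                       specs = list(search_spec("6/6", "low", 0),
                                    search_spec("10/10", "low", 0)))
cohort <- assign_groups(cohort)  # adds quartile and mhc_dosage

rates <- grouped_match_rates(matches, cohort, "mhc_dosage",
                             loci_set = "6/6")
rates
#> # A tibble: 3 × 5
#>   grouping   group     n n_with_match   rate
#>   <chr>      <chr> <int>        <int>  <dbl>
#> 1 mhc_dosage 0       338          292 0.864
#> 2 mhc_dosage 1       169           37 0.219
#> 3 mhc_dosage 2        93            4 0.0430

percent_decrease(rates$rate[rates$group == "0"],
                 rates$rate[rates$group == "2"])
#> Percent decrease: 95% (86.39% -> 4.30%)

sibling_match_prob(1:4)
#> [1] 0.2500000 0.4375000 0.5781250 0.6835938
```

Patients with two African MHC haplotypes (dosage 2) find a donor in
4.3% of searches versus 86.4% for dosage 0 — the simulated analogue of
the match-rate gradient in admixed registries; the `sibling_match_prob`
series is the Mendelian reference for family searches. The full
pipeline (`run_pipeline()`, or `Rscript scripts/run_pipeline.R`) runs
simulate → ancestry → match → analyze → report from one config and
seed, writing CSV artifacts, a stats JSON, a markdown report and a
checksum manifest.

## Documentation

The methods vignette
(`vignettes/registry-match-simulation.Rmd`) describes the matching
model, the generator's design and defaults, the estimator, the
statistics, numerical conventions, and known limitations.
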