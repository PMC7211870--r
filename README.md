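# badgerabc

Demographic inference of badger introductions from Great Britain into
Ireland.

Irish badgers (*Meles meles*) carry a mixed genetic heritage: island-wide
mitochondrial haplotypes point to an Atlantic-fringe origin, while badgers
in the northeastern and southeastern counties are British-like at nuclear
microsatellites. `badgerabc` implements the analysis chain used to date
and characterise that British-like sub-population: did it arise by an old
divergence within Ireland, or by a recent, human-mediated introduction of
British animals that admixed with residents?

The package provides:

* **Descriptive population genetics** for diploid microsatellite data in
  GENEPOP format: allele numbers, Nei's unbiased gene diversity, observed
  heterozygosity, Weir–Cockerham *F*<sub>IS</sub> and pairwise θ
  (*F*<sub>ST</sub>) with permutation tests, Jost's *D*, the
  Garza–Williamson *M*-ratio, Goldstein's (δμ)², allele-frequency *Z*
  tests, and mitochondrial diversity summaries.
* **Bayesian-clustering post-processing**: Evanno's ΔK from replicated
  log-likelihood tables and the *Q* ≥ 0.85 membership threshold that
  defines the "native" versus admixed split.
* **Haplotype assignment** of 214 bp control-region sequences against a
  named reference catalogue, with per-region frequency tables.
* **Coalescent simulation** (Rcpp) of microsatellite loci under a
  generalized stepwise mutation model and two demographic scenarios —
  divergence versus admixture — relating the British population (pop 1),
  the native Irish sub-population (pop 2) and the British-like Irish
  sub-population (pop 3).
* **Approximate Bayesian computation**: rejection on 15 summary
  statistics, scenario choice by weighted logistic regression, parameter
  posteriors by local-linear regression adjustment, and a PCA
  posterior-predictive model check.
* **A synthetic-data generator** that reproduces the study's sampling
  design (91/414/40 individuals, 14 loci, published haplotype
  frequencies), so the whole pipeline runs and is tested without any
  data download.

The central model: under the admixture scenario, pop 3 is founded at time
*t*<sub>a</sub> ∈ [10, 500] generations before present by drawing a
fraction *r*<sub>a</sub> of its ancestry from Britain, with the deep
British–Irish split at *t*<sub>d</sub> ∈ [500, 15 000] generations;
effective sizes are uniform on [10, 15 000] (GB) and [10, 10 000] (Irish).
Times convert to years at six years per badger generation.

## Worked example

A reduced version of the full analysis (small sample sizes and reference
table so it runs in seconds):

```r
library(badgerabc)

design <- study_design(n_gb = 30, n_irish1 = 60, n_irish2 = 20, seed = 42)
ds <- generate_dataset(design)
population_summary(ds$genotypes)
#>   population  N   Na    He    Ho      Fis
#> 1         GB 30 14.9 0.845 0.843  0.00272
#> 2     Irish1 60 14.1 0.799 0.818 -0.02347
#> 3     Irish2 20 12.1 0.822 0.825 -0.00354

obs <- compute_observed_summaries(ds$genotypes, c("GB", "Irish1", "Irish2"))
specs <- list(scenario_spec("divergence"), scenario_spec("admixture"))
ref <- build_reference_table(specs, 2000, design$sample_sizes, seed = 42)
rej <- abc_rejection(ref, obs, tolerance = 0.05)
scenario_posterior(rej$accepted, rej$distances, obs)
#>   scenario posterior  lower upper
#> 1        1     0.056 0.0046 0.433
#> 2        2     0.944 0.5674 0.995

acc2 <- rej$accepted$scenario == 2
pp <- parameter_posterior(rej$accepted[acc2, ], rej$distances[acc2], obs)
pp$summary
#>   parameter     mean   median     q025     q975
#> 1        N1 9739.759 1.06e+04 3886.959 1.39e+04
#> 2        N2 5505.289 5.41e+03 1987.809 8.88e+03
#> 3        N3 6297.515 6.53e+03 1814.879 9.16e+03
#> 4  t_recent  128.245 9.43e+01   17.329 4.77e+02
#> 5    t_deep 2907.061 2.50e+03  940.123 8.58e+03
#> 6        ra    0.314 2.85e-01    0.131 7.22e-01

generations_to_years(94.3)
#> [1] 565.8
```

Read: the data (generated under admixture with *t*<sub>a</sub> = 110
generations and *r*<sub>a</sub> = 0.25) select the admixture scenario with
posterior 0.94, and date the event at a median ≈ 94 generations ≈ 570
years before present with ≈ 29% British contribution — recovering the
truth within the posterior uncertainty.

Real data enter through `read_genepop()` / `read_fasta()` /
`read_metadata()`, or the column-mapping hook `as_genotype_table()`; the
`run_*()` pipeline commands (and `inst/cli/badgerabc-cli.R`) wrap the same
functions with file output and provenance logs.

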