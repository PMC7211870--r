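---
title: "Dating the introduction of British badgers into Ireland: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating the introduction of British badgers into Ireland: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(badgerabc)
```

## The scientific question

Irish badgers (*Meles meles*) carry a mixed genetic signal: island-wide
mitochondrial haplotypes point to an Atlantic-fringe (Iberian/Scandinavian)
origin, while a geographically restricted subset of animals in the
northeastern and southeastern counties is, at nuclear microsatellites,
strikingly British-like.  The question this package addresses is *when* and
*how* that British-like Irish sub-population arose: by an old split within
Ireland, or by a recent, human-mediated introduction of British animals that
admixed with residents.

`badgerabc` implements the full analysis chain for that question:

1. descriptive population genetics of a three-population design — a British
   sample (pop 1), a "native" Irish sub-population (pop 2) and a British-like
   Irish sub-population (pop 3);
2. post-processing of Bayesian clustering output (Evanno's $\Delta K$, and the
   $Q \ge 0.85$ membership threshold that defines the native/admixed split);
3. mitochondrial control-region haplotype assignment and frequencies;
4. coalescent simulation of microsatellite data under two competing
   demographic scenarios, and approximate Bayesian computation (ABC) for
   scenario choice and parameter dating.

## The two demographic scenarios

Both scenarios relate the three sampled populations backwards in time, with
diploid effective sizes $N_1, N_2, N_3$:

* **Scenario 1 — divergence.**  Pop 3 splits from pop 2 at a recent time
  $t_1$; pops 1 and 2 derive from a common ancestral population at a deep
  time $t_2$.
* **Scenario 2 — admixture.**  Pop 3 is founded at a recent time $t_a$ by an
  admixture event in which a fraction $r_a$ of its ancestry comes from the
  British pop 1 and $1 - r_a$ from the Irish pop 2; pops 1 and 2 split at a
  deep time $t_d$.

Prior bounds (uniform, independent): $N_1 \in [10, 15\,000]$,
$N_2, N_3 \in [10, 10\,000]$; recent time $\in [10, 500]$ generations before
present (gbp); deep time $\in [500, 15\,000]$ gbp with the recent time
strictly earlier; $r_a \in (0,1)$.  Times convert to years at a badger
generation time of 6 years (`generations_to_years()`), so the recent-event
prior spans roughly 60–3000 years before present and the deep split reaches
back past the Last Glacial Maximum.  Both scenarios have prior probability
one half.

### The coalescent simulator

`simulate_locus()` (Rcpp) runs a continuous-time Kingman coalescent: within a
population of diploid size $N$, $k$ lineages coalesce at rate
$k(k-1)/(4N)$ per generation.  At the recent event, pop-3 lineages move into
pop 2 (divergence) or independently into pop 1 with probability $r_a$
(admixture); at the deep event the remaining populations merge.  We use the
Kingman approximation rather than generation-by-generation Wright–Fisher
because all prior $N \ge 10$ and the approximation error is negligible at
desk scale.  The ancestral population is given size $N_2$: the analysis
design names no separate ancestral-size parameter, so the ancestral epoch
inherits the native Irish size (an explicit, overridable convention,
`scenario_spec(n_anc = )`).

Microsatellite mutation follows a generalized stepwise model (GSM):
mutations are Poisson on branches with per-locus rate $\mu_\ell$, and each
mutation moves the allele by $\pm G$ motif steps with
$G \sim \mathrm{Geometric}(P_\ell)$ (so $P_\ell \to 1$ recovers the strict
stepwise model).  Allele states live on a bounded ladder of 40 contiguous
states with reflecting boundaries, rooted at the ladder midpoint — the
standard device that prevents unbounded drift of fragment sizes.  At
moderate diversity the ladder is effectively infinite; its compression
becomes measurable only as diversity saturates (see *Limitations*).

Mutation hyper-priors follow the standard microsatellite defaults: the
across-locus mean rate $\bar\mu \sim U(10^{-4}, 10^{-3})$ per generation
with per-locus $\mu_\ell \sim \Gamma(\text{shape }2, \text{mean }\bar\mu)$
truncated to $[10^{-6}, 10^{-2}]$, and mean geometric parameter
$\bar P \sim U(0.1, 0.3)$ with $P_\ell \sim \Gamma(2)$ truncated to
$(0.01, 0.9)$.  These are configurable (`default_priors()`), since the
analysis tool's manual defaults are versioned.

## Summary statistics

Observed and simulated datasets are reduced to the same fixed 15-statistic
vector (`summary_names()`): per population the across-locus mean allele
number, mean genic diversity (Nei's unbiased
$\tfrac{2n}{2n-1}(1-\sum p_i^2)$) and mean Garza–Williamson
$M = k/(r+1)$; plus Weir–Cockerham $\hat\theta$ and Goldstein's
$(\delta\mu)^2$ for the three population pairs in the fixed order
(1,2), (1,3), (2,3) — the pairing order is a convention that simply has to
be identical on both sides, and is.

The descriptive layer exposes the same estimators individually, plus Jost's
$D$ (Nei–Chesser bias-corrected $H_S$, $H_T$; per-locus
$D_{est} \cdot k/(k-1)$ averaged arithmetically across loci, with a
harmonic-mean option since the across-locus summary used by common
implementations differs), Weir–Cockerham $f$ ($F_{IS}$), two-proportion
$Z$ tests of allele frequencies with Bonferroni correction, and
mitochondrial diversity summaries (haplotype counts, segregating sites,
pairwise-difference moments, and Hudson-style sequence
$F_{ST} = 1 - \bar\pi_W/\bar\pi_B$, chosen because it requires no
substitution model).  Multi-locus $F$-statistics sum variance components
over alleles and loci before taking the ratio, matching the behaviour of
the classical F-statistics programs rather than averaging per-locus ratios.

## ABC: rejection, scenario choice, parameter estimation

`abc_rejection()` standardizes each summary by its reference-table standard
deviation (MAD available as an option) and retains the closest 1% of
simulations by Euclidean distance.  `scenario_posterior()` fits a weighted
logistic regression of the scenario indicator on the centred summaries
among accepted rows — Epanechnikov weights in distance, bandwidth equal to
the maximum accepted distance — and evaluates it at the observed point; the
95% CI is the delta-method interval on the linear predictor mapped through
the inverse logit (the original analysis reports a CI without stating its
construction; the delta-method interval is the natural by-product of the
logistic fit).  `parameter_posterior()` applies the classical local-linear
adjustment: each parameter is mapped by a bounded logit onto its prior
interval (guaranteeing adjusted draws respect the prior support), regressed
on the centred summaries with the same weights, shifted to the origin, and
back-transformed; reported are weighted mean, median and 2.5%/97.5%
quantiles.  A singular regression falls back to unadjusted weighted
quantiles with a warning.  `pca_model_check()` reproduces the standard
posterior-predictive check: principal components are fitted on standardized
prior-predictive summaries, all clouds are projected, and the observed
point is flagged inside/outside the central 95% of the posterior-predictive
cloud (Mahalanobis distance in the leading components against a
$\chi^2_{0.95}$ threshold).

Inference uses microsatellite summaries only.  The combined
microsatellite-plus-mtDNA model was rejected in the source analysis as
failing its own model check, so mitochondrial sequence simulation is
deliberately out of scope here and the mtDNA layer is descriptive.

## The synthetic-data generator

No genotype data are redistributed with this package, so
`generate_dataset()` produces a *study-shaped stand-in*: 91 British, 414
native-Irish and 40 British-like-Irish diploids at 14 loci, simulated under
the admixture scenario at the posterior-scale point parameters
($N_1 = 6710$, $N_2 = 4240$, $N_3 = 5530$, $t_a = 110$ gbp, $r_a = 0.25$,
$t_d = 1820$ gbp).  The generator fixes the mutation hyper-parameters at
the midpoints of their priors ($\bar\mu = 5\times10^{-4}$, $\bar P = 0.22$)
— chosen once as the neutral representative of the default mutation model,
not fitted to anything.  Mitochondrial haplotype labels are drawn
independently per individual from the published island-wide percentage
tables (Ireland: H9 71.1, H2 18.5, H15 4.9, H4 3.8, H14 0.4, H20 0.2,
H1 0.2; Britain: H1 57.1, H4 40.6, H9 2.2; renormalized), and realized as
sequences from a deterministic synthetic 214 bp reference catalogue
(`synthetic_haplotype_catalogue()`) in which, as in the real catalogue, H20
differs from H9 at exactly one site.  County metadata place sub-population
2 in northeastern/southeastern counties.

What the stand-in does *not* emulate matters for interpreting tests run on
it: there is no missing data, no genotyping error, no within-population
inbreeding or spatial substructure (so $F_{IS} \approx 0$ by construction,
where the real Irish sample shows 0.14), the mtDNA labels are decoupled
from the nuclear genealogies, and its diversity level reflects the default
mutation model at the published effective sizes rather than the real data's
(the real study's lower heterozygosities imply a mutation-rate/size
combination below those midpoints).  Consequently, checks that pass on the
stand-in validate the *machinery* — estimator correctness, simulator
calibration, inference recovery — and not agreement with the published
descriptive values, which require the original supplementary data.

## Numerical choices and degenerate inputs

* Rejection ties at the cutoff break by row order; accepted counts are
  exactly $\lceil \text{tolerance} \times n \rceil$.
* Zero-variance summary columns are dropped from distances (warning);
  monomorphic datasets yield zero diversity, $M = 1$ and flagged,
  zero-substituted $\hat\theta$.
* Monomorphic loci are excluded from $F$-statistic component sums (they
  carry no information); loci untyped in a population are excluded from
  that population's means only.
* Evanno's $\Delta K$ pairs replicates by index when replicate counts match
  across $K$, otherwise uses the second difference of means; a zero
  replicate standard deviation flags that $K$ as undefined.
* The $Q \ge 0.85$ threshold is inclusive: "native" means at least 85%
  native-cluster membership, the complement having strictly more than 15%
  foreign heritage.
* Reference-table construction expands one master seed into per-chunk seeds
  ($\text{seed} + 1000003 \cdot \text{chunk} \bmod 2^{31}-1$), making the
  table chunk-order invariant, reproducible, and resumable from a partially
  written file.

## Problem sizes

The package's own validation uses desk-scale versions of the full design
(one million simulations per scenario in the original): the test-suite ABC
run uses 10 000 simulations per scenario at the full 91/414/40 sampling
design, scenario-recovery experiments use 8 000 per scenario at 30/30/30,
and the credible-interval coverage experiment uses a 20 000-row reference
table at 20/20/20 with 100 pseudo-observed replicates.  These sizes were
chosen so the Monte-Carlo error of each check is small relative to the
property being asserted.  `scripts/acceptance.R` re-runs the full chain at
10 000 simulations per scenario.

## Known limitations

* The bounded 40-state ladder slightly compresses diversity relative to the
  unbounded stepwise model; at $\theta = 2$ the equilibrium gene diversity
  sits a few thousandths below the closed form $1 - 1/\sqrt{1+8N\mu}$ (the
  property test allows 0.01).
* The scenario-probability CI is a delta-method interval, degenerate when
  rejection retains a single scenario.
* Sequence trimming in haplotype assignment is end-anchored window search,
  not a full alignment; indel-bearing reads need external alignment first.
* The clustering MCMC itself (and CLUMPP/DISTRUCT, DAPC) is out of scope:
  this package consumes its text outputs.
* `N` in the per-population summary table is the mean number of typed
  individuals per locus, hence fractional under missing data — the
  convention matching the published table.
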