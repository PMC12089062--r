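---
title: "Detecting selection on a color polymorphism from road mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection on a color polymorphism from road mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roadcline)
```

## The question and the estimand

Eastern gray squirrels (*Sciurus carolinensis*) occur as two discrete coat
color morphs, gray and melanic, and the melanic morph is typically more
frequent near city centers. If vehicle collisions remove the two morphs at
different rates — the gray morph matches pavement and is detected later by
drivers — then road mortality is a source of natural selection, and the
signature is a *difference between two clines*: the proportion melanic among
living squirrels as a function of distance to the city center, versus the
same proportion among road-killed (dead-on-road, DOR) squirrels. This
package estimates both clines, their posterior difference with pointwise
95% credible intervals, morph-specific effects of road and landscape
features on mortality risk, and the complementary contingency statistics
for large citizen-science photo collections.

## The living-squirrel model

Living squirrels are observed imperfectly, so the living cline is estimated
with a hierarchical N-mixture model integrating two data streams collected
at `i = 1..S` sites:

* **Point counts** `C_ijk`: the number of morph-`k` squirrels seen during
  survey `j`;
* **Camera-trap detection histories** `D_ijk`: daily binary records of
  whether morph `k` was photographed (available at a subset of sites).

The latent state is the pair of morph abundances at each site. Total
abundance follows a log-linear cline and the melanic share a logit-linear
cline, both in *standardized* distance to the city center:

```
N_total_i ~ Poisson(lambda_i),            log(lambda_i)   = beta0_N + beta1_N * d_i
N_mel_i   ~ Binomial(N_total_i, p_mel_i), logit(p_mel_i)  = beta0_M + beta1_M * d_i
```

Conditional on the latent abundances, counts are binomial draws with
per-individual detection probability quadratic in standardized daily
temperature on the logit scale (`logit p = a0_k + a1_k t + a2_k t^2`,
morph-specific), and a camera day records the morph with probability
`p* = 1 - (1 - p)^N`, the chance of photographing at least one of the `N`
individuals present.

**Marginalization.** Rather than sampling the latent abundances, the
package integrates them out analytically using Poisson thinning: splitting
`N_total ~ Poisson(lambda)` binomially yields *independent* morph
abundances `N_mel ~ Poisson(lambda p_mel)` and
`N_gray ~ Poisson(lambda (1 - p_mel))`. Each site-by-morph likelihood term
is then a one-dimensional sum over the latent count, truncated at the
smallest `N` whose Poisson upper tail is below `1e-12` (with a floor of
50, and never below the largest observed count). This makes the likelihood
deterministic and fast; the equivalence with the joint
Poisson-then-Binomial formulation is not assumed but *tested*, by brute-force
enumeration over both latents on small datasets (to 1e-8), and the
marginal itself is tested against direct enumeration (to 1e-10). The sum
is implemented in C++ because it sits inside the sampler's innermost loop.

## The DOR model and the contrast

The morph of each road-killed squirrel is a Bernoulli outcome with
`logit P(melanic) = alpha_D + beta_D * d`, fit separately from the living
model — the datasets are independent and share no parameters. Each model
standardizes distance against its own data and stores the constants with
the fit, so curves are always evaluated with the right back-transformation.

For the contrast, every posterior draw-pair produces a living curve, a DOR
curve, and their pointwise difference over a distance grid (default 100
points over 0.93–11.3 km, the survey gradient); the curves are summarized
by the mean and 2.5/97.5 percentiles. Draws are pooled across chains,
truncated to the shorter posterior, and paired by index — with independent
fits any pairing is valid, and index pairing is reproducible. A positive
difference means the melanic morph is underrepresented among roadkill
relative to the living population at that distance.

## Posterior computation

The sampler is a self-contained blocked adaptive random-walk Metropolis.
Default priors are weakly informative: Normal(0, 10) for slope and
curvature coefficients, with uniform constraints on interpretable means —
mean site abundance `exp(beta0_N) ~ U(0, 100)`, mean proportion melanic and
mean detection probabilities `~ U(0, 1)` on their natural scales (Jacobians
handled internally). All are configurable through `prior_spec()`.

Three features matter for this posterior, whose difficult directions are
the abundance and detection intercepts: more squirrels with lower
per-individual detectability explain the same data almost as well, which
produces both a strong negative posterior correlation and — on many
datasets — several genuinely distinct local modes (one per way of
splitting each morph's counts between abundance and detectability).

* **Multi-start Laplace approximation.** Before sampling, the fitting
  wrappers map the posterior: many cheap simplex runs from prior draws
  locate basins of attraction, each distinct basin is polished
  (Nelder-Mead then BFGS), and targeted probes restart the optimizer from
  the best mode with each probability-scale intercept shifted, hunting
  the reflection modes of the abundance/detection trade-off. Every
  retained mode gets an inverse-Hessian covariance and a Laplace mass
  weight. Chains start distributed across the modes (jittered by the
  local covariance), and the best mode's covariance — scaled by
  `2.38/sqrt(d)` with a scalar step size tuned toward ~23% acceptance —
  seeds the random-walk proposal.
* **Mode-jumping mixture proposals.** When several modes were found, a
  fraction of iterations (10%) propose an independent draw from a Gaussian
  mixture over the modes (two components per mode, at the Laplace scale
  and 3x it, so tails stay covered), accepted with the standard
  Metropolis-Hastings correction for the mixture density. Random walks
  cross between well-separated modes only rarely; the independence kernel
  hops them in one step, and is exact regardless of how well the mixture
  approximates the posterior.
* **Frozen adaptation.** Step-size tuning (and, for long adaptation
  phases, re-estimation of the proposal covariance from the chain
  history) stops when the adaptation phase ends, so the recorded chain is
  a valid Markov chain with the posterior as its stationary distribution.

The default protocol is 3 chains × (20,000 adaptation + 12,000 iterations),
discarding 1,000 as burn-in and thinning by 10 — retaining 1,100 draws per
chain (3,300 total; note that this protocol's arithmetic retains 3,300, not
3,000). Routine synthetic analyses and the package's own recovery tests
use a reduced protocol (2 chains × (2,500 adaptation + 3,200 iterations),
thin 5), which the recovery experiments show is sufficient for the cline
slopes at the field design.

Convergence is monitored with the split-chain Gelman-Rubin statistic
(each chain halved, so within-chain drift also registers), threshold 1.1.
Non-convergence is treated as a first-class outcome: the pipeline flags it
in its manifest, and the package's recovery tests re-run a non-converged
replicate once with a longer protocol (3 × (5,000 + 12,000)) and report
any replicate that still fails rather than silently accepting it.

Summaries are the posterior mean and 2.5/97.5% quantiles, pooled across
chains, with linear interpolation between order statistics (R's default
type-7 rule) fixed as the package-wide quantile convention.
`standardize()` uses the n−1 denominator for the SD.

## Mortality-risk regressions on a causal DAG

Whether road features cause morph-specific mortality is confounded by
urbanization: the same gradient that drives traffic and speed limits also
drives squirrel abundance and forest structure. The package encodes the
hypothesized causal structure as an explicit DAG
(`default_squirrel_dag()`): distance to the city center drives human
population density, which drives building density, speed limits, traffic,
and (with forest cover) local morph abundance; building density suppresses
forest cover, which drives fragmentation, which drives habitat split (the
difference in forest cover across road sides); above-ground crossing
structures come from building density (utility lines) and forest cover
(overhanging branches); mortality risk responds directly to speed,
traffic, crossings, habitat split, and morph abundance. The shipped edge
list is a reconstruction from the study-system literature, deliberately
editable (two-column CSV, `read_dag_csv()`).

`backdoor_sets()` enumerates all minimal covariate sets satisfying the
backdoor criterion — sets of non-descendants of the exposure that
d-separate exposure from outcome in the graph with the exposure's outgoing
edges removed. d-separation uses the moralized ancestral graph; tests
verify it against an independent path-enumeration oracle on random DAGs,
and the minimal sets against exhaustive subset enumeration. On the default
DAG the adjustment covariates required across the four exposures are
population density, forest cover, and fragmentation.

`estimate_risk_effect()` then fits the outcome (DOR location vs matched
reference location) on the exposure plus the first observed minimal
adjustment set, by **Firth mean-bias-reduced logistic regression**:
modified-score iterations on hat-value-adjusted responses maximizing
`l(beta) + 0.5 log det I(beta)`. The Jeffreys penalty keeps estimates
finite under complete separation — a real concern at n = 141 cases — and
removes leading-order mean bias. Population density, fragmentation, and
traffic are log-transformed before fitting so the log-odds can be linear
in them. Wald standard errors come from the inverse Fisher information;
penalized-likelihood-ratio intervals are intentionally out of scope.

## Citizen-science contingency statistics

For range-wide photo collections the package provides the classical
toolkit on 2×2 morph × dead/alive tables: expected counts under
independence, Pearson's chi-square with the Yates continuity correction
(clamped at `min(0.5, min|O-E|)`, the convention of R's `chisq.test`, so a
perfectly independent table scores exactly 0), Cramér's V computed from
the uncorrected statistic, and Agresti-Coull binomial intervals for
per-morph DOR proportions. `filter_classifications()` applies the standard
crowdsourcing screen (≥10 classifiers, ≥80% agreement) when per-image vote
counts are available; the analysis functions accept already-filtered
totals.

## The synthetic-data generator

Every stage is testable without field data because `simulate_*` functions
generate data with exactly the model structure above, returning the
generating truth alongside:

* `simulate_squirrel_landscape()` — sites uniform over 0.93–11.3 km
  (covering the curve domain evenly; the study does not dictate spacing),
  Poisson/Binomial latent abundances from the cline parameters.
* `survey_design()` + `simulate_observations()` — defaults fix each site
  at the study's design medians (5 point-count surveys everywhere; 263
  camera days at a ~24/41 share of randomly chosen sites), with
  temperatures from an annual sinusoid (mean 8 °C, amplitude 10 °C,
  daily SD 3 °C) standardized pooled across all occasions. All of this is
  configurable; the defaults are the conditions under which the package's
  recovery claims are made.
* `simulate_dor_records()` — uniform carcass distances, Bernoulli morphs
  from the DOR cline.
* `simulate_risk_dataset()` — covariates generated parent-first along the
  DAG with Gaussian structural equations on transformed scales (log for
  positive multiplicative covariates, logit for proportions, Bernoulli for
  crossings), then a logistic outcome; the default is balanced
  case-reference sampling from a large population pool, mirroring the
  matched design (equal group sizes by construction), with
  `balanced = FALSE` giving population prevalence instead.
* `make_citizen_table()` — 2×2 tables from classification totals.

Default generating values for the clines and detection coefficients are
realistic field-scale values for an urban melanism gradient (mean site
abundance ≈ 13 at the gradient midpoint, declining with distance; melanism
declining from ≈ 0.6 urban to ≈ 0.1 rural among living squirrels; daily
detection probabilities ≈ 0.10–0.18 at average temperature, lower for the
melanic morph).

What the generator deliberately does **not** emulate: spatial
autocorrelation among sites, road-network geometry, observer heterogeneity,
carcass persistence/detectability, multi-year dynamics, and
raster-derived covariate error. Passing recovery tests therefore shows the
estimators are correct *under the model*, not that the model is adequate
for any particular field system.

## Numerical conventions and degenerate inputs

* Latent-sum truncation: Poisson tail < 1e-12, floor 50, never below the
  maximum observed count; a documented ceiling (default 500 in the fitting
  wrappers, far above anything the priors support) guards against
  pathological proposals. `lambda = 0` is handled as the point mass on
  `N = 0`; detection probabilities of exactly 0 or 1 are handled by their
  exact limiting likelihoods.
* Proposal tuning targets 23% acceptance; Robbins-Monro steps shrink as
  `5/sqrt(batch)`; covariance re-estimation from chain history is available
  (`adapt_cov`) but off in the fitting wrappers — with short adaptation
  phases a self-estimated covariance can collapse and trap a chain, while
  the Laplace covariance is stable.
* Firth iterations stop when the largest modified-score component is below
  `1e-8` (default), cap 100 iterations, flag rather than raise on
  non-convergence; step-halving guarantees the penalized log-likelihood is
  non-decreasing.
* Problem sizes used by the shipped tests: oracle enumerations run on 2-3
  site toys; recovery uses 20 replicates at the field design (41 sites,
  medians as above, 141 DOR records) with the reduced protocol; the Wald
  calibration study uses 120 replicates of the matched risk design. These
  sizes give the test statistics enough resolution for the stated
  tolerances while keeping the default suite routine to run.

## A minimal end-to-end run

```{r example, eval = FALSE}
cfg <- pipeline_config(out_dir = "run1", seed = 42)
report <- run_full_pipeline(cfg)
report$summary            # Table-1-style posterior summary
autoplot(report$contrast) # clines and their difference
```

The report bundle includes long-format posterior CSVs, the summary table
with an excludes-zero flag, the three curves, risk-effect JSON, the
contingency statistics, the R-hat report, and a manifest with the seed
expansion — re-running with the same config reproduces every numeric
output byte-for-byte.
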