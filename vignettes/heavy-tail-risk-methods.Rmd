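---
title: "Modelling censored, heavy-tailed contaminant concentrations for dietary risk assessment"
author: "phthalrisk developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling censored, heavy-tailed contaminant concentrations for dietary risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phthalrisk)
```

## The problem

Plasticizer residues such as DBP (dibutyl phthalate) and DEHP
(bis(2-ethylhexyl) phthalate) accumulate in fatty food matrices. Survey
concentration data for such contaminants have three awkward features at
once:

* **left-censoring** — a substantial fraction of samples sits below the
  analytical limit of detection (LOD), so each observation is either a
  positive measurement or a non-detect flag;
* **strong right skew** — most positives are small, with occasional values
  one to two orders of magnitude larger;
* **heavy upper tails** — the extremes matter most for risk, and a single
  lognormal, gamma, Weibull or exponential body systematically misstates
  the high percentiles (P95, P99.9) that drive conservative risk
  characterization.

`phthalrisk` implements a hybrid modelling pipeline for this setting: the
positive concentrations are fitted with traditional parametric families,
extreme value mixture models (EVMMs), and two-component finite mixtures; a
three-stage protocol selects the model per analyte; a zero-inflated Monte
Carlo simulation propagates concentrations and lognormal consumption into
estimated daily intake (EDI); and hazard quotients (HQ) and a cumulative
hazard index (HI) characterize the risk, with bootstrap confidence
intervals for the upper-tail percentiles.

## The models

### Extreme value mixture model

The EVMM splices a parametric bulk $H(\cdot \mid \eta)$ (lognormal, Weibull
or gamma) below a threshold $u$ to a generalized Pareto distribution (GPD)
$G(\cdot \mid \xi, \sigma, u)$ for exceedances:

$$
F(x) =
\begin{cases}
H(x \mid \eta), & x < u\\
H(u \mid \eta) + \left[1 - H(u \mid \eta)\right] G(x \mid \xi, \sigma, u), & x \ge u.
\end{cases}
$$

Two modelling choices deserve comment, because the literature uses several
variants:

* **Bulk-based tail fraction.** The mass above the threshold is the bulk's
  own tail mass $1 - H(u)$; no separate tail-fraction parameter is
  estimated. With a bulk-based tail fraction, renormalizing ("truncating")
  the bulk below $u$ produces the algebraically identical density, so the
  only substantively different variant is a *free* tail fraction $\phi_u$,
  which is available behind `tail_fraction = "free"` (its MLE is the
  exceedance proportion, profiled out in closed form). The default follows
  the spliced-CDF form above.
* **The threshold is an estimated parameter.** `evmm_fit()` profiles the
  joint likelihood over candidate thresholds at the sample quantiles P50
  to P95 in steps of 2.5 percentile points (continuous MLE of
  $(\eta, \xi, \sigma)$ at each candidate), then refines the best profile
  point by joint local optimization that includes $u$. Candidates with
  fewer than two exceedances are skipped — a GPD is unidentifiable below
  that — and a fit fails loudly if every candidate is skipped.

Numerical notes: the GPD switches to its exponential-limit formulas when
$|\xi| < 10^{-8}$ (the $(1+\xi z)^{-1/\xi}$ form cancels catastrophically
near zero); for $\xi < 0$ the finite upper endpoint $u - \sigma/\xi$ is
respected by the CDF, quantile and sampler. The sampler pushes one uniform
stream through the closed-form spliced quantile function, so draws are
exactly distributed as the CDF and byte-reproducible under a seed.

### Finite mixtures

Two-component mixtures $f(x) = \sum_i \pi_i f_i(x \mid \theta_i)$ of
lognormal, Weibull or gamma components are fitted by EM. The M-step is a
weighted MLE per component — closed form for the lognormal, 1-D
root-finding for the gamma and Weibull shapes (the Weibull shape equation
is solved on data normalized by their geometric mean so $x^k$ cannot
overflow for large $k$). Initialization splits the data at the median;
further restarts use random quantile splits; the best of `n_restarts`
(default 10) is kept. Runs that collapse a component (weight below
$10^{-6}$ or vanishing variance) are discarded, and the fit fails loudly if
every restart degenerates. Label switching is resolved by sorting
components by mean. EM's monotone log-likelihood is recorded
(`$trace`) and asserted in the tests.

### Model selection

`select_model()` implements a three-stage protocol:

1. **Goodness-of-fit screening.** Kolmogorov–Smirnov and Anderson–Darling
   statistics against the fitted CDF, with p-values from a *parametric
   bootstrap* (simulate from the fitted model, refit, recompute; $p =
   (1 + \#\{ \text{stat}_b \ge \text{stat}_{obs}\})/(B+1)$). Textbook
   critical values are invalid when parameters are estimated from the same
   data; the bootstrap restores calibration (verified: type-I error within
   $[0.03, 0.07]$ at $\alpha = 0.05$ in the acceptance suite). The refits
   inside the bootstrap must use the *same settings* as the observed fit —
   a coarser refit grid biases the p-values upward, which we observed and
   guard against by routing identical arguments to both sides.
2. **Information criteria.** Survivors are ranked by BIC, with AIC
   reported and used as tie-break. Parameter counts: 2 (or 1 for the
   exponential) for single families, bulk-parameters $+3$ for the EVMM
   ($u, \xi, \sigma$), and $2g + (g-1) = 5$ for the two-component
   mixtures. A shortlist of the top `top_k` (default 3) goes forward.
3. **Monte Carlo percentile deviations.** Each shortlisted model is
   simulated (`n_sim` = 10,000 by default) and scored by the percent
   relative difference from the empirical mean, P95 and P99.9. The winner
   minimizes the **P99.9 deviation first** (ties: mean, then P95) — a
   deliberately conservative, upper-tail-first rule; a weighted-sum
   aggregation is available via `stage3_weights`.

Mixture candidates are excluded when fewer than `min_pos_mixture`
(default 30) positives are available; two-parameter-per-component mixtures
on a couple dozen points are not meaningfully identifiable.

## Exposure and risk

Concentrations are simulated zero-inflated: a Bernoulli indicator at the
observed detection rate chooses between a draw from the selected
positive-concentration model and a non-detect imputed as Uniform(0, LOD).
The LOQ plays no role in simulation. Consumption (g/day) is lognormal per
demographic group; when only published intake percentiles are available,
`consumption_from_percentiles()` calibrates $(\mu, \sigma)$ by least
squares on the log-quantiles (exact for two targets). A range-based
fallback (`consumption_from_range()`, endpoints read as P2.5/P97.5,
optional truncation at the range) is provided but not used by default:
published ranges under-determine the lognormal and no range rule we tested
reproduces published simulated quantiles, so percentile targets are
treated as the calibration inputs of record.

EDI in µg/(kg·bw)/day is `cons * conc / weight`: g/day × mg/kg (≡ µg/g) /
kg leaves no stray unit factor. Consumption and concentration streams are
independent (no dependence is modelled). Risk is characterized by

$$\mathrm{HQ} = \mathrm{EDI} / \mathrm{TDI}, \qquad
\mathrm{HI} = \frac{\mathrm{EDI}_{\mathrm{DEHP}} \cdot 1 +
\mathrm{EDI}_{\mathrm{DBP}} \cdot 5}{50},$$

with EFSA guidance values as defaults: TDI 50 (DEHP) and 10 (DBP)
µg/(kg·bw)/day, relative potency factors 1 and 5 against a group TDI of
50 in DEHP equivalents. HQs and the HI apply pointwise at the summary
points (mean, P50, P75, P95, P99.9); with these defaults the HI equals
HQ\_DEHP + HQ\_DBP, an identity the tests assert. The HI refuses to
compute from a single analyte.

### Bootstrap uncertainty

`bootstrap_ci()` defaults to a **data-level bootstrap**: each replicate
resamples the sample rows with replacement preserving detect/non-detect
status, recomputes the detection rate, refits the *selected family* on the
resampled positives (the family is fixed — per-replicate reselection would
conflate model and parameter uncertainty), reruns the Monte Carlo
simulation under a fresh sub-seed, and records the summary percentiles.
The 95% CI is the 2.5–97.5 percentile band over replicates (default
$B = 100$). A cheaper `mode = "edi"` resamples only the simulated EDI
vector, for comparison; it omits parameter uncertainty and is expected to
be anti-conservative at the upper percentiles. Replicate refit failures
are dropped and counted; more than 20% flags the result.

## The synthetic-data generator

No real concentration data are shipped; `preset_scenario()` states a
synthetic world with known ground truth:

* **dehp-like** — 91 samples, detection rate 0.55, LOD 0.10 mg/kg; the
  positive law is a two-component gamma mixture
  $0.93\,\Gamma(7, \text{mean } 0.36) + 0.07\,\Gamma(1.4, \text{mean } 3)$
  chosen so the positive mean (≈0.55 mg/kg) falls in the published
  0.3–0.6 mg/kg band and the P99.9 (≈11 mg/kg) exceeds 10 mg/kg,
  emulating the published detection rate and tail heaviness.
* **dbp-like** — detection rate 0.32, LOD 0.05 mg/kg; lognormal bulk
  (median 0.15 mg/kg) spliced to a GPD tail ($\xi = 0.3$, $\sigma = 0.08$)
  above the bulk P90, giving a positive mean ≈0.18 and P99.9 ≈1 mg/kg.
* **null-uniform** — fully detected, light-tailed smoke scenario.

Detected positives are redrawn until they reach the LOD, so "detected"
and "quantifiable" coincide. This forces a coherence constraint we learned
the hard way: **the truth must place negligible mass below the LOD**
(both presets keep it under ~0.5%). With, say, 3% sub-LOD mass the
observed positives follow a *truncated* law rather than the nominal one —
at ~500 positives even the true model is then rejected by its own
parametric-bootstrap GOF test, and "recovering the true family" stops
being a well-posed question. The presets are validated against these
calibration targets in the test suite.

Consumption truths use the eight published age-by-sex strata (body
weights and P50/P75/P95 daily intakes of the survey), calibrated through
`consumption_from_percentiles()`.

What a green synthetic test does **not** establish: the generator draws
i.i.d. samples from clean parametric laws; real survey data carry
measurement error, batch effects, regional sampling structure and an
LOD–LOQ reporting band, none of which are emulated. Selection consistency
on these bundles shows the protocol works when its assumptions hold, not
that the published analyte-specific winners are correct.

## Numerical and design choices

* **Gamma convention** is (shape, rate) internally; `scale` is accepted at
  construction and converted. Published analyses rarely state which
  convention they used; one internal convention prevents silent misfits.
* **Optimization**: Nelder–Mead on log-transformed scale parameters with
  moment-based starts (Justus approximation for the Weibull shape; GPD
  starts at $\xi = 0.1$, $\sigma$ = sd of exceedances). Non-convergence is
  flagged on the result, never hidden.
* **Quantile convention**: R type-7 sample quantiles throughout, so the
  empirical P99.9 of ~500 points interpolates between the two largest
  order statistics; Stage-3 deviations at P99.9 are accordingly noisy, and
  the protocol's upper-tail-first rule inherits that noise (visible in the
  selection-consistency experiments, where a correct heavy-tailed model
  occasionally loses Stage 3 to a more stable short-tailed candidate).
* **Seeding**: every sampler takes an explicit seed and restores the
  caller's RNG state; one master seed spawns named sub-streams
  (`derive_seed()`) per stage, group and analyte, so any stage can be
  replayed in isolation and end-to-end reports are byte-identical under a
  fixed config + seed.
* **Budget scaling in the test suite** (documented, tolerances never
  changed): the GOF calibration study runs at $B = 200$ and the CI
  coverage study at $B = 50$ with $n_{sim} = 2{,}000$, as the acceptance
  criteria themselves state; the selection-consistency study uses
  $B = 40$ bootstrap GOF replicates and caps EM at 250 iterations,
  applied identically to observed fits and bootstrap refits.
* **Configuration** is YAML (JSON accepted) with an explicit validator
  (unknown keys rejected); every output embeds the config MD5 and master
  seed for provenance.

## Known limitations

* Censored likelihoods are not implemented: models are fitted to the
  positives only; the censored fraction enters through the Bernoulli
  detection indicator instead.
* The bootstrap CIs quantify sampling plus Monte Carlo uncertainty under
  the *selected* family; model-form uncertainty is excluded by design.
* The HI covers two analytes; congeners sharing the group TDI but not
  measured (e.g. BBP, DINP) would add to the true cumulative index, so the
  reported HI is, if anything, an underestimate.
* EVMM threshold estimation by profile grid is robust but slow-ish in
  bootstrap loops; the profile grid is the tuning lever, and the GOF
  p-values are only as good as the match between observed-fit and refit
  settings.
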