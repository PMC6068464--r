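---
title: "Modeling the synaptic vesicle protein life cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the synaptic vesicle protein life cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svlifecycle)
```

## The model and its assumptions

Pulse-chase tagging of synaptic vesicle proteins shows two separated time
scales: tagged proteins stop participating in release with a time
constant of about 0.4 days, but leave the synapse only after about
1.6 days. `svlifecycle` models this as an irreversible three-state chain
— releasable, inactive, degraded — with constant per-day rates `k_inact`
and `k_deg`, and with release events forming a Poisson process at rate
`usage_rate` that is active only in the releasable state. The model's
assumptions are deliberately minimal:

* transitions are memoryless (single-exponential residence in each
  state), which is what the observed single-exponential decays of both
  the releasable fraction and the total retention support;
* there is no return path from the inactive to the releasable pool, and
  no direct degradation from the releasable state;
* release events do not themselves change the transition rates; activity
  dependence is introduced explicitly through `modulate_activity()`.

Under these assumptions the releasable survival is `exp(-k_inact * t)`,
the total retention is the two-compartment expression implemented in
`total_retention()`, the total lifetime is hypoexponential with mean
`1/k_inact + 1/k_deg`, and the number of release rounds per lifetime is
geometric with mean `usage_rate / k_inact` (a Poisson process observed
over an exponential window).

## Parameters, units and defaults

| parameter | unit | default | origin |
|---|---|---|---|
| `k_inact` | /day | 2.5 | reciprocal of the 0.4-day releasable constant |
| `k_deg` | /day | 0.8333 | 1/(1.6 − 0.4) days, see below |
| `burst_rate` | Hz | 0.09 | measured culture burst frequency |
| `per_burst_fraction` | — | 0.0675 | back-computed, see below |
| `usage_rate` | /day | 524.88 | `burst_rate × per_burst_fraction × 86400` |

Two of these deserve comment.

**Reading the 1.6-day constant.** The longer constant can be read either
as the mean *total* synaptic residence (so the inactive phase alone lasts
1.6 − 0.4 = 1.2 days and `k_deg = 1/1.2`), or as the slow exponential
eigenvalue of the retention curve itself (`k_deg = 1/1.6`). Sequential
exponential means add, which makes the first reading the natural one for
a residence-time measurement, and it is the package default;
`params_from_time_constants(interpretation = "slow-eigenvalue")` selects
the alternative. At these rate values the two differ by ~25% in `k_deg`
but do not change any usage-related quantity, which depends only on
`k_inact` and `usage_rate`.

**The per-burst release fraction.** `per_burst_fraction` is not directly
printed as a number anywhere; it is back-computed from the three
quantities that are: ~210 release rounds per lifetime, the 0.4-day
releasable residence, and the 0.09 Hz burst rate, giving
`210 / (0.4 × 86400 × 0.09) ≈ 0.0675`. The package treats 0.0675 as the
canonical default and verifies consistency through the closed-form usage
mean (209.952) and the cross-validation product, which are algebraically
identical:

```{r}
p <- kinetic_params()
c(model = usage_distribution(p)$mean, crossval = cross_validated_usage(p))
```

The burst-to-usage equivalence is exact: thinning Poisson burst times at
`burst_rate` with independent per-burst Bernoulli releases of probability
`per_burst_fraction` yields a Poisson release process at their product —
so a per-burst description and a continuous usage rate are the same
model.

## Activity modulation

Raising network activity accelerates the inactivation of tagged
proteins. `modulate_activity(params, a)` implements the usage-coupled
variant as the default: both `burst_rate` (hence `usage_rate`) and
`k_inact` scale by `a`, so vesicles that are used more often also retire
sooner and the *mean number of release rounds per lifetime is invariant*
— the signature of a usage counter rather than a clock. The alternative
(`couple_usage = FALSE`) scales only `k_inact`, modeling a pure timer
that runs faster; it reduces the usage mean proportionally. The package
treats the invariance of the default variant as a tested property.

## The simulator

`simulate_trajectories()` samples each life history exactly by the
inverse CDF of the exponential residences and a Poisson release count
over the realized releasable window — no time discretization, so the
closed forms above are exact oracles for simulated cohorts, and all
Monte-Carlo comparisons in the test suite use plain 3-standard-error
bounds without discretization allowances. Release *times* (exchangeable
uniforms over the releasable phase) are materialized only on request,
because at ~210 events per vesicle they would dominate memory for
100,000-vesicle cohorts without adding information beyond the count.
Replicate noise on cohort time courses is multiplicative Gaussian,
clipped to [0, 1.05]; the measurement noise model of intensity
normalization is not documented for the original experiments, so the
multiplicative form (constant coefficient of variation, the usual
behavior of normalized fluorescence) is an explicit assumption of the
generator rather than a measured property.

## Fitting

`fit_exponential_decay()` minimizes unweighted least squares of
`A·exp(−t/τ) + b` over pooled replicates via Levenberg-Marquardt, with
five log-spaced starts for τ (0.1–10 days) because the likelihood is
nearly flat in τ once τ exceeds the observation window; the best-SSE
start wins and non-convergence is reported as a flag, not an error.
The plateau `b` is fixed at zero unless requested — both plateau-free
and plateau fits are exposed since the provenance of the printed
constants in that respect is not recorded. `fit_two_state()` fits the
releasable and total series jointly over `(k_inact, k_deg)` on a log
scale with equal weights; a fit with `k_inact ≤ k_deg` is flagged
non-physical, which in practice indicates swapped inputs, because in
this system the releasable pool empties faster than the inactive pool
degrades. `bootstrap_ci()` resamples whole replicates (case resampling)
and attaches percentile 95% intervals; with a single replicate the
interval is degenerate and flagged.

## Imaging and trace quantifiers

The quantifiers mirror how the microscopy endpoints are defined, with
the unstated instrument details fixed as module defaults:

* **Spot detection** — Gaussian smoothing at the PSF scale, threshold at
  the image median plus `k` MADs, connected components, minimum area.
  Two spots closer than the resolution merge into one component by
  construction.
* **Background** — per-image median outside all masks. Background is
  subtracted as region totals (sum minus pixel count × background)
  rather than per-pixel clamped differences: clamping rectifies
  zero-mean shot noise into a spurious positive off-cluster signal. If
  background subtraction annihilates the whole image (uniform image),
  the raw intensity split is reported.
* **Off-cluster dilation** — the reference mask is dilated by one PSF
  sigma before the outside intensity is summed, so PSF-blurred rim light
  counts as in-cluster.
* **Isotope ratios** — heavy/light ratios are computed pixel-wise and
  averaged (zero-light pixels excluded); the sum/sum convention is an
  option. The fold over baseline is exactly reciprocal under swapping
  the ROI and baseline regions under the pixel-wise convention.
* **Overlay** — both images normalized by their own maxima; each pixel
  takes the larger source, ties going to the ratio image.
* **Burst detection** — onsets are found on the *rise* of the boxcar-
  smoothed trace (lag-window difference) thresholded at 3.5 noise
  standard deviations, with noise estimated from successive differences
  of the raw trace. A global median+MAD threshold on the dF/F level
  fails at high burst rates, where piled-up transients lift both the
  location and the scale estimate; successive differences see only the
  sampling noise. The reported rate corrects for the 2-s refractory
  dead time (`n/(T − n·τ_r)`), which restores unbiasedness for Poisson
  bursts up to at least 0.3 Hz; the raw count over duration is also
  returned.
* **Per-burst release** — the sypHy upstroke is measured as the
  difference of window means (1 s post vs 0.5 s pre onset), not a peak
  sample, so trace noise averages out instead of biasing the estimate
  upward.

## Damage accumulation

If degradation happens only after a protein has been damaged, measured
turnover lifetimes bound the damage rates. `damage_probability()`
implements two onset models: memoryless (exponential hazard) and staged
(damage completes after `m` sequential exponential steps, a gamma
waiting time with the same mean but delayed onset; `m = 1` recovers the
exponential model exactly). The expected damaged fraction of a vesicle's
protein complement at inactivation integrates the damage CDF over the
exponential inactivation age; for the staged model this has the closed
series `1 − Σ_{j<m} k_i r^j/(k_i+r)^{j+1}` with `r = m/lifetime`, and a
quadrature route is kept for cross-checking. The staged default `m = 3`
is a design choice: with day-scale protein lifetimes, only a
delayed-onset model yields the near-zero damaged fraction at
inactivation that motivates reading inactivation as a *predictive*
removal mechanism, and the damaged-at-inactivation fraction decreases
monotonically in `m` at fixed mean damage time — the quantitative form
of "vesicles are retired just before damage begins". Proteins are
copy-number weighted by default (an unweighted option exists, since the
original weighting is not recorded). The bundled
`synthetic_protein_table.csv` carries illustrative copy numbers and
lifetimes and is labeled synthetic: the measured per-protein lifetimes
live in external supplementary material that is not redistributed here.

## Synthetic data: what it emulates, and what it does not

Every generator returns its ground truth, and all defaults are
centralized in `generator_defaults()`. Measured quantities keep their
measured values (decay constants 0.4/1.6 days, burst rate 0.09 Hz,
off-cluster fraction 3%, enrichment fold 2.0); instrumental settings are
synthetic choices: 10% multiplicative replicate noise, 10 Hz sampling
with SNR 5 and a 1-s calcium kernel with a 20-s sypHy re-acidification,
256-pixel images at 20 nm/pixel with a 40-nm PSF sigma, 500 photons per
unit intensity over a 2% uniform background, 200 ion counts per pixel
over a 0.004 baseline isotope ratio. The generators emulate the
*structure* of the measurements — replicate scatter, Poisson photon and
ion statistics, burst-locked step/transient pairing, co-cluster geometry
with a controllable off-cluster intensity share — but not microscope
physics: no STED resolution anisotropy, no drift, no bleaching, no
detector artifacts, no synapse-to-synapse parameter heterogeneity.
Passing recovery tests therefore demonstrates that the quantifiers are
correct and calibrated under the stated noise models, not that they are
robust to every instrumental pathology of real data.

## Numerical choices

* Rates within a relative 1e-8 switch the two-compartment expressions to
  the Erlang limit (`k t e^{-kt}` retention term, `k² t e^{-kt}`
  density), avoiding catastrophic cancellation; the test suite checks
  sup-norm agreement of the two branches at the boundary.
* Usage pmfs are tabulated to the point where the geometric tail mass
  falls below 1e-6; the mean is always the exact `λ_u/k_inact`, never a
  truncated sum.
* Fits optimize `log τ` (and log rates in the two-state fit) so the
  positivity constraint is structural rather than penalized.
* Spot placement uses dart throwing with a minimum separation of ten PSF
  sigmas, a packing-density feasibility pre-check, and a
  consecutive-failure cap, so infeasible configurations fail fast
  instead of looping.
* Problem sizes in the tests — 1e5-vesicle cohorts, 100 fitted datasets
  per constant, 20 traces, 10 images, 100–200 bootstrap replicates —
  were chosen so Monte-Carlo standard errors sit comfortably below the
  tolerances being verified while the whole suite stays fast.

## Known limitations

* The three-state chain has no return path and no spatial structure; it
  cannot represent partial reactivation of inactive vesicles or
  bouton-level heterogeneity.
* The 1.6-day interpretation ambiguity is exposed but not resolved; only
  external data could decide it.
* `detect_bursts` assumes bursts rise within one sampling interval and
  decay on a ~1-s scale; slow-onset events would need a different
  matched filter.
* The damage extrapolation inherits the assumption that turnover
  lifetime equals damage time; if proteins are degraded for other
  reasons, the inferred damage rates are upper bounds.
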