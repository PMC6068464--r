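# svlifecycle

Kinetics of the synaptic vesicle protein life cycle in cultured neurons.

Synaptic vesicle proteins are tagged during recycling (for example with
antibodies against lumenal domains of Synaptotagmin 1), after which the
labeled cohort can be chased for days. Two robust observations emerge from
such pulse-chase experiments: the tagged proteins stop participating in
release quickly (releasable-pool time constant ~0.4 days), yet remain in
the synapse considerably longer (~1.6 days) before being degraded. This
package implements the three-state kinetic model that reconciles the two
time scales, together with the measurement quantifiers and synthetic-data
generators needed to exercise the full analysis end to end.

## The model

A vesicle protein assembly moves irreversibly through three states,

    releasable --k_i--> inactive --k_d--> degraded

with constant rates (per day). While releasable, the vesicle undergoes
release events as a Poisson process with rate λ_u; under spontaneous
network activity this rate equals f_b · p_b · 86400, where f_b is the
burst frequency (Hz) and p_b the probability that a releasable vesicle
releases in one burst. The model's closed forms:

* releasable survival: R(t) = exp(−k_i t)
* total synaptic retention: R(t) + I(t) with
  I(t) = k_i/(k_d − k_i) · (exp(−k_i t) − exp(−k_d t))
* total lifetime: hypoexponential (sum of the two exponential phases),
  mean 1/k_i + 1/k_d
* release rounds per lifetime: geometric, P(N = n) = q pⁿ with
  q = k_i/(k_i + λ_u), mean λ_u/k_i

With k_i = 1/0.4 d⁻¹, f_b = 0.09 Hz and p_b = 0.0675, the mean usage is
λ_u/k_i ≈ 210 release rounds per lifetime, and the independent
cross-validation route — hours spent releasable × bursts per hour ×
fraction released per burst — gives the identical number.

The package also contains a per-vesicle stochastic simulator, nonlinear
least-squares fitting of pulse-chase decays (single-exponential and joint
two-state) with bootstrap intervals, the bespoke microscopy quantifiers
(spot detection, off-cluster intensity fraction, per-spot enrichment
fold, isotope-ratio fold over baseline, winner-take-all ratio/fluorescence
overlay, pH-probe releasable fraction, calcium burst detection), a
damage-accumulation extrapolation, and seed-deterministic generators for
every input with ground truth attached.

## Worked example

```r
library(svlifecycle)

p <- kinetic_params()
p
#> Vesicle life-cycle kinetic parameters
#>   k_inact: 2.5 /day   (releasable time constant 0.4 d)
#>   k_deg:   0.8333 /day   (inactive time constant 1.2 d; total residence 1.6 d)
#>   bursts:  0.09 Hz, per-burst release fraction 0.0675
#>   usage:   524.9 releases/day while releasable (mean 210 per lifetime)

cross_validated_usage(p)
#> [1] 209.952

# simulate a labeled cohort and refit the pulse-chase decay
tr <- simulate_trajectories(p, 1e5, seed = 7)
mean(tr$n_releases)
#> [1] 210.0712

d <- gen_decay_dataset(seed = 3)      # tau 0.4 d, 10% noise, 3 replicates
fit <- fit_exponential_decay(d$timecourse)
fit
#> Pulse-chase fit (single-exponential model)
#>   tau        0.38898
#>   A          1.0102
#>   SSE 0.021681 over 5 starts
```

The fitted `tau` is the releasable-pool time constant in days; `A` the
normalized initial intensity. The same workflow with
`gen_two_channel_image()` / `off_cluster_fraction()` recovers the ~3%
off-cluster intensity of tagged molecules, and `detect_bursts()` on
`gen_calcium_syphy_pair()` traces recovers the 0.09 Hz culture burst
rate.

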