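# Independent Monte-Carlo oracles, written as naive direct simulations so
# the closed forms and the package simulator can both be checked against
# them. These deliberately avoid every package code path they verify.

# fraction of a cohort still in the synapse (releasable or inactive) at t
mc_total_retention <- function(ki, kd, t, n = 1e5) {
  t_in <- stats::rexp(n, ki)
  t_dg <- t_in + stats::rexp(n, kd)
  mean(t_dg > t)
}

# fraction still releasable at t
mc_releasable <- function(ki, t, n = 1e5) {
  mean(stats::rexp(n, ki) > t)
}

# mean release count per lifetime: Poisson usage over exponential residence
mc_usage <- function(ki, lu, n = 1e5) {
  t_in <- stats::rexp(n, ki)
  stats::rpois(n, lu * t_in)
}

# damaged fraction at inactivation for a single protein, m-stage damage
mc_damaged_at_inactivation <- function(ki, lifetime, m, n = 1e5) {
  t_in <- stats::rexp(n, ki)
  t_damage <- stats::rgamma(n, shape = m, rate = m / lifetime)
  mean(t_damage <= t_in)
}

# default-parameter helper used across files
default_params <- function() kinetic_params()
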