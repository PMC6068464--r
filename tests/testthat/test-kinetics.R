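test_that("parameter construction validates rates and burst consistency", {
  p <- kinetic_params()
  expect_equal(p$k_inact, 2.5)
  expect_equal(p$k_deg, 1 / 1.2)
  expect_equal(p$usage_rate, p$burst_rate * p$per_burst_fraction * 86400,
               tolerance = 1e-12)
  expect_error(kinetic_params(k_inact = 0), "positive")
  expect_error(kinetic_params(per_burst_fraction = 1.2), "\\[0, 1\\]")
  expect_error(kinetic_params(usage_rate = 100), "inconsistent")
})

test_that("time-constant mapping supports both readings of the long constant", {
  expect_equal(params_from_time_constants(0.4, 1.6)$k_deg, 1 / 1.2)
  expect_equal(params_from_time_constants(0.4, 1.6, "slow-eigenvalue")$k_deg,
               1 / 1.6)
  expect_error(params_from_time_constants(0.4, 0.3), "exceed")
})

test_that("releasable survival follows the single exponential", {
  p <- kinetic_params()
  expect_equal(releasable_survival(p, 0), 1)
  expect_equal(releasable_survival(p, 0.4), exp(-1), tolerance = 1e-12)
  expect_equal(releasable_survival(p, 1), exp(-2.5), tolerance = 1e-12)
  tt <- seq(0, 5, by = 0.1)
  expect_true(all(diff(releasable_survival(p, tt)) < 0))
  expect_error(releasable_survival(p, -1), "non-negative")
})

test_that("total retention matches the two-compartment closed form and limits", {
  p <- kinetic_params()
  expect_equal(total_retention(p, 0), 1)
  expect_equal(total_retention(p, 1), 0.6108548, tolerance = 1e-6)
  # Erlang limit at equal rates
  pe <- kinetic_params(k_inact = 1, k_deg = 1,
                       burst_rate = NULL, per_burst_fraction = NULL)
  expect_equal(total_retention(pe, 1), 2 * exp(-1), tolerance = 1e-12)
  # retention dominates releasable survival, both decreasing
  tt <- seq(0, 10, by = 0.25)
  expect_true(all(total_retention(p, tt) >= releasable_survival(p, tt)))
  expect_true(all(diff(total_retention(p, tt)) < 0))
})

test_that("lifetime distributions have analytic means and integrate to one", {
  p <- kinetic_params()
  rel <- lifetime_distribution(p, "releasable")
  ina <- lifetime_distribution(p, "inactive")
  tot <- lifetime_distribution(p, "total")
  expect_equal(rel$mean, 0.4)
  expect_equal(ina$mean, 1.2)
  expect_equal(tot$mean, 1.6)
  expect_equal(rel$density[1L], 2.5)
  # hypoexponential closed form at t = 1
  d1 <- tot$density[which.min(abs(tot$grid - 1))]
  expect_equal(d1, 0.4406, tolerance = 1e-3)
  for (d in list(rel, ina, tot)) {
    expect_true(all(d$density >= 0))
    integral <- sum(diff(d$grid) * (head(d$density, -1) + tail(d$density, -1)) / 2)
    expect_equal(integral, 1, tolerance = 1e-3)
  }
  expect_error(lifetime_distribution(p, "nonsense"))
})

test_that("hypoexponential density converges to the Erlang(2) limit", {
  tt <- seq(0, 10, length.out = 500L)
  base <- kinetic_params(k_inact = 1, k_deg = 1,
                         burst_rate = NULL, per_burst_fraction = NULL)
  erlang <- lifetime_distribution(base, "total", grid = tt)$density
  near <- kinetic_params(k_inact = 1, k_deg = 1 + 5e-9,
                         burst_rate = NULL, per_burst_fraction = NULL)
  hypo <- lifetime_distribution(near, "total", grid = tt)$density
  expect_lt(max(abs(hypo - erlang)), 1e-6)
})

test_that("usage distribution is geometric with the analytic mean", {
  p <- kinetic_params()
  u <- usage_distribution(p)
  expect_equal(u$mean, 209.952, tolerance = 1e-9)
  expect_equal(u$pmf[1L], 2.5 / (2.5 + p$usage_rate), tolerance = 1e-9)
  expect_equal(sum(u$pmf) + u$tail_mass, 1, tolerance = 1e-9)
  # geometric ratio constant
  expect_equal(u$pmf[2L] / u$pmf[1L], p$usage_rate / (2.5 + p$usage_rate),
               tolerance = 1e-12)
  # no usage at all
  p0 <- kinetic_params(burst_rate = 0, per_burst_fraction = 0.5)
  u0 <- usage_distribution(p0)
  expect_equal(u0$pmf[1L], 1)
  expect_equal(u0$mean, 0)
  pna <- kinetic_params(burst_rate = NULL, per_burst_fraction = NULL)
  expect_error(usage_distribution(pna), "usage_rate")
})

test_that("burst arithmetic and the cross-validation product agree", {
  expect_equal(usage_rate_from_bursts(0.09, 0.0675), 524.88, tolerance = 1e-12)
  expect_equal(usage_rate_from_bursts(0, 0.5), 0)
  expect_equal(usage_rate_from_bursts(0.09, 1), 7776)
  expect_error(usage_rate_from_bursts(0.09, 1.5), "\\[0, 1\\]")
  p <- kinetic_params()
  cv <- cross_validated_usage(p)
  expect_equal(cv, 209.952, tolerance = 1e-9)
  # the two routes to the usage headline are algebraically identical
  expect_equal(cv, usage_distribution(p)$mean, tolerance = 1e-9)
  # linear in the releasable residence
  p2 <- kinetic_params(k_inact = 5)
  expect_equal(cross_validated_usage(p2), cv / 2, tolerance = 1e-12)
  expect_equal(cross_validated_usage(kinetic_params(per_burst_fraction = 0)), 0)
})

test_that("activity modulation scales rates and preserves usage mean by default", {
  p <- kinetic_params()
  expect_equal(modulate_activity(p, 1)$k_inact, p$k_inact)
  up <- modulate_activity(p, 1.5)
  expect_equal(up$k_inact, 1.5 * p$k_inact)
  expect_equal(up$usage_rate, 1.5 * p$usage_rate)
  expect_lt(releasable_survival(up, 0.5), releasable_survival(p, 0.5))
  expect_equal(usage_distribution(modulate_activity(p, 1.8))$mean,
               usage_distribution(p)$mean, tolerance = 1e-9)
  # uncoupled variant changes the usage mean
  un <- modulate_activity(p, 1.8, couple_usage = FALSE)
  expect_equal(un$usage_rate, p$usage_rate)
  expect_lt(usage_distribution(un)$mean, usage_distribution(p)$mean)
  expect_error(modulate_activity(p, 0), "positive")
})

test_that("closed forms agree with Monte-Carlo oracles over random rate draws", {
  set.seed(42)
  for (i in 1:20) {
    ki <- exp(stats::runif(1, log(0.1), log(10)))
    kd <- exp(stats::runif(1, log(0.1), log(10)))
    lu <- exp(stats::runif(1, log(1), log(1000)))
    p <- kinetic_params(k_inact = ki, k_deg = kd, usage_rate = lu,
                        burst_rate = NULL, per_burst_fraction = NULL)
    t_eval <- 0.5 / ki + 0.5 / kd
    n <- 1e5
    # survival and retention vs binomial MC; SE from the closed-form
    # probability so it cannot collapse to zero when the sample saturates
    p_r <- releasable_survival(p, t_eval)
    mc_r <- mc_releasable(ki, t_eval, n)
    expect_lt(abs(p_r - mc_r), 3 * sqrt(p_r * (1 - p_r) / n) + 1e-12)
    p_t <- total_retention(p, t_eval)
    mc_t <- mc_total_retention(ki, kd, t_eval, n)
    expect_lt(abs(p_t - mc_t), 3 * sqrt(p_t * (1 - p_t) / n) + 1e-12)
    # usage mean vs MC (geometric variance)
    counts <- mc_usage(ki, lu, n)
    se_u <- stats::sd(counts) / sqrt(n)
    expect_lt(abs(usage_distribution(p)$mean - mean(counts)), 3 * se_u)
  }
})

test_that("parameters round-trip through flat JSON", {
  p <- kinetic_params()
  path <- tempfile(fileext = ".json")
  write_params(p, path)
  doc <- jsonlite::read_json(path)
  expect_named(doc, c("k_inact_per_day", "k_deg_per_day",
                      "burst_rate_hz", "per_burst_fraction"))
  q <- read_params(path)
  expect_equal(q$k_inact, p$k_inact)
  expect_equal(q$usage_rate, p$usage_rate)
})
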