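# Closed-form life-cycle kinetics: survival of the releasable pool, total
# synaptic retention of a labeled cohort, lifetime densities per compartment,
# and the usage (release-count) distribution.

# relative rate difference below which the Erlang limit formula is used;
# avoids catastrophic cancellation in (exp(-k_i t) - exp(-k_d t)) / (k_d - k_i)
.DEGENERATE_TOL <- 1e-8

#' Survival of the releasable pool
#'
#' Fraction of a labeled cohort still in the releasable state at time
#' \code{t}: \code{exp(-k_inact * t)}.
#'
#' @param params a \code{\link{kinetic_params}} object.
#' @param t time(s) since labeling, days, non-negative.
#' @return fraction(s) in (0, 1].
#' @export
releasable_survival <- function(params, t) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be non-negative and finite")
  exp(-params$k_inact * t)
}

#' Total synaptic retention of a labeled cohort
#'
#' Fraction of the cohort still present in the synapse (releasable or
#' inactive) at time \code{t} under the two-compartment chain:
#' \deqn{R(t) = e^{-k_i t}, \quad
#'       I(t) = \frac{k_i}{k_d - k_i}(e^{-k_i t} - e^{-k_d t})}
#' with the Erlang limit \eqn{I(t) = k t e^{-k t}} when the two rates are
#' numerically equal.
#'
#' @inheritParams releasable_survival
#' @return fraction(s) in (0, 1].
#' @export
total_retention <- function(params, t) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be non-negative and finite")
  ki <- params$k_inact; kd <- params$k_deg
  R <- exp(-ki * t)
  if (abs(ki - kd) < .DEGENERATE_TOL * ki) {
    I <- ki * t * exp(-ki * t)
  } else {
    I <- ki / (kd - ki) * (exp(-ki * t) - exp(-kd * t))
  }
  R + I
}

#' Lifetime distribution of a life-cycle compartment
#'
#' Residence-time density of the releasable state (exponential with rate
#' \code{k_inact}), the inactive state (exponential with rate \code{k_deg}),
#' or the total synaptic lifetime (hypoexponential: sum of the two
#' independent exponential phases), evaluated on a user grid.
#'
#' @param params a \code{\link{kinetic_params}} object.
#' @param compartment one of \code{"releasable"}, \code{"inactive"},
#'   \code{"total"}.
#' @param grid strictly increasing time grid, days, starting at 0. The
#'   default spans ten mean lifetimes of the requested compartment.
#' @return an object of class \code{"lifetime_distribution"}: a list with
#'   \code{compartment}, \code{grid} (days), \code{density} (per day) and
#'   the analytic \code{mean} (days).
#' @export
lifetime_distribution <- function(params,
                                  compartment = c("releasable", "inactive", "total"),
                                  grid = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  compartment <- match.arg(compartment)
  ki <- params$k_inact; kd <- params$k_deg
  mean_life <- switch(compartment,
                      releasable = 1 / ki,
                      inactive = 1 / kd,
                      total = 1 / ki + 1 / kd)
  if (is.null(grid)) grid <- seq(0, 10 * mean_life, length.out = 2001L)
  if (grid[1L] != 0 || any(diff(grid) <= 0))
    stop("grid must be strictly increasing and start at 0")
  density <- switch(compartment,
    releasable = stats::dexp(grid, rate = ki),
    inactive = stats::dexp(grid, rate = kd),
    total = hypoexp_density(grid, ki, kd))
  structure(list(compartment = compartment, grid = grid,
                 density = density, mean = mean_life),
            class = "lifetime_distribution")
}

# density of the sum of Exp(ki) and Exp(kd); Erlang(2) limit when rates equal
hypoexp_density <- function(t, ki, kd) {
  if (abs(ki - kd) < .DEGENERATE_TOL * ki) {
    ki^2 * t * exp(-ki * t)
  } else {
    ki * kd / (ki - kd) * (exp(-kd * t) - exp(-ki * t))
  }
}

#' @export
print.lifetime_distribution <- function(x, ...) {
  cat(sprintf("Lifetime distribution (%s compartment)\n", x$compartment))
  cat(sprintf("  analytic mean: %.4g days; grid: %d points over [0, %.4g] days\n",
              x$mean, length(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
plot.lifetime_distribution <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l",
                 xlab = "lifetime (days)", ylab = "density (per day)",
                 main = sprintf("%s lifetime (mean %.3g d)", x$compartment, x$mean), ...)
  invisible(x)
}

#' Distribution of release rounds per lifetime
#'
#' With release events arriving as a Poisson process at \code{usage_rate}
#' during an exponentially distributed releasable residence (rate
#' \code{k_inact}), the number of releases per lifetime is geometric:
#' \deqn{P(N = n) = q p^n, \quad q = \frac{k_i}{k_i + \lambda_u},\;
#'       p = \frac{\lambda_u}{k_i + \lambda_u}}
#' with mean \eqn{\lambda_u / k_i}. The probability mass is returned for
#' \eqn{n = 0, \ldots, n_{max}}; the analytic geometric tail is accounted
#' for in the mean, which is exact.
#'
#' @param params a \code{\link{kinetic_params}} object with a usage rate.
#' @param n_max largest release count tabulated. The default extends until
#'   the tail mass beyond \code{n_max} is below 1e-6.
#' @return an object of class \code{"usage_distribution"}: list with
#'   \code{n} (counts 0..n_max), \code{pmf}, \code{tail_mass} (analytic mass
#'   beyond n_max) and the exact \code{mean}.
#' @export
usage_distribution <- function(params, n_max = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  if (is.null(params$usage_rate))
    stop("usage_rate is not set; supply usage or burst parameters")
  ki <- params$k_inact; lu <- params$usage_rate
  p <- lu / (ki + lu)
  q <- ki / (ki + lu)
  if (is.null(n_max)) {
    n_max <- if (p == 0) 0L else max(0L, ceiling(log(1e-6) / log(p)))
  }
  n <- 0:n_max
  pmf <- q * p^n
  structure(list(n = n, pmf = pmf,
                 tail_mass = p^(n_max + 1),
                 mean = lu / ki),
            class = "usage_distribution")
}

#' @export
print.usage_distribution <- function(x, ...) {
  cat("Release rounds per lifetime (geometric law)\n")
  cat(sprintf("  mean: %.4g rounds; P(N = 0) = %.4g; tabulated to n = %d (tail %.2g)\n",
              x$mean, x$pmf[1L], max(x$n), x$tail_mass))
  invisible(x)
}

#' Cross-validated release rounds per lifetime
#'
#' The activity-based route to the usage headline: the mean time spent in
#' the releasable pool, in hours (\code{24 / k_inact}), multiplied by the
#' number of bursts per hour (\code{3600 * burst_rate}) and by the fraction
#' of the releasable pool that releases per burst. Algebraically identical
#' to the mean of \code{\link{usage_distribution}} when the usage rate
#' derives from the same burst parameters.
#'
#' @param params a \code{\link{kinetic_params}} object with burst parameters.
#' @return expected release rounds per lifetime.
#' @examples
#' cross_validated_usage(kinetic_params())  # ~210
#' @export
cross_validated_usage <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (is.null(params$burst_rate) || is.null(params$per_burst_fraction))
    stop("burst_rate and per_burst_fraction must be set")
  hours_releasable <- 24 / params$k_inact
  bursts_per_hour <- 3600 * params$burst_rate
  hours_releasable * bursts_per_hour * params$per_burst_fraction
}

#' Export a lifetime distribution as two-column delimited text
#'
#' Writes \code{grid} (days) and \code{density} (per day) as a two-column
#' tab-separated file with a header.
#'
#' @param dist a \code{lifetime_distribution} object.
#' @param path output path.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "lifetime_distribution"))
  utils::write.table(
    data.frame(time_days = dist$grid, density_per_day = dist$density),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
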