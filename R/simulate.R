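# Per-vesicle stochastic simulation of the three-state life cycle. Sampling
# is by the exact exponential inverse CDF (no time stepping), so the closed
# forms in kinetics.R are exact oracles for the simulated cohorts.

#' Simulate vesicle protein life histories
#'
#' Draws \code{n} independent trajectories of the three-state chain:
#' the inactivation time is exponential with rate \code{k_inact}, the
#' additional inactive residence exponential with rate \code{k_deg}, and
#' release events form a Poisson process at \code{usage_rate} restricted to
#' the releasable phase. The per-trajectory release count is always
#' recorded; the event times themselves are materialized only when
#' \code{keep_times = TRUE} (they are exchangeable uniforms over the
#' releasable phase, so most analyses need only the count).
#'
#' @param params a \code{\link{kinetic_params}} object.
#' @param n number of vesicles (>= 1).
#' @param seed integer seed; the simulation is bit-reproducible for a
#'   fixed seed.
#' @param keep_times materialize sorted release-time vectors per vesicle.
#' @return an object of class \code{"vesicle_trajectories"}: a data frame
#'   with columns \code{t_inact} (days), \code{t_deg} (days),
#'   \code{n_releases}, and, when requested, a list column
#'   \code{release_times} (sorted, each within [0, t_inact)).
#' @export
simulate_trajectories <- function(params, n, seed = NULL, keep_times = FALSE) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  t_inact <- stats::rexp(n, rate = params$k_inact)
  t_deg <- t_inact + stats::rexp(n, rate = params$k_deg)
  lu <- if (is.null(params$usage_rate)) 0 else params$usage_rate
  n_releases <- stats::rpois(n, lambda = lu * t_inact)
  out <- data.frame(t_inact = t_inact, t_deg = t_deg, n_releases = n_releases)
  if (keep_times) {
    out$release_times <- lapply(seq_len(n), function(i) {
      if (n_releases[i] == 0L) numeric(0)
      else sort(stats::runif(n_releases[i], 0, t_inact[i]))
    })
  }
  class(out) <- c("vesicle_trajectories", "data.frame")
  out
}

#' @export
print.vesicle_trajectories <- function(x, ...) {
  cat(sprintf("%d simulated vesicle trajectories\n", nrow(x)))
  cat(sprintf("  mean releasable residence: %.4g d; mean total residence: %.4g d\n",
              mean(x$t_inact), mean(x$t_deg)))
  cat(sprintf("  mean release rounds per lifetime: %.4g\n", mean(x$n_releases)))
  invisible(x)
}

#' Cohort time course from simulated trajectories
#'
#' Converts per-vesicle life histories into the pulse-chase observables:
#' the fraction of the cohort still releasable and the fraction still in
#' the synapse (releasable or inactive) at each requested time.
#'
#' @param trajectories a \code{\link{simulate_trajectories}} result.
#' @param times non-negative, increasing sampling times, days.
#' @return an object of class \code{"cohort_timecourse"}: list with
#'   \code{times}, \code{releasable_fraction}, \code{total_fraction},
#'   \code{n_vesicles}, \code{noise_sd} (0 for a noiseless cohort).
#' @export
cohort_timecourse <- function(trajectories, times) {
  stopifnot(inherits(trajectories, "vesicle_trajectories"))
  if (nrow(trajectories) == 0L) stop("empty trajectory set")
  if (any(times < 0) || any(diff(times) <= 0) && length(times) > 1L)
    stop("times must be non-negative and increasing")
  n <- nrow(trajectories)
  releasable <- vapply(times, function(t) sum(trajectories$t_inact > t) / n, numeric(1L))
  total <- vapply(times, function(t) sum(trajectories$t_deg > t) / n, numeric(1L))
  structure(list(times = times,
                 releasable_fraction = releasable,
                 total_fraction = total,
                 n_vesicles = n, noise_sd = 0),
            class = "cohort_timecourse")
}

#' Add replicate-style observation noise to a cohort time course
#'
#' Applies multiplicative Gaussian noise, \code{value * (1 + e)} with
#' \code{e ~ N(0, noise_sd^2)}, to both fraction series, clipping to
#' [0, 1.05] (normalized intensities can slightly exceed 1 through the
#' normalization itself, but not by more than 5\%).
#'
#' @param tc a \code{cohort_timecourse}.
#' @param noise_sd coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return a \code{cohort_timecourse} with \code{noise_sd} recorded.
#' @export
add_observation_noise <- function(tc, noise_sd, seed = NULL) {
  stopifnot(inherits(tc, "cohort_timecourse"))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("noise_sd must be a single non-negative number")
  if (noise_sd == 0) return(tc)
  if (!is.null(seed)) set.seed(seed)
  jitter1 <- 1 + stats::rnorm(length(tc$times), 0, noise_sd)
  jitter2 <- 1 + stats::rnorm(length(tc$times), 0, noise_sd)
  tc$releasable_fraction <- pmin(pmax(tc$releasable_fraction * jitter1, 0), 1.05)
  tc$total_fraction <- pmin(pmax(tc$total_fraction * jitter2, 0), 1.05)
  tc$noise_sd <- noise_sd
  tc
}

#' Convert a cohort time course to Timecourse tables
#'
#' Returns the fitting module's long-format table (columns \code{time},
#' \code{value}, \code{replicate}, \code{condition}) for one series of a
#' simulated cohort.
#'
#' @param tc a \code{cohort_timecourse}.
#' @param series \code{"releasable"} or \code{"total"}.
#' @param replicate replicate label.
#' @return a \code{data.frame} consumable by the fitting functions.
#' @export
as_timecourse <- function(tc, series = c("releasable", "total"), replicate = 1L) {
  stopifnot(inherits(tc, "cohort_timecourse"))
  series <- match.arg(series)
  value <- if (series == "releasable") tc$releasable_fraction else tc$total_fraction
  data.frame(time = tc$times, value = value,
             replicate = replicate, condition = series)
}

#' Export simulated trajectories as delimited text
#'
#' One row per vesicle: \code{t_inact}, \code{t_deg}, \code{n_releases}.
#'
#' @param trajectories a \code{vesicle_trajectories} object.
#' @param path output path (tab-separated, with header).
#' @export
write_trajectories <- function(trajectories, path) {
  stopifnot(inherits(trajectories, "vesicle_trajectories"))
  utils::write.table(
    trajectories[, c("t_inact", "t_deg", "n_releases")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
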