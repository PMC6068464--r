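#' Kinetic parameters of the vesicle protein life cycle
#'
#' Constructs the parameter set of the three-state life-cycle model
#' (releasable -> inactive -> degraded). Vesicle proteins leave the
#' releasable pool at rate \code{k_inact} (per day) and inactive proteins
#' are degraded at rate \code{k_deg} (per day). While releasable, a vesicle
#' undergoes release events as a Poisson process at \code{usage_rate}
#' (events per day). Usage can equivalently be specified through network
#' activity: bursts occur at \code{burst_rate} (Hz) and each burst releases
#' a releasable vesicle with probability \code{per_burst_fraction}, so that
#' \code{usage_rate = burst_rate * per_burst_fraction * 86400}.
#'
#' The defaults encode the fitted culture values: a releasable-pool time
#' constant of 0.4 days (\code{k_inact = 2.5} per day), a mean total
#' synaptic residence of 1.6 days (hence a mean inactive residence of
#' 1.2 days, \code{k_deg = 1/1.2} per day), a spontaneous burst rate of
#' 0.09 Hz, and a per-burst release fraction of 0.0675.
#'
#' @param k_inact inactivation rate, per day (reciprocal of the releasable
#'   time constant). Default \code{1/0.4}.
#' @param k_deg degradation rate of inactive vesicles, per day. Default
#'   \code{1/(1.6 - 0.4)}.
#' @param burst_rate network burst frequency, Hz, or \code{NULL}.
#' @param per_burst_fraction probability that a releasable vesicle releases
#'   in one burst, in [0, 1], or \code{NULL}.
#' @param usage_rate release-event rate while releasable, per day. Computed
#'   from the burst parameters when \code{NULL} and both are given.
#' @return An object of class \code{"kinetic_params"}: a list with fields
#'   \code{k_inact}, \code{k_deg}, \code{usage_rate}, \code{burst_rate},
#'   \code{per_burst_fraction}.
#' @examples
#' p <- kinetic_params()
#' p$usage_rate / p$k_inact  # mean release rounds per lifetime, ~210
#' @export
kinetic_params <- function(k_inact = 1 / 0.4,
                           k_deg = 1 / (1.6 - 0.4),
                           burst_rate = 0.09,
                           per_burst_fraction = 0.0675,
                           usage_rate = NULL) {
  if (!is.numeric(k_inact) || length(k_inact) != 1L || !is.finite(k_inact) || k_inact <= 0)
    stop("k_inact must be a single strictly positive rate (per day)")
  if (!is.numeric(k_deg) || length(k_deg) != 1L || !is.finite(k_deg) || k_deg <= 0)
    stop("k_deg must be a single strictly positive rate (per day)")
  if (!is.null(burst_rate)) {
    if (!is.numeric(burst_rate) || length(burst_rate) != 1L || burst_rate < 0)
      stop("burst_rate must be a single non-negative frequency (Hz)")
  }
  if (!is.null(per_burst_fraction)) {
    if (!is.numeric(per_burst_fraction) || length(per_burst_fraction) != 1L ||
        per_burst_fraction < 0 || per_burst_fraction > 1)
      stop("per_burst_fraction must lie in [0, 1]")
  }
  if (is.null(usage_rate)) {
    if (!is.null(burst_rate) && !is.null(per_burst_fraction))
      usage_rate <- usage_rate_from_bursts(burst_rate, per_burst_fraction)
  } else {
    if (!is.numeric(usage_rate) || length(usage_rate) != 1L || usage_rate < 0)
      stop("usage_rate must be a single non-negative rate (per day)")
    if (!is.null(burst_rate) && !is.null(per_burst_fraction)) {
      implied <- usage_rate_from_bursts(burst_rate, per_burst_fraction)
      if (implied > 0 && abs(usage_rate - implied) > 1e-9 * implied)
        stop("usage_rate inconsistent with burst_rate * per_burst_fraction * 86400")
      if (implied == 0 && usage_rate != 0)
        stop("usage_rate inconsistent with burst_rate * per_burst_fraction * 86400")
    }
  }
  structure(list(k_inact = k_inact, k_deg = k_deg,
                 usage_rate = usage_rate,
                 burst_rate = burst_rate,
                 per_burst_fraction = per_burst_fraction),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Vesicle life-cycle kinetic parameters\n")
  cat(sprintf("  k_inact: %.4g /day   (releasable time constant %.4g d)\n",
              x$k_inact, 1 / x$k_inact))
  cat(sprintf("  k_deg:   %.4g /day   (inactive time constant %.4g d; total residence %.4g d)\n",
              x$k_deg, 1 / x$k_deg, 1 / x$k_inact + 1 / x$k_deg))
  if (!is.null(x$burst_rate))
    cat(sprintf("  bursts:  %.4g Hz, per-burst release fraction %.4g\n",
                x$burst_rate, x$per_burst_fraction))
  if (!is.null(x$usage_rate))
    cat(sprintf("  usage:   %.4g releases/day while releasable (mean %.4g per lifetime)\n",
                x$usage_rate, x$usage_rate / x$k_inact))
  invisible(x)
}

#' Build kinetic parameters from printed pulse-chase time constants
#'
#' Maps the two measured time constants to model rates. The releasable
#' constant always gives \code{k_inact = 1/tau_active}. The longer
#' constant is ambiguous: under \code{"total-mean"} (default) it is read
#' as the mean total synaptic residence, so the inactive phase lasts
#' \code{tau_total - tau_active} on average and
#' \code{k_deg = 1/(tau_total - tau_active)}; under
#' \code{"slow-eigenvalue"} it is read as the slow exponential constant of
#' the retention curve itself, so \code{k_deg = 1/tau_total}.
#'
#' @param tau_active releasable-pool time constant, days.
#' @param tau_total the longer retention time constant, days
#'   (> \code{tau_active}).
#' @param interpretation how to read \code{tau_total} (see above).
#' @param ... further arguments passed to \code{\link{kinetic_params}}
#'   (burst parameters).
#' @return a \code{\link{kinetic_params}} object.
#' @examples
#' params_from_time_constants(0.4, 1.6)$k_deg                       # 0.833
#' params_from_time_constants(0.4, 1.6, "slow-eigenvalue")$k_deg    # 0.625
#' @export
params_from_time_constants <- function(tau_active = 0.4, tau_total = 1.6,
                                       interpretation = c("total-mean",
                                                          "slow-eigenvalue"),
                                       ...) {
  interpretation <- match.arg(interpretation)
  if (tau_total <= tau_active)
    stop("tau_total must exceed tau_active")
  k_deg <- switch(interpretation,
                  "total-mean" = 1 / (tau_total - tau_active),
                  "slow-eigenvalue" = 1 / tau_total)
  kinetic_params(k_inact = 1 / tau_active, k_deg = k_deg, ...)
}

#' Convert burst activity to a per-day usage rate
#'
#' Network bursts at \code{burst_rate} Hz, each releasing a given releasable
#' vesicle with probability \code{per_burst_fraction}, thin the Poisson
#' burst stream into a Poisson release stream; the per-day release rate is
#' simply \code{burst_rate * per_burst_fraction * 86400}.
#'
#' @param burst_rate burst frequency, Hz (non-negative).
#' @param per_burst_fraction per-burst release probability in [0, 1].
#' @return release-event rate per vesicle, per day.
#' @examples
#' usage_rate_from_bursts(0.09, 0.0675)  # 524.88 /day
#' @export
usage_rate_from_bursts <- function(burst_rate, per_burst_fraction) {
  if (!is.numeric(burst_rate) || any(burst_rate < 0))
    stop("burst_rate must be non-negative")
  if (!is.numeric(per_burst_fraction) ||
      any(per_burst_fraction < 0 | per_burst_fraction > 1))
    stop("per_burst_fraction must lie in [0, 1]")
  burst_rate * per_burst_fraction * 86400
}

#' Scale neuronal activity up or down
#'
#' Returns a parameter set for a culture whose network activity is scaled
#' by \code{multiplier}. In the default usage-coupled variant both the
#' burst rate (hence the usage rate) and the inactivation rate scale, so
#' vesicles that are used more often are also inactivated sooner and the
#' mean number of release rounds per lifetime is unchanged. The
#' alternative variant (\code{couple_usage = FALSE}) scales only
#' \code{k_inact}.
#'
#' @param params a \code{\link{kinetic_params}} object.
#' @param multiplier activity scale factor, strictly positive.
#' @param couple_usage if \code{TRUE} (default) scale burst/usage rates
#'   together with \code{k_inact}; if \code{FALSE} scale \code{k_inact} only.
#' @return a \code{kinetic_params} object.
#' @export
modulate_activity <- function(params, multiplier, couple_usage = TRUE) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.numeric(multiplier) || length(multiplier) != 1L ||
      !is.finite(multiplier) || multiplier <= 0)
    stop("multiplier must be a single strictly positive number")
  kinetic_params(
    k_inact = params$k_inact * multiplier,
    k_deg = params$k_deg,
    burst_rate = if (couple_usage && !is.null(params$burst_rate))
      params$burst_rate * multiplier else params$burst_rate,
    per_burst_fraction = params$per_burst_fraction,
    usage_rate = if (is.null(params$usage_rate)) NULL
      else if (couple_usage) params$usage_rate * multiplier
      else params$usage_rate)
}

#' Read/write kinetic parameters as flat JSON
#'
#' The on-disk form is a flat JSON document with keys
#' \code{k_inact_per_day}, \code{k_deg_per_day}, \code{burst_rate_hz},
#' \code{per_burst_fraction}.
#'
#' @param params a \code{kinetic_params} object.
#' @param path file path.
#' @return \code{read_params} returns a \code{kinetic_params} object;
#'   \code{write_params} returns \code{path} invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "kinetic_params"))
  doc <- list(k_inact_per_day = params$k_inact,
              k_deg_per_day = params$k_deg,
              burst_rate_hz = params$burst_rate,
              per_burst_fraction = params$per_burst_fraction)
  doc <- doc[!vapply(doc, is.null, logical(1L))]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  kinetic_params(k_inact = doc$k_inact_per_day,
                 k_deg = doc$k_deg_per_day,
                 burst_rate = doc$burst_rate_hz,
                 per_burst_fraction = doc$per_burst_fraction)
}
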