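# Pulse-chase decay fitting. Both fitters are nonlinear least squares
# (Levenberg-Marquardt via minpack.lm) with multi-start initialization over
# log-spaced time constants, returning a classed "svl_fit" object with the
# usual modelling methods.

# multi-start grid for the decay time constant, days
.TAU_STARTS <- c(0.1, 0.3, 1, 3, 10)

#' Read and write pulse-chase time-course tables
#'
#' The on-disk form is delimited text with header
#' \code{time_days,value,replicate,condition}; in memory the table uses
#' columns \code{time} (days), \code{value} (normalized intensity),
#' \code{replicate}, \code{condition}.
#'
#' @param path file path.
#' @param tc a time-course \code{data.frame}.
#' @return \code{read_timecourse} returns the \code{data.frame}.
#' @export
read_timecourse <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_days", "value", "replicate", "condition")
  if (!all(need %in% names(df)))
    stop("expected header time_days,value,replicate,condition")
  data.frame(time = df$time_days, value = df$value,
             replicate = df$replicate, condition = df$condition)
}

#' @rdname read_timecourse
#' @export
write_timecourse <- function(tc, path) {
  tc <- validate_timecourse(tc)
  utils::write.csv(
    data.frame(time_days = tc$time, value = tc$value,
               replicate = tc$replicate, condition = tc$condition),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_timecourse <- function(tc, min_times = 3L) {
  if (!is.data.frame(tc) || !all(c("time", "value") %in% names(tc)))
    stop("a timecourse needs columns time and value")
  if (!"replicate" %in% names(tc)) tc$replicate <- 1L
  if (!"condition" %in% names(tc)) tc$condition <- "default"
  if (any(tc$time < 0)) stop("times must be non-negative")
  if (any(!is.finite(tc$value))) stop("values must be finite")
  if (length(unique(tc$time)) < min_times)
    stop(sprintf("at least %d distinct time points are required", min_times))
  tc
}

#' Fit a single-exponential decay to a pulse-chase time course
#'
#' Least-squares fit of \eqn{A e^{-t/\tau} + b} to normalized intensities,
#' pooling all replicates with equal weight. The plateau \code{b} is fixed
#' at 0 unless \code{with_plateau = TRUE}. Each of the five log-spaced
#' time-constant starts (0.1, 0.3, 1, 3, 10 days) is refined by
#' Levenberg-Marquardt and the lowest-SSE solution is kept; if no start
#' converges the best attempt is still returned with
#' \code{converged = FALSE} rather than an error.
#'
#' @param tc time-course table (columns \code{time} in days, \code{value};
#'   optional \code{replicate}, \code{condition}).
#' @param with_plateau estimate an additive plateau \code{b}.
#' @return an object of class \code{"svl_fit"} with \code{estimates}
#'   (named: \code{tau} days, \code{A}, and \code{b} if fitted),
#'   \code{sse}, \code{n_starts}, \code{converged}, \code{model}, and the
#'   data used.
#' @examples
#' tc <- data.frame(time = 0:10, value = exp(-(0:10) / 1.6))
#' coef(fit_exponential_decay(tc))["tau"]
#' @export
fit_exponential_decay <- function(tc, with_plateau = FALSE) {
  tc <- validate_timecourse(tc)
  t <- tc$time; y <- tc$value
  resid_fun <- function(par) {
    tau <- exp(par[["log_tau"]])
    b <- if (with_plateau) par[["b"]] else 0
    y - (par[["A"]] * exp(-t / tau) + b)
  }
  best <- NULL
  for (tau0 in .TAU_STARTS) {
    start <- c(log_tau = log(tau0), A = max(y), b = if (with_plateau) min(y) else NULL)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.list(start), fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    ok <- fit$info %in% 1:4
    if (is.null(best) || sse < best$sse) {
      best <- list(par = fit$par, sse = sse, converged = ok)
    }
  }
  if (is.null(best)) stop("all optimizer starts failed to evaluate")
  est <- c(tau = exp(best$par$log_tau), A = best$par$A)
  if (with_plateau) est <- c(est, b = best$par$b)
  new_svl_fit(estimates = est, sse = best$sse, converged = best$converged,
              n_starts = length(.TAU_STARTS), model = "single-exponential",
              data = tc, with_plateau = with_plateau)
}

#' Jointly fit the two-state life-cycle model to paired time courses
#'
#' Fits the releasable-survival and total-retention closed forms
#' simultaneously over \code{(k_inact, k_deg)} by unweighted least squares
#' (both series equally weighted), with multi-start log-spaced rate
#' initializations. Both series are assumed normalized to 1 at t = 0 up to
#' noise. Physically the releasable pool empties faster than the inactive
#' pool degrades (\code{k_inact > k_deg}); a fit violating that ordering is
#' returned with \code{physical = FALSE} (the usual cause is swapped
#' inputs).
#'
#' @param releasable_tc time course of the releasable fraction.
#' @param total_tc time course of the total synaptic retention.
#' @return an \code{"svl_fit"} with estimates \code{k_inact}, \code{k_deg}
#'   (per day) plus derived \code{tau_active} and \code{tau_total} (days),
#'   and a \code{physical} flag.
#' @export
fit_two_state <- function(releasable_tc, total_tc) {
  rtc <- validate_timecourse(releasable_tc)
  ttc <- validate_timecourse(total_tc)
  resid_fun <- function(par) {
    p <- kinetic_params(k_inact = exp(par[["log_ki"]]),
                        k_deg = exp(par[["log_kd"]]),
                        burst_rate = NULL, per_burst_fraction = NULL)
    c(rtc$value - releasable_survival(p, rtc$time),
      ttc$value - total_retention(p, ttc$time))
  }
  starts <- expand.grid(ki = c(0.5, 2.5, 8), kd = c(0.2, 0.8, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = list(log_ki = log(starts$ki[i]),
                                    log_kd = log(starts$kd[i])),
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = fit$par, sse = sse, converged = fit$info %in% 1:4)
  }
  if (is.null(best)) stop("all optimizer starts failed to evaluate")
  ki <- exp(best$par$log_ki); kd <- exp(best$par$log_kd)
  est <- c(k_inact = ki, k_deg = kd,
           tau_active = 1 / ki, tau_total = 1 / ki + 1 / kd)
  fit <- new_svl_fit(estimates = est, sse = best$sse, converged = best$converged,
                     n_starts = nrow(starts), model = "two-state",
                     data = list(releasable = rtc, total = ttc))
  fit$physical <- ki > kd
  if (!fit$physical)
    warning("non-physical ordering k_inact <= k_deg; inputs may be swapped")
  fit
}

new_svl_fit <- function(estimates, sse, converged, n_starts, model, data,
                        with_plateau = FALSE) {
  structure(list(estimates = estimates, sse = sse, converged = converged,
                 n_starts = n_starts, model = model, data = data,
                 with_plateau = with_plateau,
                 ci_low = NULL, ci_high = NULL),
            class = "svl_fit")
}

#' Bootstrap confidence intervals for a decay fit
#'
#' Case-resampling bootstrap over replicates: whole replicate series are
#' resampled with replacement, the model refitted, and percentile 95\%
#' intervals attached to the fit. With a single replicate the interval is
#' degenerate and a warning is recorded on the result.
#'
#' @param tc the time-course table to resample.
#' @param with_plateau passed to \code{\link{fit_exponential_decay}}.
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed (fixed seed gives identical intervals).
#' @return an \code{"svl_fit"} with \code{ci_low}/\code{ci_high} per
#'   parameter.
#' @export
bootstrap_ci <- function(tc, with_plateau = FALSE, B = 500L, seed = NULL) {
  tc <- validate_timecourse(tc)
  if (B < 100L) stop("B must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_exponential_decay(tc, with_plateau = with_plateau)
  reps <- unique(tc$replicate)
  single <- length(reps) < 2L
  draws <- matrix(NA_real_, nrow = B, ncol = length(fit$estimates),
                  dimnames = list(NULL, names(fit$estimates)))
  for (b in seq_len(B)) {
    take <- sample(reps, length(reps), replace = TRUE)
    boot_tc <- do.call(rbind, lapply(seq_along(take), function(j) {
      part <- tc[tc$replicate == take[j], , drop = FALSE]
      part$replicate <- j
      part
    }))
    bf <- tryCatch(fit_exponential_decay(boot_tc, with_plateau = with_plateau),
                   error = function(e) NULL)
    if (!is.null(bf)) draws[b, ] <- bf$estimates
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  fit$ci_low <- apply(draws, 2L, stats::quantile, probs = 0.025, names = FALSE)
  fit$ci_high <- apply(draws, 2L, stats::quantile, probs = 0.975, names = FALSE)
  fit$B <- nrow(draws)
  if (single) {
    fit$degenerate_ci <- TRUE
    warning("single replicate: bootstrap interval is degenerate")
  }
  fit
}

# ---- svl_fit methods --------------------------------------------------------

#' @export
coef.svl_fit <- function(object, ...) object$estimates

#' @export
print.svl_fit <- function(x, ...) {
  cat(sprintf("Pulse-chase fit (%s model)%s\n", x$model,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  est <- x$estimates
  for (nm in names(est)) {
    line <- sprintf("  %-10s %.5g", nm, est[[nm]])
    if (!is.null(x$ci_low))
      line <- sprintf("%s  [%.5g, %.5g]", line, x$ci_low[[nm]], x$ci_high[[nm]])
    cat(line, "\n")
  }
  cat(sprintf("  SSE %.5g over %d starts\n", x$sse, x$n_starts))
  if (!is.null(x$physical) && !x$physical)
    cat("  WARNING: non-physical rate ordering (k_inact <= k_deg)\n")
  invisible(x)
}

#' @export
summary.svl_fit <- function(object, ...) {
  print(object)
  if (object$model == "single-exponential") {
    r <- residuals(object)
    cat(sprintf("  residual sd: %.4g over %d observations\n",
                stats::sd(r), length(r)))
  }
  invisible(object)
}

#' @export
predict.svl_fit <- function(object, newdata = NULL, ...) {
  if (object$model == "single-exponential") {
    t <- if (is.null(newdata)) object$data$time else newdata$time
    est <- object$estimates
    b <- if (object$with_plateau) est[["b"]] else 0
    est[["A"]] * exp(-t / est[["tau"]]) + b
  } else {
    t <- if (is.null(newdata)) object$data$releasable$time else newdata$time
    p <- kinetic_params(k_inact = object$estimates[["k_inact"]],
                        k_deg = object$estimates[["k_deg"]],
                        burst_rate = NULL, per_burst_fraction = NULL)
    cbind(releasable = releasable_survival(p, t),
          total = total_retention(p, t))
  }
}

#' @export
residuals.svl_fit <- function(object, ...) {
  if (object$model == "single-exponential") {
    object$data$value - predict(object)
  } else {
    p <- kinetic_params(k_inact = object$estimates[["k_inact"]],
                        k_deg = object$estimates[["k_deg"]],
                        burst_rate = NULL, per_burst_fraction = NULL)
    c(object$data$releasable$value -
        releasable_survival(p, object$data$releasable$time),
      object$data$total$value -
        total_retention(p, object$data$total$time))
  }
}

#' @export
plot.svl_fit <- function(x, ...) {
  if (x$model == "single-exponential") {
    graphics::plot(x$data$time, x$data$value, xlab = "time (days)",
                   ylab = "normalized intensity", ...)
    tt <- seq(0, max(x$data$time), length.out = 200L)
    graphics::lines(tt, predict(x, data.frame(time = tt)))
  } else {
    tt <- seq(0, max(x$data$total$time), length.out = 200L)
    pr <- predict(x, data.frame(time = tt))
    graphics::plot(x$data$total$time, x$data$total$value,
                   xlab = "time (days)", ylab = "fraction",
                   ylim = c(0, 1.05), ...)
    graphics::points(x$data$releasable$time, x$data$releasable$value, pch = 2)
    graphics::lines(tt, pr[, "total"]); graphics::lines(tt, pr[, "releasable"], lty = 2)
  }
  invisible(x)
}

#' Export a fit result as JSON
#'
#' @param fit an \code{svl_fit}.
#' @param path output path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "svl_fit"))
  doc <- list(model = fit$model,
              estimates = as.list(fit$estimates),
              sse = fit$sse, n_starts = fit$n_starts,
              converged = fit$converged)
  if (!is.null(fit$ci_low)) {
    doc$ci_low <- as.list(fit$ci_low)
    doc$ci_high <- as.list(fit$ci_high)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
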