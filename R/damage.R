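# Damage-accumulation extrapolation: given per-protein turnover lifetimes
# (taken as proxies for damage times, assuming degradation follows damage),
# how much of a vesicle's protein complement is damaged by a given age, and
# in particular at the moment of inactivation.

#' Per-protein copy number and lifetime table
#'
#' Validates a table with one row per vesicle protein: \code{name},
#' \code{copies} (copies per vesicle, >= 1) and \code{lifetime} (mean
#' turnover lifetime, days, > 0). Copy weights \code{copies / sum(copies)}
#' are used downstream unless unweighted averaging is requested.
#'
#' @param df data frame with columns \code{name}, \code{copies},
#'   \code{lifetime}.
#' @return the validated data frame with class \code{"protein_table"}.
#' @export
protein_table <- function(df) {
  if (!is.data.frame(df) || !all(c("name", "copies", "lifetime") %in% names(df)))
    stop("expected columns name, copies, lifetime")
  if (nrow(df) == 0L) stop("protein table is empty")
  if (any(df$copies < 1)) stop("copies must be >= 1")
  if (any(df$lifetime <= 0)) stop("lifetimes must be positive (days)")
  class(df) <- c("protein_table", "data.frame")
  df
}

#' Read a protein table from delimited text
#'
#' Expects header \code{name,copies,lifetime_days}.
#'
#' @param path file path.
#' @return a \code{\link{protein_table}}.
#' @export
read_protein_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "copies", "lifetime_days") %in% names(df)))
    stop("expected header name,copies,lifetime_days")
  protein_table(data.frame(name = df$name, copies = df$copies,
                           lifetime = df$lifetime_days))
}

#' Damage-onset model
#'
#' The memoryless (\code{"exponential"}) variant damages a protein copy at
#' a constant hazard \code{1/lifetime}; the \code{"staged"} variant makes
#' damage the completion of \code{stages} sequential exponential steps
#' (a gamma waiting time with the same mean), giving a delayed, sharper
#' onset. \code{stages = 1} reduces exactly to the exponential variant.
#'
#' @param variant \code{"staged"} (default) or \code{"exponential"}.
#' @param stages number of damage stages m (>= 1) for the staged variant.
#' @return a \code{"damage_model"} object.
#' @export
damage_model <- function(variant = c("staged", "exponential"), stages = 3L) {
  variant <- match.arg(variant)
  if (variant == "exponential") stages <- 1L
  if (stages < 1 || stages != round(stages)) stop("stages must be a positive integer")
  structure(list(variant = variant, stages = as.integer(stages)),
            class = "damage_model")
}

#' Probability a protein copy is damaged by age t
#'
#' Exponential variant: \eqn{1 - e^{-t/\ell}}; staged variant: the CDF of
#' a Gamma(\eqn{m}, rate \eqn{m/\ell}) waiting time — same mean damage
#' time \eqn{\ell}, sharper onset.
#'
#' @param t age(s), days, non-negative.
#' @param lifetime mean damage (turnover) lifetime, days, > 0.
#' @param model a \code{\link{damage_model}}.
#' @return probability/probabilities in [0, 1].
#' @export
damage_probability <- function(t, lifetime, model = damage_model()) {
  stopifnot(inherits(model, "damage_model"))
  if (lifetime <= 0) stop("lifetime must be positive")
  if (any(t < 0)) stop("t must be non-negative")
  m <- model$stages
  stats::pgamma(t, shape = m, rate = m / lifetime)
}

#' Expected damaged fraction of a vesicle at inactivation
#'
#' The inactivation age is exponential with rate \code{k_inact}; the
#' expected damaged fraction of the protein complement is the copy-weighted
#' mean of \eqn{E[F_p(T)]} over proteins p, with \eqn{F_p} the damage CDF.
#' For m damage stages at rate \eqn{r = m/\ell} this expectation has the
#' closed series
#' \deqn{1 - \sum_{j=0}^{m-1} \frac{k_i\, r^j}{(k_i + r)^{j+1}}}
#' (the exponential variant is the m = 1 case, \eqn{k_p/(k_p + k_i)} with
#' \eqn{k_p = 1/\ell}). A Gauss-Legendre style quadrature route is exposed
#' for cross-checking the series.
#'
#' @param table a \code{\link{protein_table}}.
#' @param params a \code{\link{kinetic_params}} object (only
#'   \code{k_inact} is used).
#' @param model a \code{\link{damage_model}}.
#' @param weighted copy-weight proteins (default) or average them equally.
#' @param method \code{"series"} (analytic, default) or
#'   \code{"quadrature"} (numerical integration over the inactivation-age
#'   density).
#' @return expected damaged fraction in [0, 1].
#' @export
expected_damaged_at_inactivation <- function(table, params,
                                             model = damage_model(),
                                             weighted = TRUE,
                                             method = c("series", "quadrature")) {
  stopifnot(inherits(table, "protein_table"), inherits(params, "kinetic_params"),
            inherits(model, "damage_model"))
  method <- match.arg(method)
  ki <- params$k_inact
  w <- if (weighted) table$copies / sum(table$copies)
       else rep(1 / nrow(table), nrow(table))
  per_protein <- vapply(table$lifetime, function(ell) {
    r <- model$stages / ell
    if (method == "series") {
      j <- 0:(model$stages - 1L)
      1 - sum(ki * r^j / (ki + r)^(j + 1L))
    } else {
      stats::integrate(function(t) {
        ki * exp(-ki * t) * damage_probability(t, ell, model)
      }, 0, Inf, rel.tol = 1e-10)$value
    }
  }, numeric(1L))
  sum(w * per_protein)
}

#' Cumulative vesicle damage time course
#'
#' Copy-weighted mean damaged fraction of the vesicle protein complement
#' as a function of vesicle age; monotone non-decreasing from 0 toward 1.
#'
#' @param table a \code{\link{protein_table}}.
#' @param grid increasing age grid starting at 0, days.
#' @param model a \code{\link{damage_model}}.
#' @param weighted copy-weight proteins (default) or average equally.
#' @return data frame with \code{age_days} and \code{damaged_fraction}.
#' @export
damage_timecourse <- function(table, grid, model = damage_model(),
                              weighted = TRUE) {
  stopifnot(inherits(table, "protein_table"), inherits(model, "damage_model"))
  if (grid[1L] != 0 || (length(grid) > 1L && any(diff(grid) <= 0)))
    stop("grid must increase from 0")
  w <- if (weighted) table$copies / sum(table$copies)
       else rep(1 / nrow(table), nrow(table))
  curves <- vapply(seq_len(nrow(table)), function(i) {
    damage_probability(grid, table$lifetime[i], model)
  }, numeric(length(grid)))
  curve <- as.numeric(matrix(curves, ncol = nrow(table)) %*% w)
  data.frame(age_days = grid, damaged_fraction = curve)
}
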