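# First-order decay kinetics: the factorized rate law linking seam-access
# probabilities to excited-state lifetimes, rate-law integration, and
# monoexponential fitting.

#' First-order decay model
#'
#' A set of parallel decay channels with rate constants
#' \eqn{\kappa_j = c_j P_j}, where \eqn{c_j} is an effective electronic
#' coupling scale and \eqn{P_j} the probability of the vibrationless state to
#' reach the j-th CI seam. The population obeys
#' \eqn{dP(t)/dt = -\sum_j \kappa_j P(t)}, hence monoexponential decay with
#' lifetime \eqn{\tau = 1/\sum_j \kappa_j}. Rates carry an explicit time
#' unit tag to keep simulation (fs) and experimental (ns) scales from mixing
#' silently.
#'
#' @param rates channel rate constants (>= 0), or `NULL` to build them as
#'   `coupling_scale * access_p`.
#' @param coupling_scale per-channel effective coupling factor (default 1:
#'   couplings of like electronic states are assumed comparable).
#' @param access_p per-channel seam-access probability in (0, 1].
#' @param unit time unit of the rates: `"fs"` or `"ns"` (rates are per unit).
#' @return object of class `decay_model` with fields `rates`, `total_rate`,
#'   `lifetime`, `unit`.
#' @export
decay_model <- function(rates = NULL, coupling_scale = 1, access_p = NULL,
                        unit = c("fs", "ns")) {
  unit <- match.arg(unit)
  if (is.null(rates)) {
    stopifnot(!is.null(access_p))
    if (any(access_p <= 0 | access_p > 1)) {
      stop("access probabilities must lie in (0, 1]", call. = FALSE)
    }
    rates <- rep_len(coupling_scale, length(access_p)) * access_p
  }
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  total <- sum(rates)
  structure(
    list(rates = as.numeric(rates), total_rate = total,
         lifetime = if (total > 0) 1 / total else Inf, unit = unit),
    class = "decay_model"
  )
}

#' @export
print.decay_model <- function(x, ...) {
  cat("<decay_model> ", length(x$rates), " channel(s); total rate ",
      format(x$total_rate, digits = 6), " /", x$unit, "; lifetime ",
      format(x$lifetime, digits = 6), " ", x$unit, "\n", sep = "")
  invisible(x)
}

#' Integrate the first-order rate law
#'
#' \eqn{P(t) = \exp(-t \sum_j \kappa_j)}: channels are additive, so two
#' channels of rate k/2 give the same trace as one of rate k.
#'
#' @param model a `decay_model`.
#' @param t_grid ascending time grid starting at 0 (in the model's unit).
#' @return tibble with columns `time`, `population`.
#' @export
integrate_rate_law <- function(model, t_grid) {
  stopifnot(inherits(model, "decay_model"))
  t_grid <- as.numeric(t_grid)
  if (is.unsorted(t_grid) || t_grid[1] < 0) {
    stop("t_grid must ascend from 0", call. = FALSE)
  }
  tibble::tibble(time = t_grid, population = exp(-model$total_rate * t_grid))
}

#' Fit a monoexponential decay
#'
#' Nonlinear least squares of \eqn{P(t) = e^{-\kappa t}} initialized by the
#' log-linear regression of \eqn{\log P} on t (the nonlinear refit avoids the
#' bias the log transform gives noise at small populations). Noiseless traces
#' are recovered to machine precision.
#'
#' @param trace data frame with columns `time` and `population` (>= 3 points,
#'   populations in (0, 1]).
#' @return object of class `decay_fit` with fields `kappa`, `tau`, `sigma`
#'   (residual standard error), `n`, `degenerate` (flag for a trace with no
#'   usable decay signal), `fit` (the `nls` object or NULL).
#' @export
fit_monoexponential <- function(trace) {
  stopifnot(all(c("time", "population") %in% names(trace)))
  t <- as.numeric(trace$time)
  p <- as.numeric(trace$population)
  if (length(t) < 3) stop("need at least 3 points", call. = FALSE)
  pos <- p > 0
  if (sum(pos) < 3) {
    stop("need at least 3 positive populations to initialize the fit", call. = FALSE)
  }
  # log-linear initialization through the origin (positive points only):
  # log P = -kappa t
  tt <- sum(t[pos]^2)
  k0 <- if (tt > 0) -sum(t[pos] * log(p[pos])) / tt else 0
  degenerate <- FALSE
  fit <- NULL
  resid0 <- sqrt(mean((p - exp(-k0 * t))^2))
  if (resid0 < 1e-12 || k0 <= 0) {
    kappa <- max(k0, 0)
    if (k0 <= 0 && stats::sd(p) < 1e-12) degenerate <- TRUE
  } else {
    fit <- minpack.lm::nlsLM(population ~ exp(-kappa * time),
                             data = data.frame(time = t, population = p),
                             start = list(kappa = k0),
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200, ftol = 1e-15, ptol = 1e-15))
    kappa <- unname(stats::coef(fit)[["kappa"]])
  }
  structure(
    list(kappa = kappa, tau = if (kappa > 0) 1 / kappa else Inf,
         sigma = sqrt(mean((p - exp(-kappa * t))^2)), n = length(t),
         degenerate = degenerate, fit = fit),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> kappa = ", format(x$kappa, digits = 8), ", tau = ",
      format(x$tau, digits = 8), " (n = ", x$n,
      if (x$degenerate) ", degenerate" else "", ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a monoexponential decay fit
#'
#' @param x a `decay_fit`.
#' @param ... unused.
#' @return one-row tibble per parameter (`term`, `estimate`, `std.error`).
#' @export
tidy.decay_fit <- function(x, ...) {
  se <- if (!is.null(x$fit)) {
    summary(x$fit)$coefficients["kappa", "Std. Error"]
  } else NA_real_
  tibble::tibble(term = "kappa", estimate = x$kappa, std.error = se)
}

#' @rdname tidy.decay_fit
#' @return `glance()`: one-row tibble with `kappa`, `tau`, `sigma`, `n`,
#'   `degenerate`.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, tau = x$tau, sigma = x$sigma, n = x$n,
                 degenerate = x$degenerate)
}

#' Plot a decay fit
#'
#' @param object a `decay_fit`.
#' @param trace the trace it was fitted to.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.decay_fit <- function(object, trace = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(trace)) {
    p <- p + ggplot2::geom_point(
      data = trace, ggplot2::aes(x = .data$time, y = .data$population),
      alpha = 0.5)
    tmax <- max(trace$time)
  } else tmax <- 5 * object$tau
  curve <- tibble::tibble(time = seq(0, tmax, length.out = 200))
  curve$population <- exp(-object$kappa * curve$time)
  p + ggplot2::geom_line(data = curve,
                         ggplot2::aes(x = .data$time, y = .data$population),
                         colour = "#d7301f") +
    ggplot2::labs(x = "time", y = "population",
                  subtitle = sprintf("kappa = %.4g, tau = %.4g",
                                     object$kappa, object$tau))
}

#' Lifetime factor between two systems from seam-access probabilities
#'
#' Under the factorized rate law with comparable electronic couplings, the
#' decay rates scale as the access probabilities, so the lifetime of system b
#' relative to system a is \eqn{\tau_b / \tau_a = P_a / P_b}. A fully
#' accessible seam (P = 1) against one reachable only by tunneling with
#' P = 0.10 gives a 10-fold lifetime increase.
#'
#' @param p_a,p_b access probabilities in (0, 1]; `p_b = 0` flags an infinite
#'   lifetime instead of returning a number.
#' @param equal_couplings must be TRUE: asserts the coupling scales are taken
#'   as identical, the regime in which the factorization holds.
#' @return list with `factor` (tau_b / tau_a) and `infinite` flag.
#' @export
lifetime_ratio <- function(p_a, p_b, equal_couplings = TRUE) {
  if (!isTRUE(equal_couplings)) {
    stop("the probability ratio equals the lifetime ratio only under equal couplings",
         call. = FALSE)
  }
  if (p_a < 0 || p_a > 1 || p_b < 0 || p_b > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p_a == 0) stop("p_a = 0: the reference system never reaches the seam", call. = FALSE)
  if (p_b == 0) return(list(factor = NA_real_, infinite = TRUE))
  list(factor = p_a / p_b, infinite = FALSE)
}
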