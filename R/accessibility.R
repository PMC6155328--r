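# Per-mode zero-point-energy accessibility of CI geometries and semiclassical
# (WKB) tunneling probabilities through the per-mode harmonic barriers.

#' WKB action integral through a per-mode harmonic barrier
#'
#' For a mode of frequency `omega` whose coordinate must reach `q_ci` beyond
#' the classical turning point, the action is
#' \deqn{S = -\int_{Q_0}^{Q_{CI}} \sqrt{\omega^2 Q^2/2 - \omega/2}\, dQ,}
#' integrated exactly as written, with no additional mass or \eqn{\sqrt{2}}
#' momentum factor (`convention = "plain"`). `convention = "standard"` applies
#' the conventional semiclassical momentum \eqn{p = \sqrt{2(V-E)}}, i.e.
#' multiplies the action by \eqn{\sqrt 2}, for sensitivity checks.
#'
#' Substituting \eqn{x = Q\sqrt\omega} shows S depends on (omega, q_ci) only
#' through the accessibility ratio \eqn{\alpha = \omega q_{ci}^2}. Either
#' `alpha` directly or the pair (`omega`, `q_ci`) may be supplied. Inside the
#' classically allowed region (alpha <= 1) the action is 0.
#'
#' @param omega mode frequency (a.u.), used with `q_ci` when `alpha` missing.
#' @param q_ci mode coordinate of the CI geometry (mass-weighted a.u.).
#' @param alpha accessibility ratio; overrides `omega`/`q_ci` when given.
#' @param method `"quadrature"` (adaptive, authoritative; abs. tol 1e-12) or
#'   `"closed_form"`.
#' @param convention `"plain"` (the action exactly as defined) or `"standard"` (see Details).
#' @return the action S (dimensionless, <= 0).
#' @export
action_integral <- function(omega = NULL, q_ci = NULL, alpha = NULL,
                            method = c("quadrature", "closed_form"),
                            convention = c("plain", "standard")) {
  method <- match.arg(method)
  convention <- match.arg(convention)
  if (is.null(alpha)) {
    stopifnot(!is.null(omega), !is.null(q_ci), omega > 0)
    alpha <- omega * q_ci^2
  }
  if (alpha < 0) stop("alpha must be non-negative", call. = FALSE)
  if (alpha <= 1 + 1e-12) return(0)
  s <- if (method == "closed_form") {
    -(sqrt(alpha * (alpha - 1)) - log(sqrt(alpha) + sqrt(alpha - 1))) / (2 * sqrt(2))
  } else {
    # integrate in x = Q sqrt(omega): S = -(1/sqrt(2)) int_1^sqrt(alpha)
    # sqrt(x^2 - 1) dx; the integrand's root at x = 1 is integrable.
    -stats::integrate(function(x) sqrt(pmax(x^2 - 1, 0)) / sqrt(2),
                      lower = 1, upper = sqrt(alpha),
                      rel.tol = 1e-13, abs.tol = 1e-12)$value
  }
  if (convention == "standard") s <- s * sqrt(2)
  s
}

#' Tunneling probability to reach a CI along one mode
#'
#' \eqn{P_i = e^{2S}} with the action from [action_integral()]; P = 1 for
#' alpha <= 1 (classically accessible, boundary inclusive), continuous at
#' alpha = 1 and strictly decreasing beyond it. Depends on the mode only
#' through alpha. Ratios within 1e-12 of 1 are treated as exactly 1.
#'
#' @param alpha accessibility ratio(s), >= 0 (vectorized).
#' @inheritParams action_integral
#' @return probabilities in (0, 1].
#' @export
tunneling_probability <- function(alpha, method = c("closed_form", "quadrature"),
                                  convention = c("plain", "standard")) {
  method <- match.arg(method)
  convention <- match.arg(convention)
  if (any(alpha < 0)) stop("alpha must be non-negative", call. = FALSE)
  vapply(alpha, function(a) {
    exp(2 * action_integral(alpha = a, method = method, convention = convention))
  }, 1.0)
}

# Solve tunneling_probability(alpha) = p for alpha >= 1 by bracketed bisection
# on the monotone P(alpha); tolerance 1e-12 in P.
.alpha_for_probability <- function(p, tol = 1e-12) {
  stopifnot(p > 0, p <= 1)
  if (p >= 1) return(1)
  lo <- 1; hi <- 2
  while (tunneling_probability(hi) > p) hi <- hi * 2
  mid <- (lo + hi) / 2
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    pm <- tunneling_probability(mid)
    if (abs(pm - p) < tol) break
    if (pm > p) lo <- mid else hi <- mid
  }
  mid
}

#' Per-mode ZPE accessibility report for a CI geometry
#'
#' For each normal mode of the reference basis, compares the harmonic mode
#' energy at the CI geometry, \eqn{W_i = \omega_i^2 Q_{CI,i}^2 / 2}, with the
#' mode zero-point energy \eqn{ZPE_i = \omega_i/2}. The ratio
#' \eqn{\alpha_i = W_i / ZPE_i = \omega_i Q_{CI,i}^2} classifies the mode as
#' classically accessible (alpha <= 1, boundary inclusive) or not; for
#' inaccessible modes the WKB action and tunneling probability are attached.
#' The geometry is classically accessible as a whole only if every mode is,
#' and the total probability to reach it is the product over modes (accessible
#' modes contribute exactly 1, so including them is harmless).
#'
#' @param basis a `normal_mode_basis`.
#' @param ci the CI geometry: a `ci_geometry`, or directly a numeric vector of
#'   normal coordinates.
#' @param align superimpose the CI geometry on the reference before projecting
#'   (default). Surrogate fixture chains must use `align = FALSE`: their mode
#'   space overlaps the rigid-body space, so superposition is not meaningful.
#' @inheritParams action_integral
#' @return object of class `accessibility_report`: a list with `modes` (tibble:
#'   `mode`, `omega_au`, `q_ci`, `w_i`, `zpe_i`, `alpha`, `accessible`,
#'   `turning_point`, `action`, `p_i`), `classically_accessible` (flag),
#'   `total_p`.
#' @export
accessibility_report <- function(basis, ci,
                                 method = c("closed_form", "quadrature"),
                                 convention = c("plain", "standard"),
                                 align = TRUE) {
  method <- match.arg(method)
  convention <- match.arg(convention)
  q <- if (inherits(ci, "ci_geometry")) to_normal_coords(basis, ci, align = align)
       else as.numeric(ci)
  stopifnot(length(q) == basis$n_modes, all(is.finite(q)))
  omega <- basis$frequencies
  w_i <- 0.5 * omega^2 * q^2
  zpe_i <- omega / 2
  alpha <- omega * q^2
  alpha[abs(alpha - 1) < 1e-12] <- 1
  action <- vapply(seq_along(alpha), function(i) {
    action_integral(alpha = alpha[i], method = if (method == "closed_form")
      "closed_form" else "quadrature", convention = convention)
  }, 1.0)
  p_i <- exp(2 * action)
  modes <- tibble::tibble(
    mode = seq_along(omega),
    omega_au = omega,
    omega_cm1 = omega_to_cm1(omega),
    q_ci = q,
    w_i = w_i,
    zpe_i = zpe_i,
    alpha = alpha,
    accessible = alpha <= 1,
    turning_point = sign(q) / sqrt(omega),
    action = action,
    p_i = p_i
  )
  structure(
    list(modes = modes,
         classically_accessible = all(modes$accessible),
         total_p = prod(p_i)),
    class = "accessibility_report"
  )
}

#' @export
print.accessibility_report <- function(x, ...) {
  cat("<accessibility_report> ", nrow(x$modes), " modes; ",
      sum(!x$modes$accessible), " inaccessible; total P = ",
      format(x$total_p, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Mode table of an accessibility report
#' @param x an `accessibility_report`.
#' @param ... unused.
#' @return the per-mode tibble.
#' @export
as_tibble.accessibility_report <- function(x, ...) x$modes

#' Total probability to reach a CI geometry
#'
#' Product of the per-mode probabilities; equals 1 iff the geometry is
#' classically accessible along every mode, and is bounded above by the
#' smallest per-mode probability.
#'
#' @param report an `accessibility_report`.
#' @return probability in (0, 1].
#' @export
total_probability <- function(report) {
  stopifnot(inherits(report, "accessibility_report"))
  prod(report$modes$p_i)
}

#' Write an accessibility report
#'
#' CSV with one row per mode plus a JSON-style summary line is the exchange
#' format for downstream kinetics.
#'
#' @param report an `accessibility_report`.
#' @param csv_path output CSV path.
#' @return `csv_path`, invisibly.
#' @export
write_accessibility_csv <- function(report, csv_path) {
  stopifnot(inherits(report, "accessibility_report"))
  utils::write.csv(as.data.frame(report$modes), csv_path, row.names = FALSE)
  invisible(csv_path)
}

#' Plot an accessibility report
#'
#' Per-mode accessibility ratios alpha_i against mode frequency, with the
#' classical-accessibility boundary alpha = 1 drawn; inaccessible modes are
#' highlighted.
#'
#' @param object an `accessibility_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.accessibility_report <- function(object, ...) {
  d <- object$modes
  ggplot2::ggplot(d, ggplot2::aes(x = .data$omega_cm1, y = .data$alpha,
                                  colour = .data$accessible)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d7301f"),
                                 name = "classically\naccessible") +
    ggplot2::labs(x = expression(omega[i] ~ (cm^-1)),
                  y = expression(alpha[i] == W[i] / ZPE[i]),
                  title = sprintf("Total access probability P = %.3g", object$total_p))
}
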