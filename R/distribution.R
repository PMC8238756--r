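# Gamma-Gompertz distribution on the model age scale (x = calendar - start_age).
#
# With Lambda(x) = (a/b)(e^{bx} - 1) the cumulative baseline hazard, the
# marginal (population) quantities are
#   h(x) = a e^{bx} / (1 + sigma2 * Lambda(x))
#   S(x) = (1 + sigma2 * Lambda(x))^{-1/sigma2}
#   f(x) = a e^{bx} (1 + sigma2 * Lambda(x))^{-(1 + 1/sigma2)}
# At sigma2 = 0 these reduce to the Gompertz forms; all evaluations use
# log1p/expm1 so the boundary is reached continuously in floating point.

# cumulative baseline hazard and its parameter derivatives (vectorized in x)
gg_cumhaz <- function(x, a, b) a / b * expm1(b * x)

check_model_age <- function(x) {
  if (any(!is.finite(x))) stop("model ages must be finite")
  if (any(x < 0)) stop("model ages must be >= 0")
  invisible(x)
}

#' Hazard of the gamma-Gompertz model
#'
#' The marginal (population) hazard \eqn{h(x) = a e^{bx} / \{1 +
#' \sigma^2 (a/b)(e^{bx}-1)\}}, or the individual baseline Gompertz hazard
#' \eqn{a e^{bx}} when `baseline = TRUE`. For \eqn{\sigma^2 > 0} the marginal
#' hazard decelerates: it falls strictly below the baseline for \eqn{x > 0}.
#'
#' @param x Model age(s), years since `p$start_age` (>= 0).
#' @param p A [gg_params()] object.
#' @param baseline If `TRUE`, return the baseline Gompertz hazard.
#' @return Hazard per year, same length as `x`.
#' @examples
#' p <- gg_params(0.015, 0.085, 0.043)
#' gg_hazard(0, p)            # equals a
#' gg_hazard(30, p) < gg_hazard(30, p, baseline = TRUE)
#' @export
gg_hazard <- function(x, p, baseline = FALSE) {
  stopifnot(inherits(p, "gg_params"))
  check_model_age(x)
  h0 <- p$a * exp(p$b * x)
  if (baseline) return(h0)
  h0 / (1 + p$sigma2 * gg_cumhaz(x, p$a, p$b))
}

#' Survival function of the gamma-Gompertz model
#'
#' \eqn{S(x) = \{1 + \sigma^2 (a/b)(e^{bx}-1)\}^{-1/\sigma^2}}, with the
#' Gompertz limit \eqn{\exp\{-(a/b)(e^{bx}-1)\}} at \eqn{\sigma^2 = 0}.
#'
#' @inheritParams gg_hazard
#' @param log.p If `TRUE`, return log survival.
#' @return Survival probability (or its log), same length as `x`.
#' @export
gg_survival <- function(x, p, log.p = FALSE) {
  stopifnot(inherits(p, "gg_params"))
  check_model_age(x)
  L <- gg_cumhaz(x, p$a, p$b)
  ls <- if (p$sigma2 == 0) -L else -log1p(p$sigma2 * L) / p$sigma2
  if (log.p) ls else exp(ls)
}

#' Density of age at death in the gamma-Gompertz model
#'
#' Marginal density \eqn{f(x) = a e^{bx} \{1 + \sigma^2 (a/b)(e^{bx}-1)
#' \}^{-(1+1/\sigma^2)}}. When a truncation scheme is supplied, the density of
#' the left-truncated lifespan \eqn{f(x)/S(\breve x)} on \eqn{(\breve x,
#' \infty)} is returned; there `x` must exceed the truncation model age.
#'
#' @inheritParams gg_hazard
#' @param trunc `NULL` for the complete-data density, or a
#'   [truncation_scheme()] / calendar truncation age for the left-truncated
#'   density.
#' @param log If `TRUE`, return the log density.
#' @return Density per year (or its log), same length as `x`.
#' @export
gg_density <- function(x, p, trunc = NULL, log = FALSE) {
  stopifnot(inherits(p, "gg_params"))
  check_model_age(x)
  s <- p$sigma2
  L <- gg_cumhaz(x, p$a, p$b)
  lf <- log(p$a) + p$b * x +
    (if (s == 0) -L else -(1 + 1 / s) * log1p(s * L))
  if (!is.null(trunc)) {
    t <- as_trunc(trunc, p)
    if (t$x_breve > 0) {
      if (any(x <= t$x_breve))
        stop("truncated density requires x > truncation model age ",
             t$x_breve)
      lf <- lf - gg_survival(t$x_breve, p, log.p = TRUE)
    }
  }
  if (log) lf else exp(lf)
}

#' Quantile of the (truncated) gamma-Gompertz survival function
#'
#' Returns the model age `x` at which the conditional survival
#' \eqn{S(x)/S(\breve x)} equals `u`; the inverse-survival transform used for
#' sampling. Closed form: \eqn{x = b^{-1}\log\{1 + (b/a)\Lambda\}} with
#' \eqn{\Lambda = \{(u S(\breve x))^{-\sigma^2} - 1\}/\sigma^2} (and
#' \eqn{\Lambda = -\log(u S(\breve x))} at \eqn{\sigma^2 = 0}).
#'
#' @param u Conditional survival probabilities in (0, 1).
#' @param p A [gg_params()] object.
#' @param trunc `NULL` (no truncation) or a [truncation_scheme()] / calendar
#'   truncation age.
#' @return Model age(s) with `gg_survival(x, p) / gg_survival(x_breve, p) = u`.
#' @export
gg_quantile <- function(u, p, trunc = NULL) {
  stopifnot(inherits(p, "gg_params"))
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1))
    stop("`u` must lie strictly in (0, 1)")
  t <- as_trunc(trunc, p)
  ls_target <- log(u) + gg_survival(t$x_breve, p, log.p = TRUE)
  s <- p$sigma2
  # Lambda at the target survival level; expm1 keeps small sigma2 exact
  Lam <- if (s == 0) -ls_target else expm1(-s * ls_target) / s
  log1p(p$b / p$a * Lam) / p$b
}

#' Log-likelihood of a left-truncated cohort sample
#'
#' \eqn{\sum_i \{\log f(x_i) - \log S(\breve x)\}}: each individual
#' contributes the log of the truncated density of their age at death.
#'
#' @param sample A [cohort_sample()].
#' @param p A [gg_params()] object (its `start_age` must match the sample's).
#' @return Log-likelihood in nats.
#' @export
gg_loglik <- function(sample, p) {
  stopifnot(inherits(sample, "cohort_sample"), inherits(p, "gg_params"))
  sum(gg_density(sample$ages, p, trunc = sample$trunc, log = TRUE))
}
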