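# Likelihood ratio test for H0: sigma2 = 0 (no mortality deceleration) and
# its large-sample power approximation.

#' Likelihood ratio test for a zero frailty variance
#'
#' Tests \eqn{H_0: \sigma^2 = 0} (Gompertz, no mortality deceleration) against
#' \eqn{H_1: \sigma^2 > 0} in the gamma-Gompertz model. Because \eqn{\sigma^2
#' = 0} lies on the boundary of the parameter space, the statistic follows,
#' asymptotically under \eqn{H_0}, a 50:50 mixture of a point mass at zero and
#' a \eqn{\chi^2_1} distribution; the p-value is \eqn{0.5 \Pr(\chi^2_1 > LR)}
#' for \eqn{LR > 0} and 1 when the unrestricted estimate sits on the boundary
#' (\eqn{LR = 0}). Using the plain \eqn{\chi^2_1} reference instead would be
#' conservative and lower the power.
#'
#' @param sample A [cohort_sample()].
#' @param alpha Test level in (0, 0.5).
#' @return Object of class `"gg_lrt"`: list with `statistic`, `p_value`,
#'   `reject`, `alpha`, `mle_null` and `mle_alt` (both `"gg_fit"`).
#' @examples
#' p <- gg_params(0.015, 0.085, 0.043)
#' smp <- simulate_cohort(p, 5000, seed = 7)
#' lr_test(smp)
#' @export
lr_test <- function(sample, alpha = 0.05) {
  stopifnot(inherits(sample, "cohort_sample"),
            alpha > 0, alpha < 0.5)
  fit0 <- gg_fit(sample, fix_sigma2 = TRUE)
  fit1 <- gg_fit(sample, fix_sigma2 = FALSE)
  lr <- max(0, 2 * (fit1$loglik - fit0$loglik))
  pval <- if (lr > 0) 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
          else 1
  structure(list(statistic = lr, p_value = pval, reject = pval <= alpha,
                 alpha = alpha, mle_null = fit0, mle_alt = fit1),
            class = "gg_lrt")
}

#' @export
print.gg_lrt <- function(x, ...) {
  cat("Likelihood ratio test for H0: sigma2 = 0 (50:50 chi^2_1 mixture null)\n")
  cat(sprintf("  LR = %.4f, p-value = %.4f  (level %.3g: %s H0)\n",
              x$statistic, x$p_value, x$alpha,
              if (x$reject) "reject" else "do not reject"))
  cat(sprintf("  sigma2_hat = %g\n", x$mle_alt$params_hat$sigma2))
  invisible(x)
}

#' Asymptotic power of the likelihood ratio test
#'
#' Large-sample approximation to the power of the boundary likelihood ratio
#' test at level \eqn{\alpha} and sample size \eqn{n}:
#' \deqn{\beta_n(\sigma^2) \approx 1 - \Phi\{\Phi^{-1}(1-\alpha) -
#'   \sqrt{n}\,\sigma^2/\kappa\},}
#' where \eqn{\kappa = \sqrt{[I(\theta)]^{-1}_{33}}} is computed from the
#' expected Fisher information at the design's truncation age. At
#' \eqn{\sigma^2 = 0} the power equals the level.
#'
#' @param p A [gg_params()] object (its `sigma2` is the alternative).
#' @param trunc A [truncation_scheme()] or calendar truncation age.
#' @param n Sample size at that truncation age.
#' @param alpha Test level in (0, 0.5).
#' @param rel.tol Quadrature tolerance for the Fisher information.
#' @return Object of class `"power_result"`: list with `beta`, `alpha`, `n`,
#'   `kappa`, `trunc_age`.
#' @examples
#' p <- gg_params(0.015, 0.085, 0.043)
#' lrt_power(p, trunc = 90, n = 20000)$beta    # about 0.278
#' @export
lrt_power <- function(p, trunc, n, alpha = 0.05, rel.tol = 1e-10) {
  stopifnot(inherits(p, "gg_params"), n >= 1, alpha > 0, alpha < 0.5)
  t <- as_trunc(trunc, p)
  kappa <- sqrt(.gg_inv_info(fisher_info(p, t, rel.tol = rel.tol))["sigma2",
                                                                   "sigma2"])
  beta <- 1 - stats::pnorm(stats::qnorm(1 - alpha) - sqrt(n) * p$sigma2 /
                             kappa)
  structure(list(beta = beta, alpha = alpha, n = n, kappa = kappa,
                 trunc_age = t$trunc_age),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "LRT power %.3f at level %.3g (n = %g, truncation age %g, kappa = %.4f)\n",
    x$beta, x$alpha, x$n, x$trunc_age, x$kappa))
  invisible(x)
}

#' Truncation age required to reach a target power
#'
#' Finds the largest integer calendar truncation age at which the likelihood
#' ratio test attains power `target_beta`, when the cohort size at each
#' candidate age is translated from a known subset size at `ref_age` via
#' survival ratios (all survivors of the cohort enter the sample). The search
#' descends over integer ages from `ref_age` to the model's starting age; a
#' higher age means less data to collect, so ties resolve upward.
#'
#' @param p A [gg_params()] object with `sigma2 > 0`.
#' @param n_ref Known number of survivors to `ref_age`.
#' @param ref_age Calendar reference age (>= `p$start_age`).
#' @param target_beta Desired power in (`alpha`, 1).
#' @param alpha Test level.
#' @param rel.tol Quadrature tolerance.
#' @return Integer calendar age, with attributes `power` and `n` giving the
#'   attained power and translated sample size at that age.
#' @examples
#' p <- gg_params(0.015, 0.085, 0.043)
#' required_truncation_age(p, n_ref = 20000, ref_age = 90,
#'                         target_beta = 0.95)   # 78
#' @export
required_truncation_age <- function(p, n_ref, ref_age, target_beta,
                                    alpha = 0.05, rel.tol = 1e-10) {
  stopifnot(inherits(p, "gg_params"), n_ref >= 1, ref_age >= p$start_age,
            target_beta > alpha, target_beta < 1)
  last <- NULL
  for (age in seq(floor(ref_age), ceiling(p$start_age), by = -1)) {
    n <- cohort_size_at(p, n_ref, ref_age, age)
    pw <- lrt_power(p, age, n, alpha = alpha, rel.tol = rel.tol)
    last <- pw
    if (pw$beta >= target_beta)
      return(structure(age, power = pw$beta, n = n))
  }
  stop(sprintf(
    "target power %.3g unattainable: at starting age %g (n = %g) power is %.4f",
    target_beta, p$start_age, last$n, last$beta))
}
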