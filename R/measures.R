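# Scalar information measures and the design calculus built on them.

.gg_measure_names <- c("D", "A", "E", "DA", "I33")

# per-observation measure by name from a fisher_matrix
.gg_measure <- function(fi, measure) {
  measure <- match.arg(measure, .gg_measure_names)
  switch(measure,
         D   = det(fi$I),
         A   = 1 / sum(diag(.gg_inv_info(fi))),
         E   = min(eigen(fi$I, symmetric = TRUE, only.values = TRUE)$values),
         DA  = 1 / .gg_inv_info(fi)["sigma2", "sigma2"],
         I33 = fi$I["sigma2", "sigma2"])
}

#' Optimal-design information measures of a Fisher matrix
#'
#' Scalar summaries of a per-observation information matrix used as design
#' criteria: `d_opt` = det(I) (D-optimality), `a_opt` = 1/tr(I^-1)
#' (A-optimality), `e_opt` = smallest eigenvalue of I (E-optimality), `da_opt`
#' = 1/[I^-1]_33 = kappa^-2 (D_A-optimality focused on the frailty variance)
#' and `elem33` = [I]_33 (curvature in sigma2 at fixed Gompertz parameters).
#' Each measure also comes scaled by the probability of surviving to the
#' truncation age, `survival_weight = P(X > x_breve)`, which accounts for the
#' achievable sample size when the study enrols all survivors of a cohort.
#'
#' @param fi A `"fisher_matrix"` from [fisher_info()].
#' @return Object of class `"info_measures"`: list with `d_opt`, `a_opt`,
#'   `e_opt`, `da_opt`, `elem33`, `kappa2` (= 1/`da_opt`), `survival_weight`,
#'   and a `scaled` sublist of the five measures times the survival weight.
#' @examples
#' p <- gg_params(0.015, 0.085, 0.043)
#' info_measures(fisher_info(p, trunc = 90))
#' @export
info_measures <- function(fi) {
  stopifnot(inherits(fi, "fisher_matrix"))
  inv <- .gg_inv_info(fi)
  k2 <- inv["sigma2", "sigma2"]
  if (k2 <= 0) stop("information matrix is not positive definite")
  m <- list(d_opt = det(fi$I),
            a_opt = 1 / sum(diag(inv)),
            e_opt = min(eigen(fi$I, symmetric = TRUE,
                              only.values = TRUE)$values),
            da_opt = 1 / k2,
            elem33 = fi$I["sigma2", "sigma2"])
  w <- gg_survival(fi$trunc$x_breve, fi$params)
  m$kappa2 <- k2
  m$survival_weight <- w
  m$scaled <- lapply(m[c("d_opt", "a_opt", "e_opt", "da_opt", "elem33")],
                     function(v) v * w)
  structure(m, class = "info_measures")
}

#' @export
print.info_measures <- function(x, ...) {
  cat("Per-observation information measures (a, b, sigma2):\n")
  cat(sprintf("  D = %.6g  A = %.6g  E = %.6g  D_A = %.6g  [I]33 = %.6g\n",
              x$d_opt, x$a_opt, x$e_opt, x$da_opt, x$elem33))
  cat(sprintf("  kappa^2 = %.6g;  survival weight P(X > x_breve) = %.6g\n",
              x$kappa2, x$survival_weight))
  invisible(x)
}

#' Ratio of an information measure at two truncation ages
#'
#' Quantifies the change in per-observation information when the data are
#' left-truncated at `age_num` rather than `age_den`, e.g. I_80+/I_90+ for the
#' D_A measure kappa^-2. With `scaled = TRUE`, each measure is additionally
#' weighted by the survival probability to its truncation age, reflecting the
#' relative sizes of all-survivor samples.
#'
#' @param p A [gg_params()] object.
#' @param age_num,age_den Calendar truncation ages (>= `p$start_age`).
#' @param measure One of `"D"`, `"A"`, `"E"`, `"DA"` (default), `"I33"`.
#' @param scaled Use survival-scaled measures?
#' @param rel.tol Quadrature tolerance passed to [fisher_info()].
#' @return The ratio (measure at `age_num`) / (measure at `age_den`).
#' @export
info_ratio <- function(p, age_num, age_den, measure = "DA", scaled = FALSE,
                       rel.tol = 1e-10) {
  stopifnot(inherits(p, "gg_params"))
  num <- .gg_measure(fisher_info(p, age_num, rel.tol = rel.tol), measure)
  den <- .gg_measure(fisher_info(p, age_den, rel.tol = rel.tol), measure)
  if (scaled) {
    num <- num * gg_survival(age_num - p$start_age, p)
    den <- den * gg_survival(age_den - p$start_age, p)
  }
  num / den
}

#' Translate a cohort size across truncation ages
#'
#' Given the number of survivors to `ref_age` in a cohort following the model,
#' the expected number of survivors to `target_age` is `n_ref *
#' S(target)/S(ref)`, rounded to the nearest integer.
#'
#' @param p A [gg_params()] object.
#' @param n_ref Known subset size at `ref_age`.
#' @param ref_age,target_age Calendar ages (>= `p$start_age`).
#' @return Integer cohort size at `target_age`.
#' @examples
#' p <- gg_params(0.015, 0.085, 0.043)
#' cohort_size_at(p, 10000, ref_age = 90, target_age = 60)  # 73558
#' @export
cohort_size_at <- function(p, n_ref, ref_age, target_age) {
  stopifnot(inherits(p, "gg_params"), n_ref >= 1,
            ref_age >= p$start_age, target_age >= p$start_age)
  lr <- gg_survival(target_age - p$start_age, p, log.p = TRUE) -
    gg_survival(ref_age - p$start_age, p, log.p = TRUE)
  round(n_ref * exp(lr))
}

#' Equivalent sample size at another truncation age
#'
#' The smallest sample size at truncation age `dst_age` whose total
#' information matches that of `n_src` observations truncated at `src_age`,
#' i.e. the `n` solving `n * I_dst >= n_src * I_src` for the chosen
#' per-observation measure (rounded up, so the returned design is never less
#' informative).
#'
#' @inheritParams info_ratio
#' @param n_src Sample size at `src_age`.
#' @param src_age,dst_age Calendar truncation ages.
#' @return Integer sample size at `dst_age`.
#' @export
equivalent_n <- function(p, n_src, src_age, dst_age, measure = "DA",
                         rel.tol = 1e-10) {
  stopifnot(n_src >= 1)
  ceiling(n_src * info_ratio(p, src_age, dst_age, measure = measure,
                             rel.tol = rel.tol))
}

#' Approximate variance of the frailty-variance MLE
#'
#' For sufficiently large true \eqn{\sigma^2 > 0}, \eqn{var(\hat\sigma^2)
#' \approx \kappa^2 / n} with \eqn{\kappa^2 = [I(\theta)]^{-1}_{33}} at the
#' design's truncation age. At \eqn{\sigma^2 = 0} this quantity is *not* the
#' variance of the estimator (boundary asymptotics); it remains useful for
#' comparing designs through its relative changes.
#'
#' @param p A [gg_params()] object.
#' @param trunc A [truncation_scheme()] or calendar truncation age.
#' @param n Sample size at that truncation age.
#' @param rel.tol Quadrature tolerance.
#' @return Approximate variance \eqn{\kappa^2/n}.
#' @export
var_sigma2_approx <- function(p, trunc, n, rel.tol = 1e-10) {
  stopifnot(n >= 1)
  fi <- fisher_info(p, trunc, rel.tol = rel.tol)
  .gg_inv_info(fi)["sigma2", "sigma2"] / n
}
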