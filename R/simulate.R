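# Cohort simulator and the replication-study harness used to validate the
# quadrature-based Fisher information against averaged observed information.

#' Simulate a cohort of ages at death
#'
#' Draws `n` independent ages at death from the (optionally left-truncated)
#' gamma-Gompertz model by the inverse-survival transform applied to uniform
#' variates. The same seed always reproduces the same sample.
#'
#' @param p A [gg_params()] object.
#' @param n Number of individuals (>= 1).
#' @param trunc `NULL` or a [truncation_scheme()] / calendar truncation age;
#'   all simulated deaths occur above it.
#' @param seed Optional integer seed.
#' @return A [cohort_sample()].
#' @export
simulate_cohort <- function(p, n, trunc = NULL, seed = NULL) {
  stopifnot(inherits(p, "gg_params"), n >= 1)
  t <- as_trunc(trunc, p)
  if (!is.null(seed)) set.seed(seed)
  cohort_sample(gg_quantile(stats::runif(n), p, trunc = t), t)
}

#' Restrict a cohort to survivors beyond a higher age
#'
#' Keeps only deaths above the new calendar truncation age and updates the
#' sample's truncation scheme. Subsetting is idempotent and nested: the 90+
#' subset of a cohort is contained in its 85+ subset.
#'
#' @param sample A [cohort_sample()].
#' @param age New calendar truncation age (>= the sample's current one).
#' @return A [cohort_sample()] of the survivors to `age`.
#' @export
subset_survivors <- function(sample, age) {
  stopifnot(inherits(sample, "cohort_sample"))
  if (age < sample$trunc$trunc_age)
    stop("cannot lower the truncation age of an observed sample (current ",
         sample$trunc$trunc_age, ")")
  t <- truncation_scheme(age, sample$trunc$start_age)
  keep <- sample$ages > t$x_breve
  if (!any(keep)) stop("no survivors beyond age ", age, " in the sample")
  cohort_sample(sample$ages[keep], t)
}

#' Replication study: simulate, subset, fit, aggregate
#'
#' Generates `replications` cohorts from the model, restricts each to the
#' requested survivor subsets, fits the gamma-Gompertz model by maximum
#' likelihood, runs the boundary likelihood ratio test, and aggregates: the
#' averaged observed information \eqn{\bar J = R^{-1}\sum_r J(\hat\theta^{(r)})}
#' per subset is compared elementwise with the quadrature-based \eqn{n I(\theta)}
#' scaled by the theoretical subset size, and empirical means and variances of
#' the estimates and the LRT rejection rate are reported.
#'
#' The initial cohort size at the model's starting age is translated from
#' `n_ref` at `ref_age` via survival ratios. Per-replication child seeds are
#' `seed + replicate index`, so any single replication is reproducible in
#' isolation. Replications whose fit fails are excluded from the averages and
#' counted.
#'
#' @param p A [gg_params()] object.
#' @param n_ref Target number of survivors to `ref_age` (e.g. the 90+ size).
#' @param ref_age Calendar age anchoring the cohort size (default 90).
#' @param subset_ages Calendar truncation ages to analyse (default
#'   `c(60, 80, 85, 90)`), each >= `p$start_age`.
#' @param replications Number of simulated cohorts (>= 1).
#' @param seed Root integer seed.
#' @param alpha Level of the likelihood ratio test.
#' @param rel.tol Quadrature tolerance for the reference information.
#' @return Object of class `"sim_study"`: list with `params`, `replications`,
#'   `n_start`, and `subsets`, a named list per subset age holding `n_theory`,
#'   `mean_n`, `J_bar`, `nI` (the quadrature reference), `mean_rel_diff`
#'   (mean over the 6 unique elements of |J_bar - nI|/|nI|), `est_mean`,
#'   `est_var`, `reject_rate`, `boundary_rate` and `n_failed`.
#' @export
run_sim_study <- function(p, n_ref, ref_age = 90,
                          subset_ages = c(60, 80, 85, 90),
                          replications = 200, seed = 1, alpha = 0.05,
                          rel.tol = 1e-10) {
  stopifnot(inherits(p, "gg_params"), replications >= 1,
            all(subset_ages >= p$start_age))
  subset_ages <- sort(subset_ages)
  n_start <- cohort_size_at(p, n_ref, ref_age, p$start_age)
  # quadrature reference per subset, computed once
  refs <- lapply(subset_ages, function(a) fisher_info(p, a, rel.tol = rel.tol))
  names(refs) <- as.character(subset_ages)

  acc <- lapply(subset_ages, function(a)
    list(J = matrix(0, 3, 3), est = NULL, rej = logical(0), bnd = logical(0),
         n = integer(0), failed = 0L))
  names(acc) <- as.character(subset_ages)

  for (r in seq_len(replications)) {
    full <- simulate_cohort(p, n_start, trunc = p$start_age, seed = seed + r)
    for (a in as.character(subset_ages)) {
      sub <- subset_survivors(full, as.numeric(a))
      res <- tryCatch({
        lt <- lr_test(sub, alpha = alpha)
        fit <- lt$mle_alt
        list(J = fit$observed_info$I, est = coef(fit),
             rej = lt$reject, bnd = fit$boundary, n = sub$n)
      }, error = function(e) NULL)
      if (is.null(res)) {
        acc[[a]]$failed <- acc[[a]]$failed + 1L
      } else {
        acc[[a]]$J <- acc[[a]]$J + res$J
        acc[[a]]$est <- rbind(acc[[a]]$est, res$est)
        acc[[a]]$rej <- c(acc[[a]]$rej, res$rej)
        acc[[a]]$bnd <- c(acc[[a]]$bnd, res$bnd)
        acc[[a]]$n <- c(acc[[a]]$n, res$n)
      }
    }
  }

  subsets <- lapply(as.character(subset_ages), function(a) {
    ok <- length(acc[[a]]$rej)
    if (ok == 0L) stop("all replications failed for subset age ", a)
    J_bar <- acc[[a]]$J / ok
    n_theory <- cohort_size_at(p, n_ref, ref_age, as.numeric(a))
    nI <- n_theory * refs[[a]]$I
    ut <- upper.tri(nI, diag = TRUE)
    list(age = as.numeric(a),
         n_theory = n_theory,
         mean_n = mean(acc[[a]]$n),
         J_bar = J_bar,
         nI = nI,
         mean_rel_diff = mean(abs(J_bar[ut] - nI[ut]) / abs(nI[ut])),
         est_mean = colMeans(acc[[a]]$est),
         est_var = apply(acc[[a]]$est, 2, stats::var),
         reject_rate = mean(acc[[a]]$rej),
         boundary_rate = mean(acc[[a]]$bnd),
         n_used = ok,
         n_failed = acc[[a]]$failed)
  })
  names(subsets) <- as.character(subset_ages)
  structure(list(params = p, replications = replications, n_start = n_start,
                 seed = seed, alpha = alpha, subsets = subsets),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(
    "Replication study: R = %d cohorts of n = %g at start age %g\n",
    x$replications, x$n_start, x$params$start_age))
  for (s in x$subsets)
    cat(sprintf(
      paste0("  %g+: n ~ %g, mean rel diff |J_bar - nI|/|nI| = %.4f, ",
             "reject %.3f, sigma2_hat = 0 in %.2f, failed %d\n"),
      s$age, s$n_theory, s$mean_rel_diff, s$reject_rate, s$boundary_rate,
      s$n_failed))
  invisible(x)
}

#' Write a replication-study summary as CSV
#'
#' One row per subset age with the aggregate statistics of [run_sim_study()].
#'
#' @param study A `"sim_study"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_study_csv <- function(study, path) {
  stopifnot(inherits(study, "sim_study"))
  rows <- do.call(rbind, lapply(study$subsets, function(s)
    data.frame(age = s$age, n_theory = s$n_theory, mean_n = s$mean_n,
               mean_rel_diff = s$mean_rel_diff,
               mean_a = s$est_mean["a"], mean_b = s$est_mean["b"],
               mean_sigma2 = s$est_mean["sigma2"],
               var_sigma2 = s$est_var["sigma2"],
               reject_rate = s$reject_rate,
               boundary_rate = s$boundary_rate,
               n_failed = s$n_failed)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
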