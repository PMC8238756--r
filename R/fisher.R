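# Expected and observed Fisher information for left-truncated observations.

# upper integration limit: age U where the conditional survival
# S(U)/S(x_breve) drops below `tail`, found by bisection on the log scale
.gg_upper <- function(p, t, tail = 1e-14) {
  ls_b <- gg_survival(t$x_breve, p, log.p = TRUE)
  f <- function(x) gg_survival(x, p, log.p = TRUE) - ls_b - log(tail)
  hi <- t$x_breve + 10
  while (f(hi) > 0) hi <- hi + 10
  stats::uniroot(f, c(t$x_breve, hi), tol = 1e-8)$root
}

#' Expected Fisher information per left-truncated observation
#'
#' Computes \eqn{I(\theta) = -E[\partial^2 \log f_{X|X>\breve x}(X;\theta) /
#' \partial\theta\partial\theta^T \mid X > \breve x]} for the gamma-Gompertz
#' model by adaptive quadrature of the analytic Hessian against the truncated
#' density. No closed form exists for these integrals, so each of the six
#' unique elements is integrated separately over \eqn{(\breve x, U)}, where
#' \eqn{U} is the age at which the conditional survival falls below `tail`.
#'
#' @param p A [gg_params()] object.
#' @param trunc `NULL` (complete observation) or a [truncation_scheme()] /
#'   calendar truncation age.
#' @param rel.tol Relative tolerance requested per element from
#'   [stats::integrate()].
#' @param tail Conditional survival mass beyond the upper integration limit.
#' @return Object of class `"fisher_matrix"`: list with the 3 x 3 symmetric
#'   matrix `I` (parameter order a, b, sigma2), `params`, `trunc`, and
#'   quadrature diagnostics `abs.error` (per unique element) and
#'   `subdivisions`.
#' @examples
#' p <- gg_params(0.015, 0.085, 0.043)
#' fi <- fisher_info(p, trunc = 90)
#' solve(fi$I)["sigma2", "sigma2"]   # kappa^2 for survivors to 90+
#' @export
fisher_info <- function(p, trunc = NULL, rel.tol = 1e-10, tail = 1e-14) {
  stopifnot(inherits(p, "gg_params"))
  t <- as_trunc(trunc, p)
  U <- .gg_upper(p, t, tail)
  ls_b <- gg_survival(t$x_breve, p, log.p = TRUE)
  cols <- c("aa", "ab", "as", "bb", "bs", "ss")
  vals <- errs <- structure(numeric(6), names = cols)
  subdiv <- 0L
  for (k in seq_along(cols)) {
    integrand <- function(x) {
      h <- .gg_dlog(x, p, t$x_breve)[[paste0("d_", cols[k])]]
      -h * exp(gg_density(x, p, log = TRUE) - ls_b)
    }
    q <- tryCatch(
      stats::integrate(integrand, lower = t$x_breve, upper = U,
                       rel.tol = rel.tol, abs.tol = 0, subdivisions = 400L),
      error = function(e) e)
    if (inherits(q, "error") || q$message != "OK")
      stop("quadrature failed for element ", cols[k], " at truncation age ",
           t$trunc_age, ": ",
           if (inherits(q, "error")) conditionMessage(q) else q$message)
    vals[k] <- q$value
    errs[k] <- q$abs.error
    subdiv <- max(subdiv, q$subdivisions)
  }
  structure(list(I = .gg_mat3(vals), params = p, trunc = t,
                 abs.error = errs, subdivisions = subdiv),
            class = "fisher_matrix")
}

#' Observed Fisher information of a sample
#'
#' \eqn{J(\hat\theta) = -\sum_i \partial^2 \log f_{X|X>\breve x}(x_i;
#' \hat\theta)/\partial\theta\partial\theta^T}: the negative Hessian of the
#' sample log-likelihood, normally evaluated at the maximum-likelihood
#' estimate (this contract is documented, not enforced).
#'
#' @param sample A [cohort_sample()].
#' @param p_hat A [gg_params()] object, typically `coef` of a [gg_fit()].
#' @return Object of class `"fisher_matrix"` (with `abs.error = NULL`).
#' @export
observed_info <- function(sample, p_hat) {
  stopifnot(inherits(sample, "cohort_sample"), inherits(p_hat, "gg_params"))
  check_above_trunc(sample$ages, sample$trunc)
  d <- .gg_dlog(sample$ages, p_hat, sample$trunc$x_breve)
  sums <- vapply(d[c("d_aa", "d_ab", "d_as", "d_bb", "d_bs", "d_ss")], sum, 0)
  structure(list(I = .gg_mat3(-sums), params = p_hat,
                 trunc = sample$trunc, abs.error = NULL, subdivisions = NULL),
            class = "fisher_matrix")
}

#' @export
print.fisher_matrix <- function(x, ...) {
  kind <- if (is.null(x$abs.error)) "Observed" else "Expected"
  cat(sprintf("%s Fisher information, left truncation at calendar age %g\n",
              kind, x$trunc$trunc_age))
  print(x$I)
  if (!is.null(x$abs.error))
    cat(sprintf("max estimated quadrature error: %.2e\n", max(x$abs.error)))
  invisible(x)
}

# inverse with a condition-number guard; kappa^2 must be trustworthy
.gg_inv_info <- function(fi, max_cond = 1e12) {
  I <- if (inherits(fi, "fisher_matrix")) fi$I else fi
  cond <- kappa(I, exact = TRUE)
  if (!is.finite(cond) || cond > max_cond)
    stop(sprintf("information matrix is ill-conditioned (kappa = %.3g); %s",
                 cond, "refusing to invert"))
  solve(I)
}

#' Serialize a Fisher information matrix
#'
#' `write_fisher_csv()` writes the 3 x 3 matrix with a header row;
#' `write_fisher_json()` writes elements plus quadrature diagnostics.
#'
#' @param fi A `"fisher_matrix"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fisher_csv <- function(fi, path) {
  stopifnot(inherits(fi, "fisher_matrix"))
  utils::write.csv(as.data.frame(fi$I), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_fisher_csv
#' @export
write_fisher_json <- function(fi, path) {
  stopifnot(inherits(fi, "fisher_matrix"))
  obj <- list(parameters = unclass(fi$params),
              trunc_age = fi$trunc$trunc_age,
              elements = as.list(structure(
                fi$I[upper.tri(fi$I, diag = TRUE)],
                names = c("aa", "ab", "bb", "as", "bs", "ss"))),
              abs_error = as.list(fi$abs.error))
  writeLines(.gg_to_json(obj), path)
  invisible(path)
}

# minimal JSON writer for nested lists of scalars/vectors (no escaping needs
# beyond plain names/numbers used here)
.gg_to_json <- function(x) {
  if (is.list(x)) {
    if (is.null(names(x)))
      paste0("[", paste(vapply(x, .gg_to_json, ""), collapse = ","), "]")
    else
      paste0("{", paste(sprintf('"%s":%s', names(x),
                                vapply(x, .gg_to_json, "")),
                        collapse = ","), "}")
  } else if (is.character(x)) {
    sprintf('"%s"', x)
  } else if (is.logical(x)) {
    paste(tolower(as.character(x)), collapse = ",")
  } else if (length(x) == 1L) {
    format(x, digits = 17)
  } else {
    paste0("[", paste(format(x, digits = 17), collapse = ","), "]")
  }
}
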