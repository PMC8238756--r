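#' Gamma-Gompertz model parameters
#'
#' Bundles the parameter triple of the gamma-Gompertz frailty model together
#' with the calendar age that is mapped to model age 0. Individual hazards are
#' Gompertz, \eqn{h_0(x) = a e^{bx}}, multiplied by a gamma-distributed frailty
#' with mean 1 and variance \eqn{\sigma^2}; model age \eqn{x} is calendar age
#' minus `start_age`.
#'
#' @param a Baseline mortality level at model age 0 (per year, > 0).
#' @param b Rate of ageing: exponential slope of the baseline log-hazard
#'   (per year, > 0).
#' @param sigma2 Frailty variance \eqn{\sigma^2} (dimensionless, >= 0).
#'   `sigma2 = 0` is the homogeneous (pure Gompertz) boundary case.
#' @param start_age Calendar age corresponding to model age 0 (years, >= 0).
#'   Defaults to 60, the usual starting age for senescent-mortality models.
#'
#' @return An object of class `"gg_params"`: a list with components `a`, `b`,
#'   `sigma2`, `start_age`.
#' @examples
#' p <- gg_params(a = 0.015, b = 0.085, sigma2 = 0.043)
#' p
#' @export
gg_params <- function(a, b, sigma2, start_age = 60) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0)
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b), b > 0)
  stopifnot(is.numeric(sigma2), length(sigma2) == 1L, is.finite(sigma2),
            sigma2 >= 0)
  stopifnot(is.numeric(start_age), length(start_age) == 1L,
            is.finite(start_age), start_age >= 0)
  structure(list(a = a, b = b, sigma2 = sigma2, start_age = start_age),
            class = "gg_params")
}

#' @export
print.gg_params <- function(x, ...) {
  cat("Gamma-Gompertz parameters (model age 0 = calendar age ",
      format(x$start_age), ")\n", sep = "")
  cat(sprintf("  a = %g   b = %g   sigma2 = %g\n", x$a, x$b, x$sigma2))
  invisible(x)
}

#' Left-truncation scheme
#'
#' Describes left truncation at a common calendar age: only individuals who
#' survive beyond `trunc_age` are observed. The model-scale truncation age
#' `x_breve = trunc_age - start_age` is derived; `x_breve = 0` means complete
#' observation from the model's starting age.
#'
#' @param trunc_age Calendar left-truncation age (years, >= `start_age`).
#' @param start_age Calendar age mapped to model age 0 (years). Typically the
#'   `start_age` of the [gg_params()] object used alongside.
#'
#' @return An object of class `"gg_trunc"`: list with `trunc_age`, `start_age`
#'   and `x_breve`.
#' @examples
#' truncation_scheme(90)           # survivors to age 90+, model scale 30
#' @export
truncation_scheme <- function(trunc_age, start_age = 60) {
  stopifnot(is.numeric(trunc_age), length(trunc_age) == 1L,
            is.finite(trunc_age))
  stopifnot(is.numeric(start_age), length(start_age) == 1L,
            is.finite(start_age), start_age >= 0)
  if (trunc_age < start_age)
    stop("`trunc_age` must not be below `start_age`")
  structure(list(trunc_age = trunc_age, start_age = start_age,
                 x_breve = trunc_age - start_age),
            class = "gg_trunc")
}

#' @export
print.gg_trunc <- function(x, ...) {
  cat(sprintf("Left truncation at calendar age %g (model age %g)\n",
              x$trunc_age, x$x_breve))
  invisible(x)
}

# Coerce a truncation spec to "gg_trunc": numbers are calendar ages.
as_trunc <- function(t, p) {
  if (inherits(t, "gg_trunc")) {
    if (!isTRUE(all.equal(t$start_age, p$start_age)))
      stop("truncation scheme and parameters use different `start_age`")
    return(t)
  }
  if (is.null(t)) return(truncation_scheme(p$start_age, p$start_age))
  truncation_scheme(t, p$start_age)
}

#' Cohort of ages at death
#'
#' A sample of ages at death observed under a common left-truncation age:
#' every recorded age strictly exceeds the truncation age.
#'
#' @param ages Numeric vector of ages at death on the *model* scale (years
#'   since `start_age`), each strictly greater than the truncation model age.
#' @param trunc A [truncation_scheme()], or a calendar truncation age.
#' @param start_age Calendar age mapped to model age 0; used when `trunc` is
#'   given as a number.
#'
#' @return Object of class `"cohort_sample"`: list with `ages` (model scale),
#'   `trunc` and `n`.
#' @seealso [read_cohort_csv()] for calendar-age CSV input,
#'   [simulate_cohort()] to generate samples from the model.
#' @export
cohort_sample <- function(ages, trunc, start_age = 60) {
  if (!inherits(trunc, "gg_trunc")) trunc <- truncation_scheme(trunc, start_age)
  ages <- as.numeric(ages)
  if (length(ages) == 0L) stop("empty sample")
  if (any(!is.finite(ages))) stop("non-finite ages in sample")
  if (any(ages <= trunc$x_breve))
    stop("all ages must strictly exceed the truncation age (model scale ",
         trunc$x_breve, ")")
  structure(list(ages = ages, trunc = trunc, n = length(ages)),
            class = "cohort_sample")
}

#' @export
print.cohort_sample <- function(x, ...) {
  cat(sprintf(
    "Cohort sample: n = %d deaths above calendar age %g (start age %g)\n",
    x$n, x$trunc$trunc_age, x$trunc$start_age))
  cat(sprintf("  calendar ages at death in [%.2f, %.2f]\n",
              min(x$ages) + x$trunc$start_age, max(x$ages) + x$trunc$start_age))
  invisible(x)
}

#' Read / write a cohort sample as CSV
#'
#' The file holds one record per individual with a header row and a column
#' `age_at_death` in calendar years. The truncation age is not stored per row;
#' it is supplied separately.
#'
#' @param path File path.
#' @param trunc_age Calendar left-truncation age of the sample.
#' @param start_age Calendar age mapped to model age 0.
#' @return `read_cohort_csv()` returns a [cohort_sample()];
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path, trunc_age, start_age = 60) {
  d <- utils::read.csv(path)
  if (!"age_at_death" %in% names(d))
    stop("CSV must contain a column `age_at_death`")
  cohort_sample(d$age_at_death - start_age,
                truncation_scheme(trunc_age, start_age))
}

#' @rdname read_cohort_csv
#' @param sample A [cohort_sample()].
#' @export
write_cohort_csv <- function(sample, path) {
  stopifnot(inherits(sample, "cohort_sample"))
  utils::write.csv(
    data.frame(age_at_death = sample$ages + sample$trunc$start_age),
    path, row.names = FALSE)
  invisible(path)
}
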