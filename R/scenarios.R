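# Built-in parameter scenarios, YAML/JSON configuration and the design table.

.gg_scenario_table <- function() {
  data.frame(
    name = paste0("S", 1:6),
    a = c(0.015, 0.015, 0.015, 0.021, 0.021, 0.021),
    b = c(0.085, 0.085, 0.085, 0.082, 0.082, 0.082),
    sigma2 = c(0.043, 0.021, 0, 0.043, 0.021, 0),
    start_age = 60,
    stringsAsFactors = FALSE)
}

#' Built-in parameter scenarios
#'
#' Six reference settings for studies of old-age mortality deceleration.
#' S1-S3 share the Gompertz parameters a = 0.015, b = 0.085 (the values
#' estimated from validated female old-age mortality data) with frailty
#' variance 0.043 (S1, pronounced deceleration), 0.021 (S2, weaker) and 0
#' (S3, none); S4-S6 repeat the three variances with a = 0.021, b = 0.082
#' (male estimates), i.e. a higher initial mortality level. Model age 0
#' corresponds to calendar age 60 throughout.
#'
#' @param name Scenario name `"S1"` ... `"S6"`.
#' @return `gg_scenario()` returns a [gg_params()] object; `gg_scenarios()`
#'   the full table as a data frame.
#' @examples
#' gg_scenario("S1")
#' gg_scenarios()
#' @export
gg_scenario <- function(name) {
  tab <- .gg_scenario_table()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown scenario `", name, "`; use one of ",
                     paste(tab$name, collapse = ", "))
  gg_params(tab$a[i], tab$b[i], tab$sigma2[i], tab$start_age[i])
}

#' @rdname gg_scenario
#' @export
gg_scenarios <- function() .gg_scenario_table()

#' Read a scenario configuration file
#'
#' Configurations are YAML (JSON, being a YAML subset, is also accepted) with
#' fields: either `scenario` (a built-in name) or `a`, `b`, `sigma2` (and
#' optional `start_age`, default 60); plus optional `truncation_ages`
#' (default 60, 80, 85, 90), `n_ref` with `ref_age` (sample-size anchor),
#' `alpha` (default 0.05) and `measures` (default all of D, A, E, DA, I33).
#'
#' @param path Path to the YAML/JSON file.
#' @return Object of class `"scenario_config"`: list with `params`
#'   ([gg_params()]), `truncation_ages`, `n_ref`, `ref_age`, `alpha`,
#'   `measures`, `name`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- function(field, why) stop("config field `", field, "`: ", why)
  p <- if (!is.null(cfg$scenario)) {
    gg_scenario(cfg$scenario)
  } else {
    for (f in c("a", "b", "sigma2"))
      if (is.null(cfg[[f]]) || !is.numeric(cfg[[f]]))
        bad(f, "required numeric value missing")
    gg_params(cfg$a, cfg$b, cfg$sigma2,
              start_age = if (is.null(cfg$start_age)) 60 else cfg$start_age)
  }
  ages <- if (is.null(cfg$truncation_ages)) c(60, 80, 85, 90) else
    as.numeric(cfg$truncation_ages)
  if (any(ages < p$start_age))
    bad("truncation_ages", "ages below the model's start_age")
  alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 0.5)
    bad("alpha", "must lie in (0, 0.5)")
  measures <- if (is.null(cfg$measures)) .gg_measure_names else
    unlist(cfg$measures)
  if (!all(measures %in% .gg_measure_names))
    bad("measures", paste("unknown measure; use",
                          paste(.gg_measure_names, collapse = ", ")))
  if (!is.null(cfg$n_ref) &&
      (!is.numeric(cfg$n_ref) || cfg$n_ref < 1))
    bad("n_ref", "must be a positive count")
  if (!is.null(cfg$n_ref) && is.null(cfg$ref_age))
    bad("ref_age", "required when n_ref is given")
  structure(list(params = p,
                 truncation_ages = sort(ages),
                 n_ref = cfg$n_ref,
                 ref_age = cfg$ref_age,
                 alpha = alpha,
                 measures = measures,
                 name = if (is.null(cfg$scenario)) cfg$name else cfg$scenario),
            class = "scenario_config")
}

#' Write a scenario configuration file
#'
#' Round-trips with [read_scenario_config()].
#'
#' @param config A `"scenario_config"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(list(name = config$name,
                        a = config$params$a, b = config$params$b,
                        sigma2 = config$params$sigma2,
                        start_age = config$params$start_age,
                        truncation_ages = config$truncation_ages,
                        n_ref = config$n_ref, ref_age = config$ref_age,
                        alpha = config$alpha,
                        measures = config$measures), path)
  invisible(path)
}

#' Design table: information measures and power across truncation ages
#'
#' For each truncation age, computes the translated cohort size, the requested
#' per-observation information measures, their survival-scaled variants, and
#' the asymptotic power of the boundary likelihood ratio test at that size.
#' This is the per-scenario design report; its power column reproduces the
#' power-versus-age-range tables that motivate the method.
#'
#' @param p A [gg_params()] object.
#' @param n_ref Cohort size anchor: number of survivors to `ref_age`.
#' @param ref_age Calendar age of the anchor (default 90).
#' @param ages Calendar truncation ages to tabulate.
#' @param alpha Level of the likelihood ratio test.
#' @param measures Subset of `c("D", "A", "E", "DA", "I33")`.
#' @param rel.tol Quadrature tolerance.
#' @return A data frame (class `"design_report"`) with one row per truncation
#'   age: `age`, `n`, one column per measure, `scaled_*` columns, `power`.
#' @examples
#' design_table(gg_scenario("S1"), n_ref = 20000, ages = c(80, 90),
#'              measures = "DA")
#' @export
design_table <- function(p, n_ref, ref_age = 90, ages = c(60, 80, 85, 90),
                         alpha = 0.05,
                         measures = c("D", "A", "E", "DA", "I33"),
                         rel.tol = 1e-10) {
  stopifnot(inherits(p, "gg_params"), all(ages >= p$start_age))
  measures <- match.arg(measures, .gg_measure_names, several.ok = TRUE)
  mkey <- c(D = "d_opt", A = "a_opt", E = "e_opt", DA = "da_opt",
            I33 = "elem33")[measures]
  rows <- lapply(sort(ages), function(age) {
    fi <- fisher_info(p, age, rel.tol = rel.tol)
    im <- info_measures(fi)
    n <- cohort_size_at(p, n_ref, ref_age, age)
    vals <- unlist(im[mkey])
    names(vals) <- measures
    scl <- unlist(im$scaled[mkey])
    names(scl) <- paste0("scaled_", measures)
    beta <- 1 - stats::pnorm(stats::qnorm(1 - alpha) -
                               sqrt(n) * p$sigma2 / sqrt(im$kappa2))
    as.data.frame(c(list(age = age, n = n), as.list(vals), as.list(scl),
                    list(power = beta)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("design_report", "data.frame")
  attr(out, "params") <- p
  attr(out, "alpha") <- alpha
  out
}

#' Run the design table from a configuration
#'
#' @param config A `"scenario_config"` (needs `n_ref`/`ref_age`).
#' @param rel.tol Quadrature tolerance.
#' @return A `"design_report"` data frame; see [design_table()].
#' @export
run_design_table <- function(config, rel.tol = 1e-10) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(config$n_ref))
    stop("config field `n_ref`: required to build a design table")
  design_table(config$params, n_ref = config$n_ref,
               ref_age = config$ref_age, ages = config$truncation_ages,
               alpha = config$alpha, measures = config$measures,
               rel.tol = rel.tol)
}

#' Write a design report
#'
#' Writes the table as CSV with fixed column order and the power column
#' formatted to 3 decimals (matching the usual presentation of such tables);
#' a companion `<path>.json` carries all values at full precision.
#'
#' @param report A `"design_report"` from [design_table()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_design_report <- function(report, path) {
  stopifnot(inherits(report, "design_report"))
  out <- as.data.frame(report)
  json <- .gg_to_json(unname(lapply(split(out, seq_len(nrow(out))), as.list)))
  writeLines(json, paste0(path, ".json"))
  out$power <- sprintf("%.3f", out$power)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
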