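# optimality criteria, scaled measures, ratios and sample-size calculus

fake_fisher <- function(I, p = S1, age = 60) {
  structure(list(I = `dimnames<-`(I, list(c("a", "b", "sigma2"),
                                          c("a", "b", "sigma2"))),
                 params = p, trunc = truncation_scheme(age, p$start_age),
                 abs.error = NULL),
            class = "fisher_matrix")
}

test_that("measures on matrices with known eigenstructure", {
  m <- info_measures(fake_fisher(diag(3)))
  expect_equal(m$d_opt, 1)
  expect_equal(m$a_opt, 1 / 3)
  expect_equal(m$e_opt, 1)
  expect_equal(m$da_opt, 1)
  m2 <- info_measures(fake_fisher(diag(c(4, 1, 0.25))))
  expect_equal(m2$d_opt, 1)
  expect_equal(m2$da_opt, 0.25)
  expect_equal(m2$e_opt, 0.25)
  expect_equal(m2$elem33, 0.25)
  # D_A measure times kappa^2 is 1 by construction
  expect_equal(m2$da_opt * m2$kappa2, 1)
  # at no truncation the survival weight is 1, so scaled == unscaled
  expect_equal(m2$scaled$da_opt, m2$da_opt)
  expect_error(info_measures(fake_fisher(matrix(1, 3, 3))), "condition")
})

test_that("A-, E- and D_A-criteria order the age ranges the same way", {
  ms <- lapply(c(60, 80, 85, 90), function(age)
    info_measures(fisher_info(S1, age)))
  for (key in c("a_opt", "e_opt", "da_opt")) {
    v <- vapply(ms, `[[`, 0, key)
    expect_true(all(diff(v) < 0))   # information falls as truncation rises
  }
  # A and E hug the D_A measure (one dominant eigenvalue of the inverse):
  # e_opt <= a_opt-type bounds hold exactly, and both stay within ~10%
  for (m in ms) {
    expect_lte(m$e_opt, m$da_opt)
    expect_gt(m$e_opt / m$da_opt, 0.9)
    expect_gt(m$a_opt / m$da_opt, 0.9)
    expect_lt(m$a_opt / m$da_opt, 1.01)
  }
})

test_that("unscaled measures fall with truncation age except [I]_33", {
  ages <- c(60, 80, 85, 90)
  for (p in all_scenarios[c("S1", "S3", "S4")]) {
    ms <- lapply(ages, function(age) info_measures(fisher_info(p, age)))
    for (key in c("d_opt", "a_opt", "e_opt", "da_opt")) {
      expect_true(all(diff(vapply(ms, `[[`, 0, key)) <= 0))
      expect_true(all(diff(vapply(ms, function(m) m$scaled[[key]], 0)) < 0))
    }
    # curvature in sigma2 alone increases with the truncation age, but the
    # shrinking pool of survivors more than compensates
    expect_true(all(diff(vapply(ms, `[[`, 0, "elem33")) > 0))
    expect_true(all(diff(vapply(ms, function(m) m$scaled$elem33, 0)) < 0))
  }
})

test_that("information ratios across truncation ages", {
  expect_equal(info_ratio(S1, 85, 85), 1, tolerance = 1e-12)
  # scaled D_A loss from 80+ to 90+ is around 87% under S1
  loss <- 1 - info_ratio(S1, 90, 80, scaled = TRUE)
  expect_gte(loss, 0.85)
  expect_lte(loss, 0.89)
  # more than half the per-observation information is lost
  expect_lt(info_ratio(S1, 90, 80), 0.5)
})

test_that("cohort size translation via survival ratios", {
  expect_equal(cohort_size_at(S1, 12345, 90, 90), 12345)
  expect_equal(cohort_size_at(S1, 10000, 90, 60), 73558)
  # forward and backward translations agree up to rounding
  n80 <- cohort_size_at(S1, 20000, 90, 80)
  expect_equal(cohort_size_at(S1, n80, 80, 90), 20000, tolerance = 1e-4)
})

test_that("equivalent sample sizes balance total information", {
  expect_equal(equivalent_n(S1, 5000, 85, 85), 5000)
  # a 90+ sample must be more than twice an 80+ sample under S1
  n90 <- equivalent_n(S1, 10000, 80, 90)
  expect_gt(n90, 20000)
  # n_src * I_src = n_dst * I_dst within rounding
  I80 <- 1 / solve(fisher_info(S1, 80)$I)["sigma2", "sigma2"]
  I90 <- 1 / solve(fisher_info(S1, 90)$I)["sigma2", "sigma2"]
  expect_equal(n90 * I90, 10000 * I80, tolerance = 1e-4)
})

test_that("kappa^2 / n variance approximation scales with n", {
  v1 <- var_sigma2_approx(S1, 90, 10000)
  v2 <- var_sigma2_approx(S1, 90, 20000)
  expect_equal(v1, 2 * v2)
})

test_that("design table assembles sizes, measures and power", {
  dt <- design_table(S1, n_ref = 20000, ages = c(80, 90), measures = "DA")
  expect_equal(dt$n, c(67681, 20000))
  expect_true(all(diff(dt$power) < 0))
  expect_true(all(dt$scaled_DA < dt$DA))
  # byte-identical CSV on rerun (determinism of the report)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_design_report(dt, f1)
  write_design_report(design_table(S1, n_ref = 20000, ages = c(80, 90),
                                   measures = "DA"), f2)
  expect_identical(readLines(f1), readLines(f2))
  # power column under no deceleration equals the level
  dt3 <- design_table(S3, n_ref = 20000, ages = c(80, 90), measures = "DA")
  expect_equal(dt3$power, c(0.05, 0.05))
})

test_that("scenario registry and config round-trip", {
  expect_equal(unclass(gg_scenario("S1"))[c("a", "b", "sigma2")],
               list(a = 0.015, b = 0.085, sigma2 = 0.043))
  expect_equal(gg_scenario("S6")$sigma2, 0)
  expect_equal(gg_scenario("S4")$a, 0.021)
  expect_error(gg_scenario("S7"), "unknown scenario")
  cfg_file <- tempfile(fileext = ".yaml")
  writeLines(c("scenario: S2", "n_ref: 20000", "ref_age: 90",
               "truncation_ages: [80, 90]", "measures: [DA]"), cfg_file)
  cfg <- read_scenario_config(cfg_file)
  expect_equal(cfg$params$sigma2, 0.021)
  out <- tempfile(fileext = ".yaml")
  write_scenario_config(cfg, out)
  cfg2 <- read_scenario_config(out)
  expect_equal(cfg2$params, cfg$params)
  expect_equal(cfg2$truncation_ages, cfg$truncation_ages)
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("a: 0.015", "b: 0.085"), bad)
  expect_error(read_scenario_config(bad), "sigma2")
})
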