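# gamma-Gompertz hazard, survival, density, quantile and log-likelihood

test_that("baseline hazard is the Gompertz form and increases in x and b", {
  expect_equal(gg_hazard(0, S1, baseline = TRUE), S1$a)
  expect_equal(gg_hazard(30, S1, baseline = TRUE), 0.015 * exp(2.55))
  # brute-force grid: doubling b at x = 10 more than doubles the hazard
  grid <- seq(0, 40, by = 2)
  h1 <- gg_hazard(grid, gg_params(0.015, 0.085, 0), baseline = TRUE)
  expect_true(all(diff(h1) > 0))
  p2 <- gg_params(0.015, 2 * 0.085, 0)
  expect_gt(gg_hazard(10, p2, baseline = TRUE),
            2 * gg_hazard(10, S1, baseline = TRUE))
  expect_error(gg_hazard(NaN, S1), "finite")
})

test_that("marginal hazard: Gompertz limits and the f/S identity", {
  expect_equal(gg_hazard(0, S1), S1$a)
  x <- seq(0, 45, by = 5)
  expect_equal(gg_hazard(x, S3), S3$a * exp(S3$b * x))
  # deceleration: marginal <= baseline, strict for sigma2 > 0 and x > 0
  for (p in all_scenarios) {
    expect_true(all(gg_hazard(x, p) <= gg_hazard(x, p, baseline = TRUE)))
    if (p$sigma2 > 0)
      expect_true(all(gg_hazard(x[-1], p) <
                        gg_hazard(x[-1], p, baseline = TRUE)))
  }
  # h(30) = f(30)/S(30) with the survival obtained by quadrature of the
  # density over (30, Inf) -- no use of the closed-form survival
  S30 <- integrate(function(u) gg_density(u, S1), 30, Inf,
                   rel.tol = 1e-12)$value
  expect_equal(gg_hazard(30, S1), gg_density(30, S1) / S30, tolerance = 1e-9)
})

test_that("survival: closed form is consistent with the density", {
  expect_equal(gg_survival(0, S1), 1)
  x <- seq(0, 50, length.out = 30)
  expect_true(all(diff(gg_survival(x, S1)) < 0))
  expect_equal(gg_survival(x, S3), exp(-S3$a / S3$b * expm1(S3$b * x)))
  # cohort of 73,558 sixty-year-olds leaves 10,000 survivors to 90+ under S1
  expect_equal(round(10000 / gg_survival(30, S1)), 73558)
  # continuity at the sigma2 = 0 boundary
  p_eps <- gg_params(S1$a, S1$b, 1e-8)
  expect_lt(max(abs(gg_survival(x, p_eps) - gg_survival(x, S3))), 1e-6)
  # survival matches quadrature of the density (S defined as upper tail mass)
  for (xx in c(5, 20, 35)) {
    tail_mass <- integrate(function(u) gg_density(u, S1), xx, Inf,
                           rel.tol = 1e-12)$value
    expect_equal(gg_survival(xx, S1), tail_mass, tolerance = 1e-9)
  }
})

test_that("density normalizes and equals hazard times survival", {
  for (p in all_scenarios[c("S1", "S3", "S4")]) {
    expect_equal(integrate(function(u) gg_density(u, p), 0, Inf,
                           rel.tol = 1e-12)$value, 1, tolerance = 1e-8)
  }
  x <- seq(0.5, 49.5, length.out = 50)
  expect_equal(gg_density(x, S1), gg_hazard(x, S1) * gg_survival(x, S1),
               tolerance = 1e-12)
  # density is minus the derivative of survival (central differences)
  d <- 1e-5
  fd <- -(gg_survival(x + d, S1) - gg_survival(x - d, S1)) / (2 * d)
  expect_equal(gg_density(x, S1), fd, tolerance = 1e-7)
})

test_that("truncated density renormalizes on (x_breve, Inf)", {
  t90 <- truncation_scheme(90)
  for (p in all_scenarios) {
    for (xb in c(0, 20, 25, 30)) {
      tt <- truncation_scheme(60 + xb)
      expect_equal(
        integrate(function(u) gg_density(u, p, trunc = tt),
                  xb + 1e-12, Inf, rel.tol = 1e-12)$value,
        1, tolerance = 1e-8)
    }
  }
  x <- seq(31, 45, by = 2)
  expect_equal(gg_density(x, S1, trunc = truncation_scheme(60)),
               gg_density(x, S1))
  # constant renormalization: f_trunc / f = 1/S(x_breve) on a grid
  ratio <- gg_density(x, S1, trunc = t90) / gg_density(x, S1)
  expect_equal(ratio, rep(1 / gg_survival(30, S1), length(x)),
               tolerance = 1e-12)
  expect_error(gg_density(25, S1, trunc = t90), "truncat")
})

test_that("log-likelihood is the sum of truncated log-density contributions", {
  t90 <- truncation_scheme(90)
  one <- cohort_sample(32.5, t90)
  expect_equal(gg_loglik(one, S1),
               gg_density(32.5, S1, trunc = t90, log = TRUE))
  two <- cohort_sample(c(32.5, 40.1), t90)
  expect_equal(gg_loglik(two, S1),
               gg_loglik(one, S1) +
                 gg_density(40.1, S1, trunc = t90, log = TRUE))
  # against a numerically renormalized density (quadrature oracle)
  Sq <- integrate(function(u) gg_density(u, S1), 30, Inf,
                  rel.tol = 1e-12)$value
  expect_equal(gg_loglik(two, S1),
               sum(log(gg_density(two$ages, S1) / Sq)), tolerance = 1e-9)
  expect_error(cohort_sample(c(29, 35), t90), "exceed")
})

test_that("quantile transform inverts the conditional survival", {
  u <- c(1e-6, 0.001, seq(0.05, 0.95, by = 0.05), 0.999)
  for (p in all_scenarios[c("S1", "S3", "S6")]) {
    for (tr in list(NULL, truncation_scheme(90))) {
      x <- gg_quantile(u, p, trunc = tr)
      xb <- if (is.null(tr)) 0 else tr$x_breve
      expect_true(all(x > xb))
      expect_equal(gg_survival(x, p) / gg_survival(xb, p), u,
                   tolerance = 1e-9)
    }
  }
  # u -> 1 at no truncation returns ages -> 0
  expect_lt(gg_quantile(1 - 1e-12, S1), 1e-9)
  # sigma2 = 0 case agrees with root-finding on S(x) = u
  for (uu in c(0.1, 0.5, 0.9)) {
    oracle <- uniroot(function(x) gg_survival(x, S3) - uu, c(0, 200),
                      tol = 1e-12)$root
    expect_equal(gg_quantile(uu, S3), oracle, tolerance = 1e-8)
  }
  expect_error(gg_quantile(0, S1), "strictly")
  expect_error(gg_quantile(1, S1), "strictly")
})
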