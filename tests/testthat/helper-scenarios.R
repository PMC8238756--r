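# shared fixtures: scenario parameters and cached simulation studies

S1 <- gg_params(0.015, 0.085, 0.043)
S2 <- gg_params(0.015, 0.085, 0.021)
S3 <- gg_params(0.015, 0.085, 0)
S4 <- gg_params(0.021, 0.082, 0.043)

# all six built-in scenarios
all_scenarios <- lapply(paste0("S", 1:6), gg_scenario)
names(all_scenarios) <- paste0("S", 1:6)

# truncated log-density as a plain function of theta, for differentiation
# oracles (kept independent of the analytic-derivative code path)
logdens_theta <- function(x, theta, xb = 0, start_age = 60) {
  a <- theta[1]; b <- theta[2]; s <- theta[3]
  L <- a / b * expm1(b * x)
  Lb <- a / b * expm1(b * xb)
  if (s == 0) log(a) + b * x - L + Lb
  else log(a) + b * x - (1 + 1 / s) * log1p(s * L) + log1p(s * Lb) / s
}

# replication studies are expensive; compute once per test run and share
.sim_cache <- new.env(parent = emptyenv())

# S1, survivors from the starting age (complete observation), R = 200
# cohorts of ~7,356 (anchored at 1,000 survivors to 90+)
cached_s1_study <- function() {
  if (is.null(.sim_cache$s1))
    .sim_cache$s1 <- run_sim_study(S1, n_ref = 1000, ref_age = 90,
                                   subset_ages = 60, replications = 200,
                                   seed = 20260101)
  .sim_cache$s1
}

# S3 (no frailty), all four survivor subsets, R = 200, anchored at 2,500
# survivors to 90+ (cohorts of ~20,000 at 60). The variance-tracking property
# asserted on this study is asymptotic; at the 90+ subset it needs
# sd(sigma2_hat) = sqrt(kappa^2/n) well below ~0.1, which anchors of a few
# hundred do not provide.
cached_s3_study <- function() {
  if (is.null(.sim_cache$s3))
    .sim_cache$s3 <- run_sim_study(S3, n_ref = 2500, ref_age = 90,
                                   subset_ages = c(60, 80, 85, 90),
                                   replications = 200, seed = 20260202)
  .sim_cache$s3
}
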