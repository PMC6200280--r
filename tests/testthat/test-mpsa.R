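# Latin-hypercube sampling, error scoring, classification, K-S scoring.

test_that("LHS places exactly one sample in each stratum of each parameter", {
  rng <- list(a = c(1, 2), b = c(10, 30), c = c(0.5, 1.5))
  s <- lhs_sample(10, rng, seed = 4)
  for (nm in names(rng)) {
    lo <- rng[[nm]][1]; hi <- rng[[nm]][2]
    strata <- findInterval(s[[nm]], seq(lo, hi, length.out = 11),
                           rightmost.closed = TRUE)
    expect_equal(sort(strata), 1:10)
  }
})

test_that("LHS respects +/-50% ranges and is seed-deterministic", {
  p <- pd1_params()
  rng <- mpsa_ranges(c("k_p_pd1", "k_a_shp"))
  s <- lhs_sample(500, rng, seed = 9)
  expect_true(all(s$k_p_pd1 >= 0.5 * p[["k_p_pd1"]] &
                    s$k_p_pd1 <= 1.5 * p[["k_p_pd1"]]))
  expect_true(all(s$k_a_shp >= 0.5 * p[["k_a_shp"]] &
                    s$k_a_shp <= 1.5 * p[["k_a_shp"]]))
  expect_identical(lhs_sample(50, rng, seed = 3),
                   lhs_sample(50, rng, seed = 3))
  expect_false(identical(lhs_sample(50, rng, seed = 3),
                         lhs_sample(50, rng, seed = 4)))
  expect_error(lhs_sample(10, list(a = c(0, 1)), 1), "positive")
  expect_error(lhs_sample(1, rng, 1), "at least 2")
})

test_that("overall error is zero at the defaults and matches a double-loop recomputation", {
  spec <- mpsa_spec("shp2_recruitment", n_sets = 10, seed = 1)
  ref <- pd1sig:::.mpsa_curves(spec$base$params, spec)
  expect_equal(overall_error(spec$base$params, spec, ref), 0)
  # perturbed set: accumulate the squared deviations in an explicit
  # dose-by-dose, time-point-by-time-point loop over trajectories
  p <- pd1_params(k_p_pd1 = 5, k_a_shp = 8e-3)
  err <- overall_error(p, spec, ref)
  acc <- 0
  for (j in seq_along(spec$pd1_doses)) {
    pools <- spec$base$pools
    pools["pd1T"] <- spec$pd1_doses[j]
    tr <- simulate_scenario(scenario(pools = pools, params = p),
                            times = c(0, spec$time_points))
    for (i in seq_along(spec$time_points)) {
      got <- tr$pct_bound_shp2[i + 1]
      if (is.na(got)) got <- 0  # zero Shp2 pool cannot occur here
      acc <- acc + (got - ref[i, j])^2
    }
  }
  expect_equal(err, acc, tolerance = 1e-10)
  expect_gt(err, 0)
})

test_that("classification thresholds on the mean error with strict acceptance", {
  cls <- classify_errors(c(1, 3))
  expect_equal(cls$threshold, 2)
  expect_identical(cls$acceptable, c(TRUE, FALSE))
  # invariant under uniform rescaling
  set.seed(31)
  for (i in 1:20) {
    e <- rexp(50)
    expect_identical(classify_errors(e)$acceptable,
                     classify_errors(1e3 * e)$acceptable)
    expect_true(any(classify_errors(e)$acceptable) &&
                  any(!classify_errors(e)$acceptable))
  }
  expect_error(classify_errors(rep(2, 5)), "degenerate")
  expect_error(classify_errors(1), "at least 2")
})

test_that("the K-S distance matches hand enumeration and the reference implementation", {
  expect_equal(ks_statistic(c(1, 2), c(2, 3)), 0.5)
  expect_equal(ks_statistic(1:5, 1:5), 0)
  expect_equal(ks_statistic(1:5, 11:15), 1)
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(40); y <- rnorm(25, mean = runif(1, -1, 1))
    expect_equal(ks_statistic(x, y),
                 unname(suppressWarnings(
                   stats::ks.test(x, y)$statistic)))
  }
  expect_error(ks_statistic(numeric(0), 1:3), "non-empty")
})

test_that("the MPSA pipeline is seed-reproducible and bounded", {
  spec <- mpsa_spec("pi3k_recruitment", n_sets = 60, seed = 21)
  r1 <- run_mpsa(spec)
  r2 <- run_mpsa(spec)
  expect_identical(tidy(r1), tidy(r2))
  expect_true(all(r1$ks$ks >= 0 & r1$ks$ks <= 1))
  expect_equal(nrow(r1$ks), 21)
  expect_equal(r1$n_sets_used + r1$n_failed, 60)
  gl <- glance(r1)
  expect_gt(gl$error_threshold, 0)
  expect_true(gl$acceptance_fraction > 0 && gl$acceptance_fraction < 1)
})

test_that("module parameter lists have the documented sizes and exclusions", {
  expect_length(mpsa_spec("shp2_recruitment")$varied_parameters, 15)
  expect_length(mpsa_spec("pi3k_recruitment")$varied_parameters, 21)
  sl <- mpsa_spec("slp76_activation")$varied_parameters
  expect_length(sl, 29)
  expect_false("k_corr" %in% sl)
  expect_false(any(c("k_a_pi3k", "k_p_cd28") %in% sl))
})

test_that("a parameter outside the readout's equations scores at the two-sample null", {
  # vary only the LAT/Slp76 branch parameters while scoring PI3K
  # recruitment: they cannot move the readout, so acceptance is driven
  # by the other parameters and their K-S should sit at null level
  spec <- mpsa_spec("pi3k_recruitment", n_sets = 150, seed = 13)
  spec$varied_parameters <- c(spec$varied_parameters, "k_p_lat", "k_a_slp")
  r <- run_mpsa(spec)
  null_ks <- r$ks$ks[r$ks$parameter %in% c("k_p_lat", "k_a_slp")]
  n_acc <- round(r$acceptance_fraction * r$n_sets_used)
  # 95% quantile of the two-sample K-S null at this class split
  crit <- 1.36 * sqrt(1 / n_acc + 1 / (r$n_sets_used - n_acc))
  expect_true(all(null_ks < crit))
})
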