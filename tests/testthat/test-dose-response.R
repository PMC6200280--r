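# PD-1 dose scans, Hill fitting and 2-D scans.

test_that("dose scans normalize to the zero-PD-1 run", {
  dr <- scan_pd1(builtin_scenario("fig3_base"),
                 doses = c(0, 10, 100, 1000, 1e4))
  z <- dplyr::filter(dr, dose_nm == 0)
  expect_true(all(abs(z$normalized - 100) < 1e-9))
  expect_true(all(abs(z$inhibition) < 1e-9))
  expect_equal(sort(unique(dr$readout)),
               sort(pd1sig:::.dose_readouts))
  expect_equal(dr$dose_density, dr$dose_nm * 2.9)
  expect_error(scan_pd1(builtin_scenario("fig3_base"), doses = c(10, 100)),
               "include 0")
})

test_that("CD28 phosphorylation declines monotonically and faster than CD3zeta", {
  dr <- scan_pd1(builtin_scenario("fig3_base"), default_doses(n = 50))
  cd28 <- dplyr::filter(dr, readout == "phospho_cd28")
  expect_true(all(diff(cd28$normalized) <= 1e-6))
  # at a high dose CD28 has lost far more signal than CD3zeta
  cd3 <- dplyr::filter(dr, readout == "phospho_cd3")
  at1000 <- which.min(abs(cd28$dose_nm - 1000))
  expect_gt(cd28$inhibition[at1000], 4 * cd3$inhibition[at1000])
})

test_that("Hill fits recover exact parameters on noiseless curves", {
  x <- 10^seq(0, 4, length.out = 25)
  f <- fit_hill(x, hill_curve(x, 1, 1.25, 126.3))
  expect_true(f$converged)
  expect_equal(f$k_max, 1, tolerance = 1e-6)
  expect_equal(f$n_hill, 1.25, tolerance = 1e-6)
  expect_equal(f$ic50, 126.3, tolerance = 1e-6)
  # round trip over 50 random parameter triples
  set.seed(88)
  for (i in 1:50) {
    k <- runif(1, 0.3, 1); n <- runif(1, 0.5, 3)
    ic50 <- 10^runif(1, 1, 3.6)
    g <- fit_hill(x, hill_curve(x, k, n, ic50))
    expect_lt(abs(g$k_max / k - 1), 1e-6)
    expect_lt(abs(g$n_hill / n - 1), 1e-6)
    expect_lt(abs(g$ic50 / ic50 - 1), 1e-6)
  }
})

test_that("Hill fits tolerate 1% multiplicative noise", {
  x <- 10^seq(0, 4, length.out = 30)
  truth <- hill_curve(x, 0.9, 1.3, 400)
  set.seed(512)
  ic50s <- replicate(20, {
    fit_hill(x, truth * (1 + rnorm(length(x), 0, 0.01)))$ic50
  })
  expect_lt(abs(median(ic50s) / 400 - 1), 0.05)
})

test_that("flat inhibition curves are flagged non-identifiable, not errors", {
  x <- 10^seq(0, 3, length.out = 10)
  f <- fit_hill(x, rep(0, 10))
  expect_false(f$converged)
  expect_true(is.na(f$ic50))
  expect_error(fit_hill(x[1:3], c(0, 0.5, 1)), "at least 4")
})

test_that("tidy and glance expose the fitted Hill parameters", {
  x <- 10^seq(0, 4, length.out = 12)
  f <- fit_hill(x, hill_curve(x, 1, 2, 100))
  td <- tidy(f)
  expect_equal(td$term, c("k_max", "n_hill", "ic50"))
  expect_equal(td$estimate[3], 100, tolerance = 1e-6)
  gl <- glance(f)
  expect_true(gl$converged)
  expect_lt(gl$rss, 1e-12)
})

test_that("doubling the dose grid moves fitted IC50s by under 2%", {
  tb30 <- ic50_table(doses = default_doses(30))
  tb60 <- ic50_table(doses = default_doses(60))
  expect_true(all(abs(tb60$ic50_molecules_per_um2 /
                        tb30$ic50_molecules_per_um2 - 1) < 0.02))
})

test_that("a 1x1 2-D scan equals the single endpoint", {
  base <- builtin_scenario("fig4")
  g <- scan_2d(base, "lckT", 100, "pd1T", 300, "pct_bound_shp2")
  pools <- base$pools; pools["lckT"] <- 100; pools["pd1T"] <- 300
  single <- endpoint(scenario(pools = pools))$pct_bound_shp2
  expect_equal(g$value, single)
  expect_error(scan_2d(base, "nope", 1, "pd1T", 1, "pct_bound_shp2"),
               "pool names")
  expect_error(scan_2d(base, "lckT", 1, "pd1T", 1, "nope"), "readout")
})

test_that("above 100 nM Lck, active-Lck fraction falls with PD-1 dose", {
  g <- scan_2d(builtin_scenario("fig7"), "lckT", c(200, 400),
               "pd1T", c(100, 300, 600), "pct_active_lck")
  for (l in c(200, 400)) {
    v <- g$value[g$lckT == l]
    expect_true(all(diff(v) < 0))
  }
})

test_that("self-dephosphorylation lowers bound Shp2 for Lck up to 500 nM", {
  base_on <- builtin_scenario("fig4", pd1T = 300)
  base_off <- builtin_scenario("fig4", pd1T = 300,
                               flags = perturbation_flags(
                                 pd1_self_dephosphorylation = FALSE))
  for (l in c(50, 200, 500)) {
    on <- scan_2d(base_on, "lckT", l, "pd1T", 300, "pct_bound_shp2")$value
    off <- scan_2d(base_off, "lckT", l, "pd1T", 300,
                   "pct_bound_shp2")$value
    expect_lte(on, off)
  }
})
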