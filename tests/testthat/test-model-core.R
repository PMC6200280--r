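# Model core: correction factor, right-hand side, readouts.

test_that("correction factor matches its closed form and clamps at zero", {
  expect_equal(correction_factor(0, 0, 100), 1)
  expect_equal(correction_factor(1025, 1025, 100), 0.5)  # 1 - 2050/4100
  # vanishes exactly at the cap and is clamped beyond it
  cap <- 100 * 41
  expect_equal(correction_factor(cap / 2, cap / 2, 100), 0)
  expect_equal(correction_factor(cap, cap, 100), 0)
  expect_error(correction_factor(10, 0, 0), "lckT")
  expect_error(correction_factor(-1, 0, 100), "non-negative")
})

test_that("rhs of the empty system is identically zero", {
  pools <- pd1_pools(cd3T = 0, cd28T = 0, zap70T = 0, pi3kT = 0, lckT = 0,
                     latT = 0, gadsT = 0, slp76T = 0, shp2T = 0, pd1T = 0)
  d <- pd1_rhs(species_state(), pools)
  expect_true(all(d == 0))
})

test_that("rhs agrees with an independent transcription on 100 random states", {
  set.seed(421)
  worst <- 0
  for (i in 1:100) {
    sp <- random_state_pools()
    d_pkg <- pd1_rhs(sp$state, sp$pools)
    d_orc <- oracle_rhs(sp$state, sp$pools, pd1_params())
    scale <- pmax(abs(d_orc), 1e-6)
    worst <- max(worst, max(abs(d_pkg - d_orc) / scale))
  }
  expect_lt(worst, 1e-12)
})

test_that("PD-1 and Shp2 family derivatives sum to zero by construction", {
  set.seed(7)
  for (i in 1:20) {
    sp <- random_state_pools()
    d <- pd1_rhs(sp$state, sp$pools)
    expect_equal(d[["pd1"]] + d[["pd1p1"]] + d[["pd1p2"]] +
                   d[["cp1"]] + d[["cp2"]], 0)
    expect_equal(d[["shp2"]] + d[["cp1"]] + d[["cp2"]], 0)
  }
})

test_that("dephosphorylation requires PD-1-bound Shp2 and phosphorylation requires active Lck", {
  pools <- pd1_pools(pd1T = 300)
  # cp1 = cp2 = 0: derivatives are invariant to the phosphatase rate
  # constants, i.e. every dephosphorylation flux is exactly zero
  s1 <- species_state(cd3a = 50, cd28a = 50, lck_yi = 40, lck_ya = 20,
                      pd1p1 = 10, pd1p2 = 5, shp2 = 300, pd1 = 285,
                      zap70i = 30, lata = 10)
  d_on <- pd1_rhs(s1, pools)
  d_off <- pd1_rhs(s1, pools,
                   flags = perturbation_flags(
                     shp2_receptor_catalysis = FALSE,
                     shp2_lck_catalysis = FALSE))
  no_cp2_terms <- setdiff(names(d_on), c("cp1", "cp2"))
  expect_identical(d_on[no_cp2_terms], d_off[no_cp2_terms])
  # lck_active = 0: derivatives are invariant to every Lck-catalysed
  # phosphorylation constant (kinase fluxes all zero)
  s2 <- species_state(cd3a = 50, cd28a = 50, lck_yi = 50, pd1 = 300,
                      shp2 = 300, zap70i = 30, zap70a1 = 10)
  d_base <- pd1_rhs(s2, pools)
  p_nok <- pd1_params(k_p_cd3 = 99, k_p_cd28 = 99, k_p_pd1 = 99,
                      k_p1_zap = 99, k_p2_zap = 99)
  d_alt <- pd1_rhs(s2, pools, params = p_nok)
  expect_identical(d_base, d_alt)
  # free Shp2 alone (no CP complex) has no catalytic activity: a purely
  # phosphorylated state with inert Lck is frozen except for association
  s3 <- species_state(cd3a = 80, shp2 = 300)
  d3 <- pd1_rhs(s3, pd1_pools(zap70T = 0))
  expect_equal(d3[["cd3a"]], 0)
})

test_that("perturbation flags zero exactly the advertised rate groups", {
  p <- pd1_params()
  expect_identical(apply_flags(p, perturbation_flags()), p)
  lck_off <- apply_flags(p, perturbation_flags(shp2_lck_catalysis = FALSE))
  zeroed <- c("k_dpa_yiya", "k_dpi_yi", "k_dpi_yiya", "k_dpa_ya", "k_dpa_pi")
  expect_true(all(lck_off[zeroed] == 0))
  expect_identical(lck_off[setdiff(names(p), zeroed)],
                   p[setdiff(names(p), zeroed)])
  self_off <- apply_flags(p, perturbation_flags(
    pd1_self_dephosphorylation = FALSE))
  expect_true(all(self_off[c("k_dp_cp2", "k_d2_shp")] == 0))
})

test_that("readouts aggregate the state exactly as defined", {
  pools <- pd1_pools(lckT = 100)
  r <- readouts(species_state(lck_yiya = 25, lck_ya = 25, lck_yi = 25),
                pools)
  expect_equal(r$pct_active_lck, 50)
  expect_equal(r$lck_pY505, 50)
  expect_equal(r$lck_pY394, 50)
  r2 <- readouts(species_state(zap70a1 = 2, zap70a2 = 3), pools)
  expect_equal(r2$zap70_pY315, 5)
  expect_equal(r2$zap70_pY493, 3)
  r0 <- readouts(species_state(), pools)
  expect_true(all(r0[c("phospho_cd3", "phospho_cd28", "phospho_lat",
                       "phospho_slp76", "lck_active")] == 0))
  # undefined percentage: NA by default, error when strict
  pools0 <- pd1_pools(lckT = 0)
  expect_true(is.na(readouts(species_state(), pools0)$pct_active_lck))
  expect_error(readouts(species_state(), pools0, strict = TRUE),
               "active Lck")
})

test_that("rhs rejects invalid states", {
  s <- species_state()
  s["cd3a"] <- -1e-6
  expect_error(pd1_rhs(s, pd1_pools()), "negative")
  # soft clip: tiny negatives are treated as zero
  s["cd3a"] <- -1e-10
  expect_silent(pd1_rhs(s, pd1_pools()))
})

test_that("parameter defaults carry the documented units and values", {
  tb <- param_table()
  expect_equal(nrow(tb), 36)
  expect_equal(tb$value[tb$parameter == "k_corr"], 41)
  expect_equal(sum(tb$unit == "(nM s)^-1"), 14)
  expect_equal(sum(tb$unit == "s^-1"), 16)
  expect_equal(sum(tb$unit == "nM"), 5)
  expect_error(pd1_params(k_a_shp = -1), "positive")
  expect_error(pd1_params(nope = 1), "unknown")
})
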