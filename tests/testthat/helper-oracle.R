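# Independent hand-transcription of the 20 rate equations, used as the
# oracle against the package's compiled right-hand side.  Written as a
# direct equation-by-equation transcription (no shared code with the
# implementation).

oracle_rhs <- function(state, pools, params) {
  y <- as.list(state)
  p <- as.list(params)
  q <- as.list(pools)
  with(c(y, p, q), {
    lck_act <- lck_yiya + lck_ya
    cp_act <- cp1 + cp2
    free_cd3 <- cd3T - (cd3a + zap70i + zap70a1 + zap70a2)
    free_cd28 <- cd28T - (cd28a + pi3kb)
    free_zap <- zap70T - (zap70i + zap70a1 + zap70a2)
    free_pi3k <- pi3kT - pi3kb
    free_lck <- lckT - (lck_yiya + lck_yi + lck_ya + lck_pi)
    free_lat <- latT - (lata + gadsa + slp76i + slp76a)
    free_gads <- gadsT - (gadsa + slp76i + slp76a)
    free_slp <- slp76T - (slp76i + slp76a)
    corr <- if (lckT > 0) max(0, 1 - (pd1p1 + pd1p2) / (lckT * k_corr)) else 0

    c(cd3a = k_p_cd3 * lck_act * free_cd3 / (KM_p_cd3 + free_cd3) -
        k_dp_cd3 * cp_act * cd3a / (KM_dp_cd3 + cd3a) +
        k_d_zap * zap70i - k_a_zap * cd3a * free_zap,
      cd28a = k_p_cd28 * lck_act * free_cd28 / (KM_p_cd28 + free_cd28) -
        k_dp_cd28 * cp_act * cd28a / (KM_dp_cd28 + cd28a) +
        k_d_pi3k * pi3kb - k_a_pi3k * cd28a * free_pi3k,
      pd1 = -k_p_pd1 * lck_act * pd1 / (KM_p_pd1 + pd1) * corr +
        k_d2_shp * cp1,
      pd1p1 = k_p_pd1 * lck_act * pd1 / (KM_p_pd1 + pd1) * corr -
        k_p_pd1 * pd1p1 * lck_act / (KM_p_pd1 + pd1p1) -
        k_a_shp * pd1p1 * shp2 + k_d1_shp * cp1 + k_d2_shp * cp2,
      pd1p2 = k_p_pd1 * pd1p1 * lck_act / (KM_p_pd1 + pd1p1) -
        k_a_shp * pd1p2 * shp2 + k_d1_shp * cp2,
      shp2 = -k_a_shp * shp2 * (pd1p1 + pd1p2) +
        k_d1_shp * (cp1 + cp2) + k_d2_shp * (cp1 + cp2),
      cp1 = k_dp_cp2 * cp2 + k_a_shp * pd1p1 * shp2 -
        k_d1_shp * cp1 - k_d2_shp * cp1,
      cp2 = -k_dp_cp2 * cp2 + k_a_shp * pd1p2 * shp2 -
        k_d1_shp * cp2 - k_d2_shp * cp2,
      lck_yiya = -k_dpa_yiya * cp_act * lck_yiya -
        k_dpi_yiya * cp_act * lck_yiya + k_pi_ya * lck_ya,
      lck_yi = k_dpa_yiya * cp_act * lck_yiya -
        k_dpi_yi * cp_act * lck_yi + k_pi_i * free_lck -
        k_pa_yi * lck_yi + k_dpa_pi * cp_act * lck_pi,
      lck_ya = k_dpi_yiya * cp_act * lck_yiya - k_pi_ya * lck_ya -
        k_dpa_ya * cp_act * lck_ya + k_pa_i * free_lck,
      lck_pi = -k_dpa_pi * cp_act * lck_pi + k_pa_yi * lck_yi,
      zap70i = k_a_zap * cd3a * free_zap - k_d_zap * zap70i -
        k_p1_zap * lck_act * zap70i,
      zap70a1 = k_p1_zap * lck_act * zap70i -
        k_p2_zap * lck_act * zap70a1,
      zap70a2 = k_p2_zap * lck_act * zap70a1,
      lata = k_p_lat * zap70a2 * free_lat -
        k_a_gads * lata * free_gads + k_d_gads * gadsa,
      slp76i = k_a_slp * gadsa * free_slp - k_d_slp * slp76i -
        k_p_slp * slp76i * zap70a2,
      slp76a = k_p_slp * slp76i * zap70a2,
      gadsa = k_a_gads * lata * free_gads - k_d_gads * gadsa -
        k_a_slp * gadsa * free_slp + k_d_slp * slp76i,
      pi3kb = k_a_pi3k * cd28a * free_pi3k - k_d_pi3k * pi3kb)
  })
}

# random valid (state, pools) pair: pools first, then a state respecting
# every conservation bound
random_state_pools <- function() {
  pools <- pd1_pools(cd3T = runif(1, 50, 800), cd28T = runif(1, 50, 800),
                     zap70T = runif(1, 50, 500), pi3kT = runif(1, 50, 500),
                     lckT = runif(1, 5, 500), latT = runif(1, 50, 500),
                     gadsT = runif(1, 50, 500), slp76T = runif(1, 50, 500),
                     shp2T = runif(1, 50, 500), pd1T = runif(1, 0, 1000))
  split4 <- function(total, k) {
    w <- runif(k + 1)
    (total * w / sum(w))[seq_len(k)]  # leaves a free remainder
  }
  zap <- split4(min(pools[["zap70T"]], pools[["cd3T"]]) * 0.9, 3)
  cd3a <- runif(1, 0, pools[["cd3T"]] - sum(zap))
  lck <- split4(pools[["lckT"]], 4)
  adapters <- split4(min(pools[["latT"]], pools[["gadsT"]],
                         pools[["slp76T"]]) * 0.9, 3)  # gadsa, slp76i, slp76a
  lata <- runif(1, 0, pools[["latT"]] - sum(adapters))
  cp <- split4(min(pools[["shp2T"]], pools[["pd1T"]]), 2)
  pd1p <- split4(pools[["pd1T"]] - sum(cp), 2)
  pi3kb <- runif(1, 0, min(pools[["pi3kT"]], pools[["cd28T"]]) * 0.9)
  cd28a <- runif(1, 0, pools[["cd28T"]] - pi3kb)
  state <- species_state(
    cd3a = cd3a, cd28a = cd28a,
    pd1 = max(pools[["pd1T"]] - sum(cp) - sum(pd1p), 0),
    pd1p1 = pd1p[1], pd1p2 = pd1p[2],
    shp2 = pools[["shp2T"]] - sum(cp), cp1 = cp[1], cp2 = cp[2],
    lck_yiya = lck[1], lck_yi = lck[2], lck_ya = lck[3], lck_pi = lck[4],
    zap70i = zap[1], zap70a1 = zap[2], zap70a2 = zap[3],
    lata = lata, slp76i = adapters[2], slp76a = adapters[3],
    gadsa = adapters[1], pi3kb = pi3kb)
  list(state = state, pools = pools)
}

# exact Hill curve generator for fit-recovery tests
hill_curve <- function(x, k, n, ic50) k * x^n / (ic50^n + x^n)
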