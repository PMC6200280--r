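# Canonical name orderings shared across the package (and with the
# compiled right-hand side, which indexes parameters positionally).

# canonical ordering shared with the C right-hand side
.rate_names <- c(
  "k_dpa_yiya", "k_dpi_yi", "k_dpi_yiya", "k_dpa_ya", "k_dpa_pi",
  "k_a_zap", "k_p1_zap", "k_p2_zap", "k_p_lat", "k_a_slp", "k_p_slp",
  "k_a_gads", "k_a_pi3k", "k_a_shp",
  "k_pi_i", "k_pi_ya", "k_pa_i", "k_pa_yi",
  "k_p_cd3", "k_dp_cd3", "k_d_zap", "k_d_slp", "k_d_gads",
  "k_p_cd28", "k_dp_cd28", "k_d_pi3k", "k_p_pd1",
  "k_d1_shp", "k_dp_cp2", "k_d2_shp",
  "KM_p_cd3", "KM_dp_cd3", "KM_p_cd28", "KM_dp_cd28", "KM_p_pd1",
  "k_corr")

.pool_names <- c("cd3T", "cd28T", "zap70T", "pi3kT", "lckT",
                 "latT", "gadsT", "slp76T", "shp2T", "pd1T")

.second_order <- .rate_names[1:14]            # (nM s)^-1
.first_order  <- .rate_names[15:30]           # s^-1
.michaelis    <- .rate_names[31:35]           # nM

.species_names <- c(
  "cd3a", "cd28a", "pd1", "pd1p1", "pd1p2", "shp2", "cp1", "cp2",
  "lck_yiya", "lck_yi", "lck_ya", "lck_pi",
  "zap70i", "zap70a1", "zap70a2",
  "lata", "slp76i", "slp76a", "gadsa", "pi3kb")

.readout_names <- c(
  "lck_active", "cp_active", "phospho_cd3", "phospho_cd28",
  "zap70_pY315", "zap70_pY493", "lck_pY505", "lck_pY394",
  "phospho_lat", "phospho_slp76",
  "pct_bound_shp2", "pct_bound_pi3k", "pct_bound_zap70", "pct_active_lck")

# readouts fit to Hill curves in the PD-1 dose-response analysis,
# in the conventional reporting order
.dose_readouts <- c("phospho_cd3", "phospho_cd28", "lck_pY505", "lck_pY394",
                    "zap70_pY315", "zap70_pY493", "phospho_lat",
                    "phospho_slp76")

.dose_molecules <- c(phospho_cd3 = "CD3zeta", phospho_cd28 = "CD28",
                     lck_pY505 = "Lck (Y505)", lck_pY394 = "Lck (Y394)",
                     zap70_pY315 = "Zap70 (Y315)", zap70_pY493 = "Zap70 (Y493)",
                     phospho_lat = "LAT", phospho_slp76 = "SLP76")
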