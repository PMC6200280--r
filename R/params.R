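# Kinetic parameters, conserved totals and the PD-1 correction factor.

#' Default kinetic parameters of the PD-1 signaling model
#'
#' Returns the 36 named rate constants of the model: second-order
#' phosphorylation/dephosphorylation and association constants in
#' (nM s)^-1, first-order catalytic and dissociation constants in s^-1,
#' Michaelis constants in nM, and the dimensionless constant `k_corr`
#' of the saturating correction applied to the first PD-1
#' phosphorylation step.
#'
#' Naming follows the field's subscript convention flattened with
#' underscores, e.g. `k_dpa_yiya` is the rate at which the PD-1-bound
#' Shp2 complexes remove the activating phosphotyrosine (Y394) from
#' doubly phosphorylated active Lck.
#'
#' @param ... Named overrides, e.g. `pd1_params(k_a_shp = 1e-3)`.
#' @return A named numeric vector of length 36.
#' @examples
#' p <- pd1_params()
#' p["k_p_pd1"]
#' @export
pd1_params <- function(...) {
  p <- c(
    k_dpa_yiya = 2.4e-5, k_dpi_yi = 2.4e-5, k_dpi_yiya = 1.2e-5,
    k_dpa_ya = 6e-6, k_dpa_pi = 1.2e-7,
    k_a_zap = 7e-5, k_p1_zap = 2e-6, k_p2_zap = 3e-5,
    k_p_lat = 1e-3, k_a_slp = 1.5e-2, k_p_slp = 3e-3,
    k_a_gads = 5e-4, k_a_pi3k = 1.4e-6, k_a_shp = 6.5e-3,
    k_pi_i = 6e-7, k_pi_ya = 6e-5, k_pa_i = 1e-6, k_pa_yi = 7.5e-4,
    k_p_cd3 = 3.29, k_dp_cd3 = 5, k_d_zap = 1e-3, k_d_slp = 0.12,
    k_d_gads = 1.5, k_p_cd28 = 1, k_dp_cd28 = 5, k_d_pi3k = 9e-4,
    k_p_pd1 = 7.5, k_d1_shp = 10, k_dp_cp2 = 5e-8, k_d2_shp = 1,
    KM_p_cd3 = 80, KM_dp_cd3 = 150, KM_p_cd28 = 1000, KM_dp_cd28 = 500,
    KM_p_pd1 = 1000, k_corr = 41)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), .rate_names)
    if (length(bad))
      abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    p[names(over)] <- unlist(over)
  }
  if (any(p <= 0))
    abort("all kinetic parameters must be strictly positive")
  p[.rate_names]
}

#' Parameter table with units
#'
#' @return A tibble with columns `parameter`, `value`, `unit` for the
#'   default parameter set.
#' @export
param_table <- function() {
  p <- pd1_params()
  unit <- rep("dimensionless", length(p))
  unit[names(p) %in% .second_order] <- "(nM s)^-1"
  unit[names(p) %in% .first_order] <- "s^-1"
  unit[names(p) %in% .michaelis] <- "nM"
  tibble(parameter = names(p), value = unname(p), unit = unit)
}

#' Conserved total concentrations
#'
#' The ten conserved protein pools of the model, in nM.  Defaults are the
#' reconstitution concentrations used for the full-network dose-response
#' simulations: 100 nM Lck and CD3zeta, 200 nM PI3K, 300 nM CD28, Zap70,
#' Shp2, LAT, Gads and Slp76, and no PD-1.
#'
#' @param ... Named overrides, e.g. `pd1_pools(pd1T = 300)`.
#' @return A named numeric vector of length 10.
#' @examples
#' pd1_pools(pd1T = 100)["pd1T"]
#' @export
pd1_pools <- function(...) {
  pools <- c(cd3T = 100, cd28T = 300, zap70T = 300, pi3kT = 200,
             lckT = 100, latT = 300, gadsT = 300, slp76T = 300,
             shp2T = 300, pd1T = 0)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), .pool_names)
    if (length(bad))
      abort(paste0("unknown pool(s): ", paste(bad, collapse = ", ")))
    pools[names(over)] <- unlist(over)
  }
  if (any(pools < 0)) abort("total pools must be non-negative")
  pools[.pool_names]
}

#' Saturating correction factor for PD-1 phosphorylation
#'
#' Shp2 recruitment to PD-1 saturates at high PD-1 dose in reconstitution
#' experiments.  The model encodes this with a factor
#' `max(0, 1 - (pd1p1 + pd1p2) / (lckT * k_corr))` multiplying the flux of
#' the first PD-1 phosphorylation step only (unphosphorylated to singly
#' phosphorylated PD-1).  The factor is clamped at zero from below so the
#' phosphorylation flux can never turn negative.
#'
#' @param pd1p1,pd1p2 Singly and doubly phosphorylated PD-1 (nM).
#' @param lckT Total Lck (nM); must be positive.
#' @param k_corr Dimensionless constant (default 41).
#' @return Dimensionless scalar in `[0, 1]`.
#' @examples
#' correction_factor(0, 0, 100)        # 1
#' correction_factor(1025, 1025, 100)  # 0.5
#' @export
correction_factor <- function(pd1p1, pd1p2, lckT,
                              k_corr = pd1_params()[["k_corr"]]) {
  if (any(pd1p1 < 0) || any(pd1p2 < 0))
    abort("phosphorylated PD-1 concentrations must be non-negative")
  if (lckT <= 0)
    abort("correction factor undefined for lckT <= 0")
  if (k_corr <= 0) abort("k_corr must be positive")
  pmax(0, 1 - (pd1p1 + pd1p2) / (lckT * k_corr))
}
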