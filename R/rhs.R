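# Single-point evaluation of the model's right-hand side.

.build_parms <- function(params, pools, clamp_cp2 = NULL) {
  c(unname(params[.rate_names]), unname(pools[.pool_names]),
    as.numeric(!is.null(clamp_cp2)),
    if (is.null(clamp_cp2)) 0 else clamp_cp2)
}

#' Time derivatives of the 20 model species
#'
#' Evaluates the model's right-hand side at a single state: the 20
#' coupled rate equations with Michaelis-Menten kinetics for receptor
#' and PD-1 (de)phosphorylation and mass action elsewhere.  Free pools
#' are obtained from the conservation relations, dephosphorylation is
#' catalysed exclusively by the PD-1-bound Shp2 complexes, and the first
#' PD-1 phosphorylation step carries the saturating
#' [correction_factor()].
#'
#' States with components between `-1e-9` and `0` nM (integrator
#' under-shoot) are clipped to zero; larger negative values are a domain
#' error.
#'
#' @param state Named species vector, see [species_state()].
#' @param pools Named totals, see [pd1_pools()].
#' @param params Named rate constants, see [pd1_params()].
#' @param flags Perturbation switches, see [perturbation_flags()];
#'   applied by zeroing the corresponding rate constants.
#' @return Named numeric vector of derivatives (nM/s).
#' @examples
#' pd1_rhs(species_state(pd1 = 300, shp2 = 300, lck_ya = 25),
#'         pd1_pools(pd1T = 300))
#' @export
pd1_rhs <- function(state, pools, params = pd1_params(),
                    flags = perturbation_flags()) {
  s <- state[.species_names]
  if (anyNA(s)) abort("state must contain all 20 species")
  if (any(s < -1e-9))
    abort(paste0("negative species concentration: ",
                 paste(.species_names[s < -1e-9], collapse = ", ")))
  s <- pmax(s, 0)
  params <- apply_flags(params, flags)
  parms <- .build_parms(params, pools, flags$clamp_cp2)
  d <- .Call(C_pd1_deriv, as.numeric(s), as.numeric(parms))
  if (any(!is.finite(d)))
    abort(paste0("non-finite derivative for species: ",
                 paste(.species_names[!is.finite(d)], collapse = ", ")))
  setNames(d, .species_names)
}
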