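# Stiff integration of scenarios and unit conversion.

.solver_rtol <- 1e-8
.solver_atol <- 1e-12

# core integrator: returns deSolve matrix at the requested times
.integrate_raw <- function(sc, times, rtol = .solver_rtol,
                           atol = .solver_atol) {
  params <- apply_flags(sc$params, sc$flags)
  parms <- .build_parms(params, sc$pools, sc$flags$clamp_cp2)
  out <- lsoda(y = unname(sc$initial_state[.species_names]),
               times = times,
               func = "pd1_derivs", parms = parms,
               dllname = "pd1sig", initfunc = "pd1_initmod",
               rtol = rtol, atol = atol, maxsteps = 50000)
  if (nrow(out) < length(times))
    abort(paste0("integration of scenario '", sc$label,
                 "' failed at t = ", max(out[, 1]), " s"))
  colnames(out) <- c("time", .species_names)
  out
}

#' Integrate a scenario over time
#'
#' Solves the 20-species model with a stiff-capable variable-step solver
#' (lsoda; relative tolerance 1e-8, absolute tolerance 1e-12 nM) and
#' returns the trajectory on an even output grid together with all
#' derived readouts.  Conservation of the PD-1 and Shp2 families and
#' non-negativity are checked on every stored point.
#'
#' @param sc A `"pd1_scenario"`.
#' @param n_points Number of output points (default 200, evenly spaced
#'   over `[0, duration]`).
#' @param times Optional explicit output times (seconds, starting at 0);
#'   overrides `n_points`.
#' @param check Verify conservation/non-negativity invariants
#'   (default `TRUE`; skipped for clamped-CP2 scenarios, whose constant
#'   catalytic pool is exempt from the Shp2/PD-1 totals).
#' @return A tibble with class `"pd1_trajectory"`: `time`, the 20
#'   species (nM) and the 14 derived readouts.
#' @examples
#' tr <- simulate_scenario(builtin_scenario("fig3_base", pd1T = 100))
#' tail(tr[, c("time", "pct_bound_shp2", "phospho_cd28")], 1)
#' @export
simulate_scenario <- function(sc, n_points = 200, times = NULL,
                              check = TRUE) {
  if (!inherits(sc, "pd1_scenario")) abort("sc must be a pd1_scenario")
  if (is.null(times)) {
    if (n_points < 2) abort("n_points must be at least 2")
    times <- seq(0, sc$duration, length.out = n_points)
  }
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    abort("times must start at 0 and be strictly increasing")
  out <- .integrate_raw(sc, times)
  df <- as_tibble(as.data.frame(out))
  if (check && is.null(sc$flags$clamp_cp2)) {
    tot <- .conservation_totals(df, sc$pools)
    if (max(abs(tot$pd1_family - sc$pools[["pd1T"]])) > 1e-6 ||
        max(abs(tot$shp2_family - sc$pools[["shp2T"]])) > 1e-6)
      abort(paste0("conservation drift beyond 1e-6 nM in scenario '",
                   sc$label, "'"))
    if (min(as.matrix(df[, .species_names])) < -1e-9)
      abort(paste0("species below -1e-9 nM in scenario '", sc$label, "'"))
  }
  res <- dplyr::bind_cols(df, readouts(df[.species_names], sc$pools))
  attr(res, "scenario_label") <- sc$label
  class(res) <- c("pd1_trajectory", class(res))
  res
}

#' Endpoint readouts of a scenario
#'
#' Integrates the scenario to `t_end` (default 1800 s, the 30-minute
#' reporting convention of the reconstitution experiments) and returns
#' the derived readouts at that instant.
#'
#' @param sc A `"pd1_scenario"`.
#' @param t_end Endpoint in seconds; must not exceed the scenario
#'   duration.
#' @return One-row tibble of derived readouts.
#' @examples
#' endpoint(builtin_scenario("fig3_base", pd1T = 300))$pct_bound_shp2
#' @export
endpoint <- function(sc, t_end = 1800) {
  if (t_end > sc$duration)
    abort("t_end exceeds the scenario duration")
  if (t_end == 0)
    return(readouts(sc$initial_state, sc$pools))
  out <- .integrate_raw(sc, c(0, t_end))
  readouts(out[nrow(out), .species_names], sc$pools)
}

#' nM to surface-density conversion
#'
#' The reconstitution experiments anchor proteins on large unilamellar
#' vesicles, so solution concentrations map to membrane surface
#' densities.  With protein surface density `d = N / sigma`,
#' `N = [P] V N_A` molecules and exposed membrane area
#' `sigma = [L] V N_A f a_L`, the factor is
#' `d/[P] = 1 / ([L] f a_L)`.  The defaults (1 mM lipid, 52.6% of lipid
#' in the outer leaflet, 0.65 nm^2 per lipid head) give the conventional
#' 2.9 molecules/um^2 per nM.
#'
#' @param lipid_mM Total lipid concentration (mM).
#' @param exposed_fraction Fraction of lipid in the outer leaflet.
#' @param lipid_head_area_nm2 Area per lipid head group (nm^2).
#' @return Conversion factor in molecules/um^2 per nM.
#' @examples
#' density_conversion_factor()  # ~2.9
#' @export
density_conversion_factor <- function(lipid_mM = 1,
                                      exposed_fraction = 0.526,
                                      lipid_head_area_nm2 = 0.65) {
  if (lipid_mM <= 0 || exposed_fraction <= 0 || lipid_head_area_nm2 <= 0)
    abort("conversion spec values must be positive")
  # [L] in molecules/nm^3: lipid_mM * 1e-3 mol/L * N_A / 1e24 nm^3/L
  n_a <- 6.02214076e23
  lipid_per_nm3 <- lipid_mM * 1e-3 * n_a / 1e24
  per_nm2 <- 1e-9 * n_a / 1e24 / (lipid_per_nm3 * exposed_fraction *
                                    lipid_head_area_nm2) # per nM, nm^-2
  per_nm2 * 1e6  # molecules/um^2 per nM
}

#' Convert between nM and PD-1 surface density
#'
#' Linear scaling by the vesicle conversion factor (default 2.9
#' molecules/um^2 per nM); the two functions are exact inverses.
#'
#' @param x Concentration (nM) or surface density (molecules/um^2);
#'   non-negative.
#' @param factor Conversion factor, see [density_conversion_factor()].
#' @return The converted value(s).
#' @examples
#' nm_to_density(1)          # 2.9
#' density_to_nm(nm_to_density(7)) # 7
#' @export
nm_to_density <- function(x, factor = 2.9) {
  if (any(x < 0)) abort("concentrations must be non-negative")
  x * factor
}

#' @rdname nm_to_density
#' @export
density_to_nm <- function(x, factor = 2.9) {
  if (any(x < 0)) abort("densities must be non-negative")
  x / factor
}
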