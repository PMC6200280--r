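# Scenario construction: perturbation flags, the builtin catalogue of
# reconstitution-system experiments, randomized scenarios, config files.

#' Perturbation switches of the model
#'
#' Each flag enables (default) or disables a group of reaction fluxes,
#' emulating the knockout protocols of the reconstitution experiments:
#'
#' * `shp2_receptor_catalysis` — dephosphorylation of CD3zeta and CD28
#'   by the PD-1-bound Shp2 complexes (`k_dp_cd3`, `k_dp_cd28`).
#' * `shp2_lck_catalysis` — dephosphorylation of all Lck forms
#'   (`k_dpa_yiya`, `k_dpi_yi`, `k_dpi_yiya`, `k_dpa_ya`, `k_dpa_pi`).
#' * `pd1_self_dephosphorylation` — self-dephosphorylation of PD-1 by its
#'   bound Shp2 (`k_dp_cp2`, `k_d2_shp`).
#' * `pd1_phosphorylation` — phosphorylation of PD-1 by Lck (`k_p_pd1`).
#' * `clamp_cp2` — optional nM value: holds the doubly phosphorylated
#'   PD-1-Shp2 complex constant as a pure catalytic pool (its binding,
#'   dissociation and self-dephosphorylation fluxes are disabled),
#'   the proxy for membrane-anchored Shp2.
#'
#' @param shp2_receptor_catalysis,shp2_lck_catalysis,pd1_self_dephosphorylation,pd1_phosphorylation
#'   Logical switches, all `TRUE` by default.
#' @param clamp_cp2 `NULL` (dynamic CP2) or a non-negative nM value.
#' @return A list with class `"pd1_flags"`.
#' @export
perturbation_flags <- function(shp2_receptor_catalysis = TRUE,
                               shp2_lck_catalysis = TRUE,
                               pd1_self_dephosphorylation = TRUE,
                               pd1_phosphorylation = TRUE,
                               clamp_cp2 = NULL) {
  if (!is.null(clamp_cp2) && clamp_cp2 < 0)
    abort("clamp_cp2 must be non-negative")
  structure(list(shp2_receptor_catalysis = shp2_receptor_catalysis,
                 shp2_lck_catalysis = shp2_lck_catalysis,
                 pd1_self_dephosphorylation = pd1_self_dephosphorylation,
                 pd1_phosphorylation = pd1_phosphorylation,
                 clamp_cp2 = clamp_cp2),
            class = "pd1_flags")
}

#' Apply perturbation flags to a parameter set
#'
#' Returns a copy of `params` with the rate constants of every disabled
#' flux group set to zero; the input is untouched.  `clamp_cp2` does not
#' modify parameters (it is handled inside the right-hand side).
#'
#' @param params Named rate constants, see [pd1_params()].
#' @param flags See [perturbation_flags()].
#' @return Named numeric vector of length 36.
#' @export
apply_flags <- function(params, flags) {
  p <- params
  tiny <- 0  # disabled fluxes are exactly zero
  if (!flags$shp2_lck_catalysis)
    p[c("k_dpa_yiya", "k_dpi_yi", "k_dpi_yiya", "k_dpa_ya", "k_dpa_pi")] <- tiny
  if (!flags$pd1_self_dephosphorylation)
    p[c("k_dp_cp2", "k_d2_shp")] <- tiny
  if (!flags$shp2_receptor_catalysis)
    p[c("k_dp_cd3", "k_dp_cd28")] <- tiny
  if (!flags$pd1_phosphorylation)
    p["k_p_pd1"] <- tiny
  p
}

.default_lck_split <- c(i = 0.25, ya = 0.25, yi = 0.25, yiya = 0.25, pi = 0)

#' Define a runnable simulation scenario
#'
#' A scenario bundles everything one integration needs: conserved pools,
#' initial state, rate parameters, perturbation flags, duration and the
#' initial distribution of Lck across its phosphoforms.  By default all
#' protein is unphosphorylated and unbound at time zero except Lck, which
#' starts 25% in each of the unphosphorylated, Y394-only, Y505-only and
#' sequentially double-phosphorylated (active) forms, matching the
#' phosphoform proportions measured in Jurkat T cells; the
#' consecutively double-phosphorylated inactive form starts at zero.
#'
#' @param pools Named totals, see [pd1_pools()].
#' @param params Named rate constants, see [pd1_params()].
#' @param flags See [perturbation_flags()].
#' @param duration Simulated time in seconds (default 1800 s = 30 min,
#'   the standard endpoint of the reconstitution experiments).
#' @param lck_split Fractions of `lckT` initially in the `i`, `ya`, `yi`,
#'   `yiya` and `pi` forms; must sum to 1.
#' @param initial Named list of initial species overrides (nM), e.g.
#'   `list(zap70i = 300)`.  Free Shp2 and unphosphorylated PD-1 are
#'   filled in from their conservation totals.
#' @param label Scenario label used in outputs.
#' @return A list with class `"pd1_scenario"`.
#' @examples
#' sc <- scenario(pd1_pools(pd1T = 300))
#' sc$initial_state[c("pd1", "shp2", "lck_ya")]
#' @export
scenario <- function(pools = pd1_pools(), params = pd1_params(),
                     flags = perturbation_flags(), duration = 1800,
                     lck_split = .default_lck_split, initial = list(),
                     label = "custom") {
  if (duration <= 0) abort("duration must be positive")
  if (abs(sum(lck_split) - 1) > 1e-12)
    abort("lck_split must sum to 1")
  if (any(lck_split < 0)) abort("lck_split fractions must be non-negative")
  lckT <- pools[["lckT"]]
  init <- species_state()
  init["lck_ya"] <- lck_split[["ya"]] * lckT
  init["lck_yi"] <- lck_split[["yi"]] * lckT
  init["lck_yiya"] <- lck_split[["yiya"]] * lckT
  init["lck_pi"] <- lck_split[["pi"]] * lckT
  if (length(initial)) {
    bad <- setdiff(names(initial), .species_names)
    if (length(bad))
      abort(paste0("unknown initial species: ", paste(bad, collapse = ", ")))
    init[names(initial)] <- unlist(initial)
  }
  if (!is.null(flags$clamp_cp2)) init["cp2"] <- flags$clamp_cp2
  # complete the conserved families
  init["shp2"] <- pools[["shp2T"]] - init[["cp1"]] - init[["cp2"]]
  init["pd1"] <- pools[["pd1T"]] - init[["pd1p1"]] - init[["pd1p2"]] -
    init[["cp1"]] - init[["cp2"]]
  # a clamped CP2 pool is exempt from the PD-1/Shp2 totals
  if (!is.null(flags$clamp_cp2)) {
    init["shp2"] <- max(init[["shp2"]], 0)
    init["pd1"] <- max(init[["pd1"]], 0)
  }
  if (any(init < 0))
    abort("initial complexes inconsistent with pools (negative free species)")
  structure(list(label = label, pools = pools, initial_state = init,
                 params = params, flags = flags, duration = duration,
                 lck_split = lck_split),
            class = "pd1_scenario")
}

#' @export
print.pd1_scenario <- function(x, ...) {
  cat("<pd1_scenario>", x$label, "\n")
  cat("  duration:", x$duration, "s\n")
  nz <- x$pools[x$pools > 0]
  cat("  pools (nM):",
      paste(names(nz), unname(nz), sep = "=", collapse = ", "), "\n")
  off <- names(Filter(isFALSE, x$flags[1:4]))
  if (length(off)) cat("  disabled:", paste(off, collapse = ", "), "\n")
  if (!is.null(x$flags$clamp_cp2))
    cat("  clamp_cp2:", x$flags$clamp_cp2, "nM\n")
  invisible(x)
}

.scenario_catalogue <- c("fig2a", "fig2b", "fig2c", "fig2d", "fig2ef",
                         "fig3_base", "fig4", "fig5", "fig6", "fig7",
                         "fig8a", "fig8b")

#' Builtin catalogue of reconstitution-system scenarios
#'
#' Named scenarios encoding the simulation protocols of the published
#' reconstitution experiments.  Concentrations a protocol does not state
#' default to the dose-response base set (see [pd1_pools()]).
#'
#' * `fig2a` — Shp2 binding-domain-only recruitment: 7.2 nM Lck, 100 nM
#'   Shp2, PD-1 dose (default 100 nM); all Shp2 catalysis and PD-1
#'   self-dephosphorylation disabled, so binding is pure
#'   association/dissociation.
#' * `fig2b` — full-length Shp2 recruitment: 300 nM PD-1, 50 nM Shp2,
#'   Lck dose (default 100 nM); all catalysis on.
#' * `fig2c` — Zap70 vs PI3K recruitment without PD-1: 800 nM CD3zeta
#'   and CD28, 300 nM Zap70 and PI3K, 100 nM Lck.
#' * `fig2d` — receptor dephosphorylation by membrane-anchored Shp2
#'   without Lck or free PD-1: starts fully engaged (300 nM `zap70i`,
#'   300 nM `pi3kb`) with CP2 clamped at 200 nM.
#' * `fig2ef` — PD-1 effect on PI3K/Zap70 recruitment: 50 nM CD3zeta,
#'   300 nM Zap70, 250 nM CD28, 500 nM PI3K, 300 nM Lck, 100 nM PD-1
#'   and Shp2.
#' * `fig3_base` — full-network dose-response base (PD-1 set per dose).
#' * `fig4`/`fig5`/`fig6`/`fig7` — 2-D concentration-scan bases.
#' * `fig8a` — Lck dephosphorylation by Shp2 disabled (300 nM PD-1 and
#'   Shp2, 100 nM Lck).
#' * `fig8b` — PD-1 self-dephosphorylation disabled (same pools).
#'
#' @param name One of the catalogue names above.
#' @param ... Overrides: pool values (e.g. `pd1T = 300`), `duration`,
#'   `params`, `flags`, `initial`.
#' @return A `"pd1_scenario"`.
#' @examples
#' builtin_scenario("fig3_base", pd1T = 100)
#' @export
builtin_scenario <- function(name, ...) {
  if (!name %in% .scenario_catalogue)
    abort(paste0("unknown scenario '", name, "'; valid names: ",
                 paste(.scenario_catalogue, collapse = ", ")))
  over <- list(...)
  base <- switch(
    name,
    fig2a = list(pools = list(lckT = 7.2, shp2T = 100, pd1T = 100),
                 flags = perturbation_flags(
                   shp2_receptor_catalysis = FALSE,
                   shp2_lck_catalysis = FALSE,
                   pd1_self_dephosphorylation = FALSE)),
    fig2b = list(pools = list(pd1T = 300, shp2T = 50, lckT = 100)),
    fig2c = list(pools = list(cd3T = 800, cd28T = 800, zap70T = 300,
                              pi3kT = 300, lckT = 100, pd1T = 0)),
    fig2d = list(pools = list(lckT = 0, pd1T = 200, shp2T = 200,
                              cd3T = 300, cd28T = 300, zap70T = 300,
                              pi3kT = 300),
                 flags = perturbation_flags(clamp_cp2 = 200),
                 initial = list(zap70i = 300, pi3kb = 300)),
    fig2ef = list(pools = list(cd3T = 50, zap70T = 300, cd28T = 250,
                               pi3kT = 500, lckT = 300, pd1T = 100,
                               shp2T = 100)),
    fig3_base = list(pools = list()),
    fig4 = list(pools = list(shp2T = 300)),
    fig5 = list(pools = list(pd1T = 300, shp2T = 300)),
    fig6 = list(pools = list(shp2T = 300, lckT = 100)),
    fig7 = list(pools = list(pd1T = 300)),
    fig8a = list(pools = list(pd1T = 300, lckT = 100, shp2T = 300),
                 flags = perturbation_flags(shp2_lck_catalysis = FALSE)),
    fig8b = list(pools = list(pd1T = 300, lckT = 100, shp2T = 300),
                 flags = perturbation_flags(
                   pd1_self_dephosphorylation = FALSE)))
  pool_over <- over[names(over) %in% .pool_names]
  pools_args <- modifyList(base$pools, pool_over)
  pools <- do.call(pd1_pools, pools_args)
  flags <- over$flags %||% base$flags %||% perturbation_flags()
  scenario(pools = pools,
           params = over$params %||% pd1_params(),
           flags = flags,
           duration = over$duration %||% 1800,
           initial = over$initial %||% base$initial %||% list(),
           label = name)
}

#' List the builtin scenario catalogue
#' @return Character vector of scenario names.
#' @export
list_scenarios <- function() .scenario_catalogue

#' Randomized scenario generator
#'
#' Draws each conserved pool uniformly within the given bounds;
#' deterministic for a given seed.  Parameters and flags are the
#' defaults.  Intended for property-style testing of conservation and
#' integration robustness.
#'
#' @param seed Integer seed.
#' @param ranges Named list of `c(lower, upper)` bounds per pool (nM);
#'   pools not listed keep their default value.
#' @param duration Simulated seconds.
#' @return A `"pd1_scenario"`.
#' @examples
#' random_scenario(1, list(pd1T = c(0, 1000), lckT = c(10, 500)))
#' @export
random_scenario <- function(seed,
                            ranges = list(cd3T = c(10, 800),
                                          cd28T = c(10, 800),
                                          zap70T = c(10, 500),
                                          pi3kT = c(10, 500),
                                          lckT = c(1, 500),
                                          latT = c(10, 500),
                                          gadsT = c(10, 500),
                                          slp76T = c(10, 500),
                                          shp2T = c(10, 500),
                                          pd1T = c(0, 1000)),
                            duration = 1800) {
  bad <- setdiff(names(ranges), .pool_names)
  if (length(bad))
    abort(paste0("unknown pool(s) in ranges: ", paste(bad, collapse = ", ")))
  pools <- pd1_pools()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (nm in names(ranges)) {
    b <- ranges[[nm]]
    if (b[1] < 0 || b[2] < b[1])
      abort(paste0("invalid bounds for ", nm))
    pools[nm] <- runif(1, b[1], b[2])
  }
  scenario(pools = pools, duration = duration,
           label = paste0("random_", seed))
}

# keep random scenario generation from touching global random state
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write / read a scenario as a flat text config
#'
#' Scenarios round-trip through a human-editable flat key-value format
#' with `pools`, `initial`, `params`, `flags` and `run` sections.
#'
#' @param x A `"pd1_scenario"`.
#' @param path File path.
#' @return `write_scenario` returns `path` invisibly; `read_scenario`
#'   returns the reconstructed scenario.
#' @export
write_scenario <- function(x, path) {
  fmt <- function(v) sprintf("%.17g", v)
  lines <- c(
    "[run]",
    paste0("label = ", x$label),
    paste0("duration = ", fmt(x$duration)),
    "[pools]",
    paste0(names(x$pools), " = ", fmt(x$pools)),
    "[initial]",
    paste0(names(x$initial_state), " = ", fmt(x$initial_state)),
    "[params]",
    paste0(names(x$params), " = ", fmt(x$params)),
    "[flags]",
    paste0(names(x$flags)[1:4], " = ",
           vapply(x$flags[1:4], isTRUE, logical(1))),
    paste0("clamp_cp2 = ",
           if (is.null(x$flags$clamp_cp2)) "none"
           else fmt(x$flags$clamp_cp2)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  section <- ""
  out <- list(run = list(), pools = list(), initial = list(),
              params = list(), flags = list())
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(kv[2])
    out[[section]][[key]] <- val
  }
  num <- function(sec) vapply(out[[sec]], as.numeric, numeric(1))
  flags <- perturbation_flags(
    shp2_receptor_catalysis = out$flags$shp2_receptor_catalysis == "TRUE",
    shp2_lck_catalysis = out$flags$shp2_lck_catalysis == "TRUE",
    pd1_self_dephosphorylation =
      out$flags$pd1_self_dephosphorylation == "TRUE",
    pd1_phosphorylation = out$flags$pd1_phosphorylation == "TRUE",
    clamp_cp2 = if (identical(out$flags$clamp_cp2, "none")) NULL
                else as.numeric(out$flags$clamp_cp2))
  init <- num("initial")
  sc <- scenario(pools = num("pools")[.pool_names],
                 params = num("params")[.rate_names],
                 flags = flags,
                 duration = as.numeric(out$run$duration),
                 initial = as.list(init),
                 label = out$run$label)
  sc$initial_state <- init[.species_names]
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
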