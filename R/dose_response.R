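# PD-1 dose scans, 2-D concentration scans and Hill-function IC50 fits.

#' Default PD-1 dose grid
#'
#' Zero plus `n` log-spaced doses between `lo` and `hi` nM.  The default
#' upper end of 1e4 nM (about 2.9e4 molecules/um^2) brackets the largest
#' fitted IC50 of the model's readouts.
#'
#' @param n Number of non-zero doses.
#' @param lo,hi Range of the log-spaced doses (nM).
#' @return Numeric vector of doses in nM, starting at 0.
#' @export
default_doses <- function(n = 30, lo = 1, hi = 1e4) {
  c(0, 10^seq(log10(lo), log10(hi), length.out = n))
}

#' PD-1 dose-response scan
#'
#' For each PD-1 dose, integrates the scenario for 30 minutes and
#' records the eight phospho-readouts (total phospho-CD3zeta,
#' phospho-CD28, Lck pY505 and pY394, Zap70 pY315 and pY493,
#' phospho-LAT, phospho-Slp76).  Each readout is normalized to its value
#' at zero PD-1; inhibition is `100 - normalized`.
#'
#' @param base A `"pd1_scenario"`; its `pd1T` is replaced by each dose.
#' @param doses PD-1 doses in nM; must include 0 (the normalization
#'   reference).
#' @param t_end Endpoint in seconds (default 1800).
#' @return A tibble with class `"pd1_dose_response"`: columns `readout`,
#'   `molecule`, `dose_nm`, `dose_density` (molecules/um^2), `raw` (nM),
#'   `normalized` (%), `inhibition` (%).
#' @examples
#' \donttest{
#' dr <- scan_pd1(builtin_scenario("fig3_base"), default_doses(10))
#' }
#' @export
scan_pd1 <- function(base, doses = default_doses(), t_end = 1800) {
  if (!any(doses == 0))
    abort("doses must include 0 to define the normalization reference")
  if (base$pools[["shp2T"]] <= 0)
    abort("dose-response base scenario must contain Shp2")
  doses <- sort(unique(doses))
  runs <- purrr::map(doses, function(d) {
    pools <- base$pools
    pools["pd1T"] <- d
    sc <- scenario(pools = pools,
      params = base$params, flags = base$flags,
      duration = max(base$duration, t_end),
      lck_split = base$lck_split,
      label = paste0(base$label, "_pd1_", signif(d, 4)))
    ep <- endpoint(sc, t_end)
    tibble(dose_nm = d, readout = .dose_readouts,
           raw = unlist(ep[.dose_readouts], use.names = FALSE))
  })
  df <- purrr::list_rbind(runs)
  ref <- df |>
    dplyr::filter(.data$dose_nm == 0) |>
    dplyr::select("readout", ref = "raw")
  res <- df |>
    dplyr::left_join(ref, by = "readout") |>
    dplyr::mutate(
      molecule = unname(.dose_molecules[.data$readout]),
      dose_density = nm_to_density(.data$dose_nm),
      normalized = 100 * .data$raw / .data$ref,
      inhibition = 100 - .data$normalized) |>
    dplyr::select("readout", "molecule", "dose_nm", "dose_density",
                  "raw", "normalized", "inhibition") |>
    dplyr::arrange(factor(.data$readout, levels = .dose_readouts),
                   .data$dose_nm)
  class(res) <- c("pd1_dose_response", class(res))
  res
}

#' Fit a Hill function to an inhibition curve
#'
#' Nonlinear least squares of `k * x^n / (ic50^n + x^n)` against the
#' inhibition fraction, with multi-start over log-spaced IC50 initial
#' guesses to avoid boundary traps on shallow curves.  Bounds:
#' `k` in (0, 1.2], `n` in (0, 10], `ic50` in [1, 1e5] molecules/um^2.
#'
#' @param dose_density Doses in molecules/um^2 (zero doses are dropped).
#' @param inhibition Inhibition as a fraction of the zero-dose signal
#'   (values in `[0, 1]`-ish; percentages are rescaled automatically).
#' @return An object of class `"hill_fit"` with elements `k_max`,
#'   `n_hill`, `ic50`, `rss`, `converged`, plus [tidy()] and [glance()]
#'   methods.  An all-zero inhibition curve returns a non-identifiable
#'   fit (`converged = FALSE`) rather than an error.
#' @examples
#' x <- 10^seq(0.5, 4, length.out = 12)
#' f <- fit_hill(x, 1 * x^1.25 / (126.3^1.25 + x^1.25))
#' glance(f)
#' @export
fit_hill <- function(dose_density, inhibition) {
  keep <- dose_density > 0
  x <- dose_density[keep]
  y <- inhibition[keep]
  if (length(x) < 4 || (log10(max(x)) - log10(min(x))) < 1)
    abort("need at least 4 dose points spanning at least one decade")
  if (max(y) > 1.5) y <- y / 100  # given as percent
  if (any(y < -1e-6)) abort("inhibition must be non-negative")
  if (all(abs(y) < 1e-12)) {
    out <- list(k_max = NA_real_, n_hill = NA_real_, ic50 = NA_real_,
                rss = 0, converged = FALSE,
                data = tibble(dose_density = x, inhibition = y))
    class(out) <- "hill_fit"
    return(out)
  }
  best <- NULL
  for (ic0 in 10^seq(1, 4, length.out = 5)) {
    fit <- try(minpack.lm::nlsLM(
      y ~ k * x^n / (ic50^n + x^n),
      start = list(k = min(max(y), 1.1), n = 1.2, ic50 = ic0),
      lower = c(k = 1e-6, n = 1e-3, ic50 = 1),
      upper = c(k = 1.2, n = 10, ic50 = 1e5),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
      silent = TRUE)
    if (!inherits(fit, "try-error")) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) abort("Hill fit failed from every start")
  co <- coef(best$fit)
  out <- list(k_max = unname(co["k"]), n_hill = unname(co["n"]),
              ic50 = unname(co["ic50"]), rss = best$rss, converged = TRUE,
              data = tibble(dose_density = x, inhibition = y))
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit>")
  if (!x$converged) {
    cat(" non-identifiable (flat inhibition curve)\n")
    return(invisible(x))
  }
  cat(sprintf(" k_max = %.3f, n = %.3f, IC50 = %.1f molecules/um^2\n",
              x$k_max, x$n_hill, x$ic50))
  invisible(x)
}

#' @rdname fit_hill
#' @param x A `"hill_fit"`.
#' @param ... Unused.
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("k_max", "n_hill", "ic50"),
         estimate = c(x$k_max, x$n_hill, x$ic50))
}

#' @rdname fit_hill
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(k_max = x$k_max, n_hill = x$n_hill, ic50 = x$ic50,
         rss = x$rss, converged = x$converged)
}

#' Hill-fit summary of all eight PD-1 dose-response readouts
#'
#' Runs a full PD-1 dose scan on the reconstitution base concentrations,
#' converts doses to surface density (2.9 molecules/um^2 per nM) and
#' fits the Hill function to each readout's inhibition curve, returning
#' the per-molecule Hill coefficient and IC50.
#'
#' @param base Base scenario (default the dose-response base set).
#' @param doses PD-1 dose grid in nM (must include 0).
#' @param params Optional rate-parameter override for the base scenario.
#' @return A tibble with columns `molecule`, `readout`,
#'   `hill_coefficient`, `ic50_molecules_per_um2`, `k_max`, `converged`,
#'   one row per readout in conventional order (CD3zeta, CD28,
#'   Lck Y505, Lck Y394, Zap70 Y315, Zap70 Y493, LAT, SLP76).
#' @examples
#' \donttest{
#' ic50_table()
#' }
#' @export
ic50_table <- function(base = builtin_scenario("fig3_base"),
                       doses = default_doses(), params = NULL) {
  if (!is.null(params)) base$params <- params
  dr <- scan_pd1(base, doses)
  dr |>
    dplyr::group_by(.data$readout, .data$molecule) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_hill(d$dose_density, d$inhibition / 100)
      tibble(hill_coefficient = f$n_hill,
             ic50_molecules_per_um2 = f$ic50,
             k_max = f$k_max, converged = f$converged)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(factor(.data$readout, levels = .dose_readouts)) |>
    dplyr::select("molecule", "readout", "hill_coefficient",
                  "ic50_molecules_per_um2", "k_max", "converged")
}

#' Two-dimensional concentration scan
#'
#' Evaluates a 30-minute endpoint readout over the Cartesian product of
#' two pool-concentration axes.
#'
#' @param base A `"pd1_scenario"`.
#' @param axis1,axis2 Pool names (see [pd1_pools()]).
#' @param values1,values2 Concentration grids (nM).
#' @param readout One of the derived readout names, e.g.
#'   `"pct_bound_shp2"`.
#' @param t_end Endpoint (seconds).
#' @return Long-format tibble with columns `axis1`, `axis2` (nM, named
#'   after the pools) and `value`.
#' @examples
#' \donttest{
#' scan_2d(builtin_scenario("fig4"), "lckT", c(10, 100),
#'         "pd1T", c(0, 300), "pct_bound_shp2")
#' }
#' @export
scan_2d <- function(base, axis1, values1, axis2, values2, readout,
                    t_end = 1800) {
  if (!axis1 %in% .pool_names || !axis2 %in% .pool_names)
    abort("axis names must be pool names")
  if (!readout %in% .readout_names)
    abort(paste0("unknown readout '", readout, "'"))
  grid <- tidyr::expand_grid(v1 = values1, v2 = values2)
  grid$value <- purrr::pmap_dbl(grid, function(v1, v2) {
    pools <- base$pools
    pools[axis1] <- v1
    pools[axis2] <- v2
    sc <- scenario(pools = pools, params = base$params,
                   flags = base$flags,
                   duration = max(base$duration, t_end),
                   lck_split = base$lck_split, label = base$label)
    endpoint(sc, t_end)[[readout]]
  })
  names(grid)[1:2] <- c(axis1, axis2)
  grid
}
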