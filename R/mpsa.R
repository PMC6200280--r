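# Multi-parametric sensitivity analysis: Latin-hypercube sampling of
# +/-50% parameter ranges, SSE-based acceptable/unacceptable
# classification against default-parameter reference time courses, and
# per-parameter two-sample Kolmogorov-Smirnov statistics.

# parameter groups varied by each analysis module; the rest stay at their
# defaults
.mpsa_param_sets <- local({
  shp2 <- c("k_p_pd1", "KM_p_pd1", "k_a_shp", "k_d1_shp", "k_d2_shp",
            "k_dp_cp2",
            "k_dpa_yiya", "k_dpi_yi", "k_dpi_yiya", "k_dpa_ya", "k_dpa_pi",
            "k_pi_i", "k_pi_ya", "k_pa_i", "k_pa_yi")
  cd28 <- c("k_p_cd28", "KM_p_cd28", "k_dp_cd28", "KM_dp_cd28",
            "k_a_pi3k", "k_d_pi3k")
  list(shp2_recruitment = shp2,                        # 15 parameters
       pi3k_recruitment = c(shp2, cd28),               # 21 parameters
       slp76_activation = setdiff(.rate_names, c(cd28, "k_corr")))  # 29
})

.mpsa_readouts <- c(shp2_recruitment = "pct_bound_shp2",
                    pi3k_recruitment = "pct_bound_pi3k",
                    slp76_activation = "pct_slp76a")

#' Specification of one MPSA module
#'
#' The sensitivity analysis is modular: each module varies the parameter
#' group feeding one readout and holds the rest at their defaults.
#'
#' * `shp2_recruitment` (15 parameters): PD-1 phosphorylation, Shp2
#'   binding/dissociation, and Lck auto-/de-phosphorylation; readout is
#'   % of Shp2 bound to PD-1.
#' * `pi3k_recruitment` (21): the above plus the CD28-PI3K group;
#'   readout is % of PI3K bound to CD28.
#' * `slp76_activation` (29): all rate parameters except the CD28-PI3K
#'   group and the correction constant; readout is % of Slp76 in the
#'   phosphorylated form.
#'
#' @param module Module name.
#' @param n_sets Number of Latin-hypercube parameter sets (default 2000;
#'   20000 matches the original full-scale analysis).
#' @param seed Integer seed controlling the sampling.
#' @param base Base scenario providing pools (default the dose-response
#'   base concentrations, near-physiological).
#' @param pd1_doses PD-1 doses in nM: default 0 plus 10 log-spaced in
#'   `[1, 1000]` (11 values).
#' @param time_points The 10 instants (s) where each time course is
#'   compared; default every 180 s over `(0, 1800]` (time zero is
#'   excluded because all readouts are identically at their initial
#'   value there).
#' @return A list with class `"mpsa_spec"`.
#' @export
mpsa_spec <- function(module = c("shp2_recruitment", "pi3k_recruitment",
                                 "slp76_activation"),
                      n_sets = 2000, seed = 1,
                      base = builtin_scenario("fig3_base"),
                      pd1_doses = c(0, 10^seq(0, 3, length.out = 10)),
                      time_points = seq(180, 1800, by = 180)) {
  module <- match.arg(module)
  if (n_sets < 2) abort("n_sets must be at least 2")
  if (length(pd1_doses) != 11)
    abort("pd1_doses must contain 11 values (0 plus 10 log-spaced)")
  if (length(time_points) != 10 || any(time_points <= 0))
    abort("time_points must be 10 positive instants")
  structure(list(module = module,
                 varied_parameters = .mpsa_param_sets[[module]],
                 readout = unname(.mpsa_readouts[module]),
                 base = base, pd1_doses = pd1_doses,
                 time_points = sort(time_points),
                 n_sets = n_sets, seed = seed),
            class = "mpsa_spec")
}

#' Latin-hypercube parameter sample
#'
#' Draws `n` parameter sets by Latin-hypercube sampling: each
#' parameter's range is split into `n` equal-width strata, one draw per
#' stratum, and the per-parameter samples are combined through
#' independent random permutations.  Deterministic for a given seed.
#'
#' @param n Number of sets (>= 2).
#' @param ranges Named list of `c(lower, upper)` ranges, all positive;
#'   see [mpsa_ranges()] for the standard +/-50% ranges.
#' @param seed Integer seed.
#' @return An `n` x `length(ranges)` tibble, one column per parameter.
#' @examples
#' lhs_sample(5, list(a = c(1, 2), b = c(10, 30)), seed = 1)
#' @export
lhs_sample <- function(n, ranges, seed) {
  if (n < 2) abort("n must be at least 2")
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  if (any(lo <= 0) || any(hi <= lo))
    abort("ranges must be positive with upper > lower")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- lhs::randomLHS(n, length(ranges))
  out <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(out) <- names(ranges)
  as_tibble(out)
}

#' Standard +/-50% MPSA ranges
#'
#' @param parameters Parameter names to vary.
#' @param params Reference parameter set.
#' @return Named list of `c(0.5 p, 1.5 p)` ranges.
#' @export
mpsa_ranges <- function(parameters, params = pd1_params()) {
  bad <- setdiff(parameters, names(params))
  if (length(bad))
    abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
  setNames(lapply(parameters,
                  function(nm) c(0.5 * params[[nm]], 1.5 * params[[nm]])),
           parameters)
}

# readout curves for one parameter set: matrix [time point x dose]
.mpsa_curves <- function(params, spec) {
  times <- c(0, spec$time_points)
  pools <- spec$base$pools
  vapply(spec$pd1_doses, function(d) {
    pools["pd1T"] <- d
    sc <- scenario(pools = pools, params = params, flags = spec$base$flags,
                   duration = max(spec$time_points),
                   lck_split = spec$base$lck_split, label = "mpsa")
    out <- .integrate_raw(sc, times)
    switch(spec$readout,
           pct_bound_shp2 = 100 * (out[-1, "cp1"] + out[-1, "cp2"]) /
             pools[["shp2T"]],
           pct_bound_pi3k = 100 * out[-1, "pi3kb"] / pools[["pi3kT"]],
           pct_slp76a = 100 * out[-1, "slp76a"] / pools[["slp76T"]])
  }, numeric(length(spec$time_points)))
}

#' Deviation of a parameter set from the reference time courses
#'
#' Sum over the 11 PD-1 doses of the sum over the 10 time points of the
#' squared deviation of the module readout from the default-parameter
#' reference.
#'
#' @param params Full named parameter vector (36 values).
#' @param spec An `"mpsa_spec"`.
#' @param reference Reference curves from the default parameters
#'   (computed internally when omitted).
#' @return Non-negative scalar.
#' @export
overall_error <- function(params, spec,
                          reference = .mpsa_curves(spec$base$params, spec)) {
  sum((.mpsa_curves(params, spec) - reference)^2)
}

#' Classify parameter sets as acceptable or unacceptable
#'
#' The threshold is the arithmetic mean of the overall errors; sets with
#' error strictly below the threshold are acceptable (ties go to
#' unacceptable).
#'
#' @param errors Numeric vector of overall errors (length >= 2).
#' @return List with `acceptable` (logical mask) and `threshold`.
#' @examples
#' classify_errors(c(1, 3))
#' @export
classify_errors <- function(errors) {
  if (length(errors) < 2) abort("need at least 2 errors")
  if (diff(range(errors)) == 0)
    abort("degenerate classification: all errors identical")
  threshold <- mean(errors)
  list(acceptable = errors < threshold, threshold = threshold)
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Maximum vertical distance between the empirical cumulative
#' distribution functions of two samples, evaluated over their pooled
#' support; the MPSA's per-parameter sensitivity score.
#'
#' @param x,y Non-empty numeric samples (here: a parameter's marginal
#'   values in the acceptable and unacceptable classes).
#' @return `D` in `[0, 1]`.
#' @examples
#' ks_statistic(c(1, 2), c(2, 3))  # 0.5
#' @export
ks_statistic <- function(x, y) {
  if (!length(x) || !length(y))
    abort("both samples must be non-empty")
  pooled <- sort(unique(c(x, y)))
  fx <- vapply(pooled, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pooled, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

#' Run one MPSA module
#'
#' Full pipeline: Latin-hypercube sampling of the module's parameters
#' within +/-50% of their defaults, overall squared error of each set's
#' readout time courses against the default-parameter reference over the
#' 11 PD-1 doses and 10 time points, mean-error classification, and a
#' per-parameter K-S statistic between the acceptable and unacceptable
#' marginal parameter distributions.
#'
#' @param spec An `"mpsa_spec"`.
#' @param progress Print a progress line every 500 sets?
#' @return An object of class `"mpsa_result"`: tibble of per-parameter
#'   K-S statistics (via [tidy()]), plus `acceptance_fraction`,
#'   `error_threshold`, `n_sets_used`, `n_failed` and `seed` (via
#'   [glance()]).
#' @examples
#' \donttest{
#' res <- run_mpsa(mpsa_spec("pi3k_recruitment", n_sets = 100, seed = 1))
#' tidy(res)
#' }
#' @export
run_mpsa <- function(spec, progress = FALSE) {
  if (!inherits(spec, "mpsa_spec")) abort("spec must be an mpsa_spec")
  ranges <- mpsa_ranges(spec$varied_parameters, spec$base$params)
  sets <- lhs_sample(spec$n_sets, ranges, spec$seed)
  reference <- .mpsa_curves(spec$base$params, spec)
  errors <- rep(NA_real_, spec$n_sets)
  for (i in seq_len(spec$n_sets)) {
    p <- spec$base$params
    p[spec$varied_parameters] <- as.numeric(sets[i, ])
    errors[i] <- tryCatch(
      overall_error(p, spec, reference),
      error = function(e) NA_real_)
    if (progress && i %% 500 == 0)
      message("  mpsa ", spec$module, ": ", i, "/", spec$n_sets)
  }
  failed <- is.na(errors)
  if (mean(failed) > 0.01)
    warn(paste0("more than 1% of parameter sets failed to integrate (",
                sum(failed), "/", spec$n_sets, ")"))
  ok <- !failed
  cls <- classify_errors(errors[ok])
  acc <- cls$acceptable
  ks <- vapply(spec$varied_parameters, function(nm) {
    v <- sets[[nm]][ok]
    ks_statistic(v[acc], v[!acc])
  }, numeric(1))
  structure(list(
    module = spec$module,
    ks = tibble(parameter = spec$varied_parameters, ks = unname(ks)) |>
      dplyr::arrange(dplyr::desc(.data$ks)),
    acceptance_fraction = mean(acc),
    error_threshold = cls$threshold,
    n_sets_used = sum(ok),
    n_failed = sum(failed),
    seed = spec$seed,
    base_pools = spec$base$pools,
    errors = errors),
    class = "mpsa_result")
}

#' @export
print.mpsa_result <- function(x, ...) {
  cat("<mpsa_result>", x$module, "\n")
  cat(sprintf("  %d sets (seed %d), %.1f%% acceptable, threshold %.4g\n",
              x$n_sets_used, x$seed, 100 * x$acceptance_fraction,
              x$error_threshold))
  print(head(x$ks, 5))
  invisible(x)
}

#' @rdname run_mpsa
#' @param x An `"mpsa_result"`.
#' @param ... Unused.
#' @method tidy mpsa_result
#' @export
tidy.mpsa_result <- function(x, ...) {
  dplyr::mutate(x$ks, module = x$module, n_sets = x$n_sets_used,
                seed = x$seed)
}

#' @rdname run_mpsa
#' @method glance mpsa_result
#' @export
glance.mpsa_result <- function(x, ...) {
  tibble(module = x$module, acceptance_fraction = x$acceptance_fraction,
         error_threshold = x$error_threshold, n_sets_used = x$n_sets_used,
         n_failed = x$n_failed, seed = x$seed)
}
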