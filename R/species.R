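# Species state, conservation checks and derived readouts.


#' Species state vector
#'
#' Builds a full 20-species state vector (nM) from named values; species
#' not mentioned are zero.  Species are the phosphorylated free receptor
#' tails (`cd3a`, `cd28a`), the PD-1 phospho-forms (`pd1`, `pd1p1`,
#' `pd1p2`), free Shp2 and its PD-1-bound complexes (`shp2`, `cp1`,
#' `cp2`), the four phosphorylated Lck forms (`lck_yiya`, `lck_yi`,
#' `lck_ya`, `lck_pi`), receptor-bound Zap70 in three phosphorylation
#' states (`zap70i`, `zap70a1`, `zap70a2`), phosphorylated LAT and its
#' adaptor complexes (`lata`, `gadsa`, `slp76i`, `slp76a`) and
#' CD28-bound PI3K (`pi3kb`).
#'
#' @param ... Named species concentrations in nM.
#' @return Named numeric vector of length 20.
#' @examples
#' species_state(pd1 = 300, shp2 = 300)
#' @export
species_state <- function(...) {
  s <- setNames(numeric(length(.species_names)), .species_names)
  vals <- list(...)
  if (length(vals)) {
    bad <- setdiff(names(vals), .species_names)
    if (length(bad))
      abort(paste0("unknown species: ", paste(bad, collapse = ", ")))
    s[names(vals)] <- unlist(vals)
  }
  if (any(s < 0)) abort("species concentrations must be non-negative")
  s
}

#' Derived readouts of a model state
#'
#' Aggregates a species state into the quantities reported by the model:
#' active Lck (`lck_yiya + lck_ya`), catalytically active PD-1-Shp2
#' complex (`cp1 + cp2`), total phosphorylated CD3zeta
#' (`cd3a + zap70i + zap70a1 + zap70a2`), total phosphorylated CD28
#' (`cd28a + pi3kb`), site-specific Zap70 and Lck phospho-sums,
#' phosphorylated LAT and Slp76, and percentage recruitments
#' (bound Shp2, PI3K, Zap70 and active Lck relative to their pools).
#'
#' Percentages are reported as `NA` when the corresponding pool is zero
#' and `strict = FALSE` (the default inside trajectory post-processing);
#' with `strict = TRUE` a zero pool raises an error.
#'
#' @param state Named species vector (see [species_state()]) or a
#'   data frame of such columns.
#' @param pools Named totals from [pd1_pools()].
#' @param strict Error on undefined percentages?
#' @return A tibble with one row per input state.
#' @examples
#' readouts(species_state(lck_ya = 25, lck_yiya = 25, lck_yi = 25),
#'          pd1_pools(lckT = 100))$pct_active_lck
#' @export
readouts <- function(state, pools, strict = FALSE) {
  df <- if (is.data.frame(state)) as_tibble(state)
        else as_tibble(as.list(state))
  miss <- setdiff(.species_names, names(df))
  if (length(miss))
    abort(paste0("state is missing species: ", paste(miss, collapse = ", ")))
  pct <- function(num, tot, what) {
    if (tot > 0) return(100 * num / tot)
    if (strict) abort(paste0("percentage of ", what,
                             " undefined: total pool is zero"))
    rep(NA_real_, length(num))
  }
  with(df, tibble(
    lck_active = lck_yiya + lck_ya,
    cp_active = cp1 + cp2,
    phospho_cd3 = cd3a + zap70i + zap70a1 + zap70a2,
    phospho_cd28 = cd28a + pi3kb,
    zap70_pY315 = zap70a1 + zap70a2,
    zap70_pY493 = zap70a2,
    lck_pY505 = lck_yi + lck_yiya + lck_pi,
    lck_pY394 = lck_ya + lck_yiya + lck_pi,
    phospho_lat = lata + gadsa + slp76i + slp76a,
    phospho_slp76 = slp76a,
    pct_bound_shp2 = pct(cp1 + cp2, pools[["shp2T"]], "bound Shp2"),
    pct_bound_pi3k = pct(pi3kb, pools[["pi3kT"]], "bound PI3K"),
    pct_bound_zap70 = pct(zap70i + zap70a1 + zap70a2, pools[["zap70T"]],
                          "bound Zap70"),
    pct_active_lck = pct(lck_yiya + lck_ya, pools[["lckT"]], "active Lck")))
}

# conservation sums used by invariant checks: the two fully conserved
# families (integrated species only) and the pool upper bounds
.conservation_totals <- function(df, pools) {
  tibble(
    pd1_family = df$pd1 + df$pd1p1 + df$pd1p2 + df$cp1 + df$cp2,
    shp2_family = df$shp2 + df$cp1 + df$cp2)
}
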