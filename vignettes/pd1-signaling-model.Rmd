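---
title: "Modeling PD-1/Shp2 inhibition of proximal TCR and CD28 signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling PD-1/Shp2 inhibition of proximal TCR and CD28 signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pd1sig)
```

## The model

PD-1 is an inhibitory receptor on T cells.  When its cytoplasmic tail is
phosphorylated by the Src-family kinase Lck, it recruits the cytosolic
phosphatase Shp2, and the resulting PD-1–Shp2 complexes dephosphorylate
the cytoplasmic tails of the TCR CD3ζ chain and of the costimulatory
receptor CD28 — the two entry points of proximal T-cell activation.
`pd1sig` implements a deterministic mass-action/Michaelis–Menten model of
this circuit as 20 coupled ODEs over the following species (all
concentrations in nM, time in seconds):

* **Receptors.** Free phosphorylated CD3ζ (`cd3a`) and CD28 (`cd28a`);
  their unphosphorylated forms are obtained algebraically from the
  conserved totals.  Phosphorylated CD3ζ binds Zap70 (`zap70i`), which
  active Lck then phosphorylates sequentially at Y315 (`zap70a1`) and
  Y493 (`zap70a2`, the catalytically active kinase).  Phosphorylated
  CD28 binds PI3K (`pi3kb`).
* **The adaptor module.** Active Zap70 phosphorylates LAT (`lata`),
  which binds Gads (`gadsa`); Gads recruits Slp76 (`slp76i`), which
  active Zap70 phosphorylates to `slp76a`, the endpoint of the modeled
  TCR branch.
* **Lck.** Five phospho-forms: unphosphorylated (free pool), Y394-only
  (`lck_ya`, active), Y505-only (`lck_yi`, inactive), Y394-then-Y505
  (`lck_yiya`, still active), and Y505-then-Y394 (`lck_pi`, locked
  inactive).  Only `lck_ya + lck_yiya` ("active Lck") carries kinase
  activity.  Interconversion is by auto-phosphorylation (first order)
  and by dephosphorylation catalysed by the PD-1-bound Shp2 complexes.
* **PD-1/Shp2.** Ligated PD-1 is phosphorylated distributively by
  active Lck (`pd1` → `pd1p1` → `pd1p2`, Michaelis–Menten).  Free Shp2
  binds either phospho-form, giving the complexes `cp1` and `cp2`;
  **only these complexes have phosphatase activity** — free Shp2 is
  catalytically inert.  The complexes also self-dephosphorylate their
  own PD-1 scaffold, which releases Shp2: a built-in negative feedback.

Receptor and PD-1 (de)phosphorylation follow Michaelis–Menten kinetics;
binding, dissociation and the Lck/Zap70/adaptor steps are mass action.
The two complexes `cp1`/`cp2` share identical binding, dissociation and
catalytic constants — there is no binding data to distinguish them, and
merging them halves the number of free constants.

### The saturating correction on PD-1 phosphorylation

Reconstitution experiments show that Shp2 recruitment saturates with
increasing PD-1 dose in a way simple mass action does not reproduce.
The model therefore multiplies the *first* phosphorylation step
(`pd1 → pd1p1`) by

$$f = \max\!\Big(0,\; 1 - \frac{[\mathrm{PD1_{p1}}] + [\mathrm{PD1_{p2}}]}
{k \cdot [\mathrm{Lck}]_T}\Big), \qquad k = 41,$$

so the pool of phosphorylated PD-1 an Lck molecule can maintain is
capped in proportion to total Lck.  Two implementation choices are
deliberate: the factor applies **only** to the first step, not to
`pd1p1 → pd1p2`; and it is clamped at zero from below, because when the
phosphorylated pool transiently exceeds the cap a negative factor would
turn a phosphorylation flux into an unphysical sink.

### Conservation by construction

Eight of the free pools (unphosphorylated CD3ζ, CD28, Zap70, PI3K,
Lck, LAT, Gads, Slp76) are never integrated; they are recomputed from
their conservation totals at every right-hand-side evaluation, so those
totals are conserved exactly.  The PD-1 family
(`pd1 + pd1p1 + pd1p2 + cp1 + cp2`) and the Shp2 family
(`shp2 + cp1 + cp2`) are integrated, and their conservation is a real
test of the transcription: the package checks both to 1e-6 nM on every
stored trajectory point.

## Numerical choices

The system is stiff (rate constants span eleven orders of magnitude,
e.g. `k_dp_cp2` = 5e-8 s⁻¹ against `k_d1_shp` = 10 s⁻¹), so
trajectories are integrated with `deSolve::lsoda` with the right-hand
side compiled in C.  Defaults: relative tolerance 1e-8, absolute
tolerance 1e-12 nM, 200 output points over 0–1800 s.  The absolute
tolerance is set well below the 1e-9 nM negativity allowance so that
integrator under-shoot near zero stays orders of magnitude inside it;
inside the right-hand side, values in (−1e-9, 0) are clipped to zero
and larger negatives raise an error.  Halving the tolerances moves
30-minute readouts by far less than 0.1% (tested).

`k_dp_cp2` = 5e-8 s⁻¹ makes the direct CP2 → CP1 self-dephosphorylation
route essentially inert on the 30-minute horizon; it is implemented
exactly as specified rather than "corrected", since CP2's Shp2-releasing
route (`k_d2_shp` = 1 s⁻¹) carries the feedback.

All endpoints are reported at t = 1800 s (30 min), the reporting
convention of the reconstitution experiments this model was built
against; no steady-state solving is attempted because the slow Lck
dephosphorylation timescales mean 30-minute values are not asymptotic.

## Scenarios

A `scenario()` bundles pools, initial state, parameters, perturbation
flags and duration.  At t = 0 everything is unphosphorylated and
unbound except Lck, which starts 25% in each of the `i`, `ya`, `yi`
and `yiya` forms (the phosphoform proportions measured in Jurkat
T cells) and 0% in `pi`.  This split is why, without PD-1, percent
active Lck holds at 50%: the auto-phosphorylation fluxes between the
forms are slow compared with the 30-minute horizon, and PD-1-bound
Shp2 is the only process that moves probability toward the inactive
forms.

`builtin_scenario()` encodes the reconstitution protocols: Shp2
binding-domain-only recruitment (catalysis disabled), full-length Shp2
recruitment, Zap70-vs-PI3K engagement races, receptor
dephosphorylation by a membrane-anchored phosphatase, the full-network
dose-response base, and the two knockout protocols (no Lck
dephosphorylation; no PD-1 self-dephosphorylation).  Where a protocol
does not state a concentration the dose-response base set is used
(100 nM Lck and CD3ζ, 200 nM PI3K, 300 nM everything else).  The
membrane-anchored phosphatase is represented by clamping `cp2` at a
constant value with its binding/dissociation/self-dephosphorylation
fluxes disabled — a constant catalytic pool.

`random_scenario()` draws pools uniformly within bounds under an
explicit seed; it exists to stress conservation and robustness in the
test suite.  What it emulates is variation in protein abundances only:
it does not vary rate constants (the MPSA does that), add measurement
noise, or model cell-to-cell heterogeneity, so passing those tests
says the integrator and conservation logic are sound across operating
points — not that the model fits any particular cell population.

## Dose-response analysis

`scan_pd1()` varies total PD-1, integrates 30 minutes per dose, and
normalizes each of eight phospho-readouts to its zero-PD-1 value.
`fit_hill()` fits

$$\mathrm{inhibition}(x) = \frac{k \, x^{\,n}}{IC_{50}^{\,n} + x^{\,n}}$$

to the *inhibition fraction* (1 − normalized signal) against PD-1
surface density.  Fitting inhibition rather than the raw normalized
signal is a deliberate reading: it makes $k$ the maximum response for
curves that saturate below 100% inhibition (most of the TCR-branch
readouts do), and $IC_{50}$ the dose of half-maximal
dephosphorylation.  Doses convert to surface density at 2.9
molecules/μm² per nM — the factor implied by 200-nm vesicles at 1 mM
lipid with 52.6% of lipid in the outer leaflet and 0.65 nm² per head
group (`density_conversion_factor()` recomputes it from that
geometry).

Fit mechanics: `minpack.lm::nlsLM` bounded at $k \in (0, 1.2]$,
$n \in (0, 10]$, $IC_{50} \in [1, 10^5]$ molecules/μm², multi-started
from five log-spaced $IC_{50}$ guesses to avoid boundary traps on the
shallow curves; an all-zero inhibition curve returns a
non-identifiable flag instead of an error.  The default grid is 0 plus
30 log-spaced doses over 1–10⁴ nM, wide enough to bracket the largest
fitted IC50 (~4700 molecules/μm² ≈ 1620 nM); doubling the grid moves
every IC50 by under 2% (tested).

```{r ic50, eval = FALSE}
ic50_table()
#>   molecule     ... hill_coefficient ic50_molecules_per_um2
#>   CD3zeta              1.40                3017.4
#>   CD28                 1.25                 126.3
#>   ...
```

The headline result: CD28 loses its phosphorylation at PD-1 doses more
than an order of magnitude below those needed to dephosphorylate CD3ζ,
and the TCR-branch targets (Zap70, LAT, SLP76) sit in between, pulled
down largely indirectly through Lck inactivation.

## Sensitivity analysis (MPSA)

`run_mpsa()` implements a multi-parametric global sensitivity analysis:

1. Latin-hypercube sample of `n_sets` parameter vectors, each varied
   parameter uniform within ±50% of its default (`lhs_sample()`, one
   draw per stratum, independent permutations per parameter).
2. For each set, the module readout is computed at 10 time points
   (every 180 s over (0, 1800]; t = 0 is excluded because every
   readout is identically at its initial value there) at 11 PD-1 doses
   (0 plus 10 log-spaced over 1–1000 nM); the overall error is the sum
   of squared deviations from the default-parameter reference.
3. Sets with error strictly below the mean error are "acceptable"
   (ties go to unacceptable — a deterministic tie-break).
4. Each parameter's sensitivity is the two-sample Kolmogorov–Smirnov
   distance between its marginal values in the two classes.

Three modules are analysed, each varying only the parameters feeding
its readout: Shp2 recruitment (15 parameters, % bound Shp2), PI3K
recruitment (21, % bound PI3K), Slp76 activation (29 — all rate
constants except the six CD28/PI3K constants and the correction
constant, % Slp76 phosphorylated).  The errors are computed on
percentage readouts, matching how the recruitment quantities are
reported.  The default `n_sets = 2000` keeps a full module run around
half a minute on one CPU and already ranks parameters stably;
`n_sets = 20000` reproduces the full-scale published analysis.  Base
concentrations are the dose-response set, recorded in every result
object.

At these settings the PI3K module is dominated by the PI3K–CD28
association constant (K-S ≈ 0.3), the Slp76 module by the rate of
Zap70 Y315 phosphorylation by Lck (K-S ≈ 0.35), and the Shp2 module by
the PD-1 phosphorylation and Shp2 association constants (K-S ≈ 0.13
each) — the package's acceptance tests assert exactly these.

## Design decisions and limitations

* **Compiled right-hand side.** The MPSA needs tens of thousands of
  stiff integrations; the C implementation brings one 30-minute
  integration to ~1.5 ms.  An independent R transcription of all 20
  equations lives in the test suite and must agree with the compiled
  code to 1e-12 relative error on random states.
* **Flags zero rate constants.** Perturbation switches act by zeroing
  the corresponding constants (`apply_flags()`), which makes "flux is
  exactly zero" a provable property rather than a numerical one.
* **Interface.** Results are tibbles; fitted objects carry
  `tidy()`/`glance()` methods and each result type has an `autoplot()`.
  The package's functions (plus `scripts/acceptance.R`) are the
  intended entry points; there is no separate shell tool.
* **Out of scope.** No stochastic simulation (the model is
  deterministic and population-averaged), no upstream ligand-binding
  kinetics for TCR or PD-1, no Csk/CD45 regulation of Lck, no spatial
  membrane geometry.  The model describes a reconstitution system;
  *in vivo* behaviour involves regulation it deliberately omits.
* **Lck at low doses.** Below ~100 nM Lck the active-Lck fraction
  responds non-monotonically to PD-1 because PD-1 activation itself
  requires Lck; conclusions about "net inhibition of Lck" hold above
  that range.
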