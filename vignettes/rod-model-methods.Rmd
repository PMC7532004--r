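---
title: "State occupancy analysis of GABA-A receptor currents: model, fits, and synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State occupancy analysis of GABA-A receptor currents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabarod)
```

## The three-state equilibrium model

GABA_A receptors visited by sustained agonist distribute across three
coarse-grained states: Resting (closed, low agonist affinity), Open
(conducting), and Desensitized (closed, high agonist affinity). `gabarod`
works with the equilibrium description of this scheme:

- `L = Resting/Open` measures constitutive activity (large L = rarely open
  without agonist);
- `Γ([X]) = ((1 + [X]/K_C) / (1 + [X]/K_O))^N` captures how agonist binding
  (dissociation constants `K_C` resting, `K_O` open, `N` sites) biases the
  resting/open equilibrium. Since the open state binds agonist more tightly
  (`K_O < K_C`), Γ falls from 1 toward `(K_O/K_C)^N` with increasing
  agonist, activating the receptor. Note the exponent applies to the
  *ratio* of the two binding polynomials: a product form would make agonist
  occupancy inhibitory, contradicting the ordering of the affinities, so
  the ratio is the only form consistent with agonist acting as an agonist.
- `Q = Open/Desensitized` sets the steady-state balance between conducting
  and desensitized receptors, independent of agonist concentration because
  the open and desensitized states are assigned equal agonist affinity.

The peak of a response (before desensitization equilibrates) and its late
plateau then have closed forms

\[
P_{peak} = \frac{1}{1 + L\Gamma},\qquad
P_{ss} = \frac{1}{1 + 1/Q + L\Gamma},\qquad
P_{des} = \frac{1}{1 + Q + Q L\Gamma}.
\]

### The inversion procedure

Measurements enter as open probabilities (currents normalized to a reference
response defined to have `P_open = 1`). The analysis never needs `L`,
`K_C`, `K_O` individually: the composite `LΓ` is read off the measured peak
(`LΓ = 1/P_peak − 1`), then held fixed while `Q` is solved from the measured
steady state (`Q = 1/(1/P_ss − 1 − LΓ)`). Both the composite path and the
full-parameter path (`gating_parameters` + `gamma_factor`) are exposed; the
composite path is what `run_occupancy()` uses. Constitutive activity in the
absence of agonist is treated as negligible throughout (an explicit design
choice; the closed forms accept any `LΓ ≥ 0` so a nonzero baseline can be
folded in by the caller if ever needed).

A steroid that promotes desensitization appears as a reduced `Q` (written
`Q*`). Because `Q` carries no agonist dependence, `Q*` estimated at
saturating agonist transfers to any other concentration
(`predict_low_agonist()`), where the occupancy of the high-affinity states
`P_open + P_des` predicts the fold change of low-concentration radioligand
binding (`binding_fold_change()`).

Worked through the reference measurements (peak 0.71; steady state 0.121
control, 0.077 with 3 µM epi-allopregnanolone), the inversion gives
`Q = 0.1459`, `Q* = 0.0864`, desensitized occupancies 0.8296 and 0.8915,
and high-affinity sums 0.9506 and 0.9685. Reports display two decimals;
full precision is always stored. At 20 nM muscimol the same procedure on
the rounded printed inputs (0.012/0.011/0.009) yields desensitized
occupancies of about 0.083 and 0.25 and a binding fold change of 2.75. The
three-decimal occupancies quoted alongside those inputs in the source
measurements (0.1001/0.2168) are only recoverable from unrounded per-cell
means; the pipeline reproduces the *procedure*, and reproduces those digits
exactly when fed steady states back-solved from them.

### Numerical choices

- **No-desensitization sentinel.** A steady state within relative tolerance
  `1e-6` of the peak returns `Q = Inf` rather than an error or a huge
  noisy number; a steady state exceeding the peak beyond tolerance raises
  an inconsistent-measurement error naming both values. The tolerance is an
  argument (`q_from_steady_state(..., tol =)`) because analytic round-trip
  work needs it tighter than measurement work.
- **Probability conservation** holds to 1e-12 by construction
  (`p_resting = LΓ·p_ss`, `p_des = 1 − (1+LΓ)p_ss`); the constructors check
  it.
- All probabilities are carried at full floating precision; rounding is
  display-only.

## Current-trace metrics

Traces are two-column records (`time_s`, `current_nA`); inward currents at
negative holding potential are flipped to positive magnitudes by a sign
flag. Choices the source measurements leave open, fixed here as package
defaults:

- **Steady-state window**: the final 10% of the application window
  (`steady_state_window()`), overridable.
- **Peak smoothing**: none by default (`smooth_width_s = 0`); oocyte
  two-electrode voltage-clamp records are low-noise, and smoothing a sharp
  transient biases the peak down.
- **Normalization**: `to_popen()` divides by the reference peak (1 mM GABA
  + 50 µM propofol, defined as `P_open = 1`) and tolerates up to 2% excess
  (clipped, with a warning) before treating the measurement as
  irreconcilable with the reference.

## Curve fits

Three nonlinear fits accompany the assays, all unweighted least squares by
default (optional `weights`), solved by Levenberg–Marquardt (`minpack.lm`)
with `ftol = ptol = 1e-10` and start values from a coarse log-spaced grid
search, which makes the fits invariant under unit rescaling of
concentration and robust to local minima:

- **Single-site isotherm** `B = B_max·x/(K_d + x)`; a fitted `K_d` outside
  `[min(x)/100, max(x)·100]` is reported as a failure rather than a number.
  Two-site models are deliberately out of scope: expressed α1β3 receptors
  show single-component muscimol binding.
- **Hill modulation curve**
  `E(c) = 100 + (E_max − 100)·c^n/(c^n + EC50^n)` with the baseline
  anchored at exactly 100% of control (the no-modulator control defines
  100; a free-baseline variant is available by flag). Inhibition
  (`E_max < 100`) is supported; when `|E_max − 100|` falls below twice the
  residual SD the fit is flagged `no_effect`, since EC50 and slope are then
  unidentifiable.
- **Mono-exponential time course**
  `B(t) = B0 + (B∞ − B0)(1 − e^{−t/τ})` for the slow onset of binding
  enhancement.

Specific binding is total minus nonspecific counts; negative values are
kept (flagged, not clipped) so replicate means stay unbiased.
`counts_to_amount()` applies the standard 2.22e12 dpm/Ci conversion.

## Photolabeling efficiency

Efficiency is `100·labeled/(labeled + unlabeled)` from extracted-chromatogram
areas, assumed directly comparable within a sample (no cross-injection
normalization); `percent_prevention()` quantifies competitor block.
Replicates aggregate as mean ± SEM; inferential statistics are left to the
user's preferred framework.

## The synthetic-data generator

The generator exists so every pipeline stage is testable end to end without
instrument data. It emulates:

- **Between-cell scatter** of open probabilities: truncated normal on
  (0, 1], defaults SD 0.25 on the peak (around 0.71) and 0.033 on the
  steady state — the reported spreads at 1 mM GABA — with paired
  control/steroid draws per cell (`simulate_responses()`).
- **Macroscopic current kinetics**: a linear R↔O↔D ODE (`deSolve::lsoda`,
  `rtol 1e-10`) whose rate ratios are pinned to the equilibrium constants,
  so its long-time occupancies equal the closed forms within 1e-6 — that
  agreement is itself a tested invariant. Absolute rates are free
  generator parameters (the analysis is equilibrium-only); defaults give
  fast activation and second-scale desensitization, visually similar to
  published traces but not fitted to them. An output `dt` too coarse to
  resolve the fastest rate errors out rather than aliasing the transient.
- **Filtration-assay counts**: expected specific binding from the
  occupancy-weighted state affinities times `B_max`, plus a linear
  nonspecific component, with multiplicative counting noise of configured
  CV (a normal approximation to Poisson counting statistics).
- **Neurosteroid action** via a three-site scheme: each ligand has per-site
  occupancy constants and per-site multiplicative efficacies on `L`
  (activation) and `Q` (desensitization). `apply_ligand()` scales each
  constant by `∏_sites (1 + (efficacy − 1)·occ)` with
  `occ = c/(c + K_site)` — occupancy-weighted so effects grow smoothly with
  concentration and saturate at the full efficacy product. This functional
  form is the package's own parameterization (no equations exist for the
  qualitative site scheme it encodes); the linear-in-occupancy mixing is
  the simplest choice consistent with independent sites, and whether
  per-site effects saturate this way is an open question the generator does
  not claim to settle.

Built-in profiles encode the qualitative site/efficacy table: the
potentiating steroid (binds all three sites, lowers L), the inhibitory
3β-epimer (intrasubunit sites only, lowers Q), a desensitizing diazirinyl
analogue (all three sites, lowers Q), and its neutral 17-epimer (binds
everywhere, changes nothing — an antagonist scaffold). One quantitative
calibration is built in: the 3β-epimer's per-site Q-efficacy (0.7503 at
K = 0.25 µM, the fitted modulation EC50, on both intrasubunit sites) is
chosen once so that 3 µM reproduces the measured `Q → Q*` shift (factor
0.592) at saturating GABA. Other efficacies are qualitative placeholders.

For the binding-modulation sweep the generator needs muscimol gating
parameters: `L` is agonist-independent and shared with GABA; muscimol's
resting affinity is taken equal to GABA's and its open-state affinity is
solved from the measured peak `P_open` of 0.012 at 20 nM
(`rod_study_parameters("muscimol")`, giving `K_O ≈ 0.48` nM, the
sub-nanomolar affinity expected of the high-affinity radioligand).

**What passing tests do and do not show.** The generator draws from the
model being fitted, with Gaussian scatter and independent cells. Recovery
tests therefore validate the *estimators and code paths*, not the model's
adequacy for real receptors: real recordings have rundown, series-resistance
error, correlated drift, solution-exchange limits on the peak, and possibly
multiple desensitized states — none of which the generator emulates.

## Simulation sizes and tolerances used in the test suite

Chosen as the package's own balance of statistical resolution against
runtime: Q/Q* recovery uses 200 seeds at the study's group sizes (7
control, 5 steroid cells) with steady-state SD 0.033, requiring the seed
means within 10% of the generating values; Hill recovery uses 100 seeds
(6 replicates × 9 concentrations, 5% CV) requiring EC50 within 20% in ≥95%
of seeds; time-constant recovery uses 50 seeds at 4 time points (1, 3, 10,
30 min — a subset of the assay grid that still brackets the plateau) with
noise SD 3.5% of control, requiring the mean τ within 10%. Noiseless
recovery must hit solver tolerance (1e-6 to 1e-4 relative) across parameter
grids.

## Known limitations

- Equilibrium only: no kinetic fitting of rate constants, no
  single-channel cluster analysis, no multi-desensitized-state models.
- `Q`'s transferability rests on exactly equal open/desensitized agonist
  affinities; a modest inequality would bend predictions at low agonist.
- The three-site efficacy parameterization is one consistent choice among
  several; only its 3 µM calibration point is empirically pinned.
- Percent-desensitization comparisons across cells inherit the
  between-cell scatter of the normalization reference; the paired design
  (`simulate_responses()` and its analysis) is the intended use.
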