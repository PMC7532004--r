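# gabarod

Analysis of GABA_A receptor macroscopic currents in the three-state
Resting–Open–Desensitized (ROD) equilibrium framework, and of neurosteroid
modulation of orthosteric radioligand binding.

## Who this is for

Ion-channel electrophysiologists and receptor pharmacologists who measure
whole-cell or oocyte GABA_A receptor currents and radioligand (e.g.
[³H]muscimol) binding, and want to translate peak and steady-state open
probabilities into state occupancies — in particular, to ask whether a
modulator that *inhibits* steady-state current while *enhancing* agonist
binding is acting by stabilizing the desensitized state.

## The model

At equilibrium the receptor distributes across Resting (R), Open (O) and
Desensitized (D) states. With agonist concentration [X], resting/open
equilibrium constant L, resting- and open-state agonist dissociation
constants K_C > K_O, N agonist sites, and open/desensitized equilibrium
constant Q = O/D:

    Γ        = [ (1 + [X]/K_C) / (1 + [X]/K_O) ]^N
    P_peak   = 1 / (1 + LΓ)
    P_ss     = 1 / (1 + 1/Q + LΓ)
    P_des    = 1 / (1 + Q + Q·LΓ)

Analysis runs the inversions: LΓ = 1/P_peak − 1 from the measured peak, then
Q = 1 / (1/P_ss − 1 − LΓ) from the measured steady state. Because agonist
affinity is taken equal in the open and desensitized states, Q (or the
steroid-modified Q*) transfers across agonist concentrations, and the
occupancy of the high-affinity states (P_open + P_des) predicts the fold
change of low-concentration radioligand binding.

Around this core the package provides current-trace metrics (normalization
to a P_open = 1 reference, percent desensitization, potentiation ratios),
the standard curve fits (single-site isotherm, baseline-anchored Hill
modulation curve, mono-exponential time course — Levenberg–Marquardt via
minpack.lm), photolabeling-efficiency quantification, and a seeded
synthetic-data generator implementing a three-site, state-dependent
neurosteroid scheme (see the methods vignette).

## Worked example

Saturating (1 mM) GABA gives peak P_open 0.71 and steady-state P_open 0.121,
reduced to 0.077 by 3 µM epi-allopregnanolone:

```r
library(gabarod)
run_occupancy(0.71, 0.121, 0.077)
#> ROD occupancy report
#>   inputs: peak 0.71, steady-state 0.121 (steroid 0.077)
#>   L*Gamma = 0.4085, Q = 0.1459
#>   control: P_rest 0.05, P_open 0.12, P_des 0.83 (sum high-affinity 0.95)
#>   steroid: Q* = 0.08637, P_des 0.89 (sum high-affinity 0.97)
#>   predicted binding fold change: 1.02
```

The steroid nearly halves Q (0.146 → 0.086): open receptors convert to
desensitized ones. At saturating agonist the high-affinity sum barely moves
(0.95 → 0.97) — the binding assay would see almost nothing. Transfer the
same Q* to 20 nM muscimol (peak P_open 0.012, steady state 0.011 → 0.009):

```r
run_occupancy(0.012, 0.011, 0.009)$binding_fold_change
#> [1] 2.745583
```

— a two-to-three-fold predicted increase in high-affinity-state occupancy,
matching the roughly two-fold enhancement of [³H]muscimol binding seen in
filtration assays at low radioligand.

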