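---
title: "Modelling class Ia anti-arrhythmic action in hERG-linked short QT syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling class Ia anti-arrhythmic action in hERG-linked short QT syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sqtsim)
```

## The problem

Short QT syndrome variant 1 (SQT1) is caused by the N588K mutation in hERG,
which attenuates inactivation of the rapid delayed rectifier current I~Kr~
without changing its activation voltage dependence. The resulting
gain-of-function abbreviates ventricular repolarization (QTc at or below
300 ms), shortens refractoriness, and creates a substrate for re-entry.
Quinidine and disopyramide — class Ia agents that block both I~Kr~ and the
fast sodium current I~Na~, with weaker actions on several other channels —
partially reverse the phenotype clinically. `sqtsim` is a multiscale
simulation framework for dissecting how these multi-channel actions combine:
state-dependent drug binding on a Markov I~Kr~ model, guarded-receptor block
of I~Na~, Hill pore block of secondary currents, and cell → transmural
strand → re-entrant sheet simulations with the associated biomarkers (APD90,
maximum upstroke velocity, QT, ERP, conduction velocity, re-entry wavelength,
transmural dispersion of repolarization, dominant frequency).

## Cell model

The myocyte is an O'Hara–Rudy-lineage human ventricular model (ENDO, MCELL
and EPI variants) with two substitutions:

* the fast sodium current uses the Luo–Rudy m³hj formulation (with the host
  model's Na reversal potential), which supports robust propagation in
  coarse-grained tissue;
* I~Kr~ is carried by a Markov chain (below) instead of the
  Hodgkin–Huxley gates.

All maximal conductances carry dimensionless multipliers (the *profile*,
`sqtsim_profile()`), which is how pore block, the mechanistic action masks
and the calibration layer enter the model. Integration is fixed-step
explicit Euler with Rush–Larsen updates for Hodgkin–Huxley gates; Markov
occupancies, block pools and concentrations advance by forward Euler.
Voltage-dependent coefficients are tabulated on a 0.02 mV grid and linearly
interpolated. The default step is `dt = 0.005` ms (step halving changes
APD90 by well under 1 ms; `dt = 0.02` ms remains accurate within ~0.3 ms and
is used for the large 2D runs). Cells are paced for 100 beats before any
biomarker is read; with a drug present the binding pools equilibrate during
this pre-pacing.

## Markov I~Kr~ and drug binding

The chain is C1 ↔ C2 ↔ C3 → {O, I} with O → C3 (β₂), I → C3 (μ), O ↔ I
(β~i~/α~i~), plus drug-bound states O\* and I\* reached by
concentration-scaled binding from O and I only (no closed-state binding).
Every voltage-dependent rate has the form `P exp(Q V)`; μ is tied by
microscopic reversibility (μ = α~i~ β₂ / β~i~) so the C3–O–I loop is
thermodynamically consistent. Only the open state conducts:
I~Kr~ = g~Kr~ · O · (V − E~K~).

N588K differs from wild type *only* in the inactivation-pathway rates: the
α~i~/β~i~ voltage dependence is shifted +45 mV depolarized, which raises the
steady-state open probability at depolarized potentials (the
gain-of-function) while leaving activation untouched. The heterozygous SQT1
condition is a 50/50 mixture of two independently-gated populations, each
with its own drug states; weight 1 on the mutant population gives the
homozygote.

The drug-bound extension adds four rate constants per drug and condition
(k~A~, l~A~, k~I~, l~I~). Because the source kinetic tables are not
reproduced here, these were fitted (`fit_herg_binding()`, bounded
Nelder–Mead on log-scaled rates, multi-start) against tail-current
dose–response anchors of Hill form (n~H~ = 1) centred on the reported IC50s:
disopyramide 10.77 µM (WT) / 15.77 µM (N588K), quinidine 0.62 µM /
2.16 µM. The clamp protocol is a 2 s step to +20 mV from −80 mV with a tail
at −40 mV, repeated at 0.25 Hz until periodic; block is read at the tail
peak. The equilibrium dose–response pins the affinities (l/k) tightly but
leaves the absolute binding/unbinding time scale under-identified; the
shipped values are the optimizer's solution of the dose–response fit alone.
This is the main caveat on the drug-bound tissue predictions: at a fixed
fitted affinity, moving the kinetics from the fitted values to the
instantaneous-equilibrium limit spans roughly a 15% range in the predicted
drug-treated QT.

## Guarded-receptor I~Na~ block

Fractional block pools b~A~, b~I~, b~R~ ride on the Luo–Rudy gates: access
to the activated site is guarded by m³hj, to the inactivated site by
(1 − hj), and to the resting site by (1 − m³)hj, all drawing on the shared
unblocked fraction. I~Na~ is scaled by (1 − b~A~ − b~I~ − b~R~). Resting
rates are solved so the frozen-gate equilibrium dose–response at a −100 mV
hold crosses 50% at the reported tonic IC50s (36 µM disopyramide, 17 µM
quinidine); inactivated-state rates are sized for pronounced use dependence
(block measured at the activation peak of each test pulse accumulates over
a 30-pulse 2 Hz train and exceeds the 1 Hz value at equal concentration).
Secondary channel actions (I~CaL~, I~to~, I~Ks~; for quinidine also I~K1~
and I~NaL~) are static Hill pore blocks with n~H~ = 1 by default
(coefficients are not reported; the choice is overridable per entry).
Currents without a reported action are simply absent from a drug's registry.

## Calibration of the drug-free model

The source kinetic and conductance tables behind the published model are in
supplementary material that is not reproduced here, so the package
*calibrates* the drug-free model against four printed anchors at 1 Hz:
wild-type strand QT ≈ 350 ms, SQT1 strand QT ≈ 241 ms (the ~31% shortening),
SQT1 endocardial APD90 ≈ 195.3 ms, and conduction velocity ≈ 60.3 cm/s. The
calibration knobs are: the global I~Kr~ conductance scale (1.51), the N588K
inactivation shift (+45 mV), the MCELL I~CaL~ heterogeneity multiplier
(0.33, which sets the M-cell-to-endocardial APD offset and hence the
terminal T-wave limb), and the tissue diffusion coefficient
(9.37 × 10⁻⁴ cm²/ms, CV is a pure function of D here). Everything
drug-related downstream of these anchors is a genuine prediction: no drug
simulation was used in this calibration.

Two properties of the published account could not be reproduced jointly
with these anchors in this lineage and are reported rather than asserted:
the maximal transmural dispersion of repolarization comes out *smaller* in
SQT1 than WT here (mutant I~Kr~ dominance compresses inter-type APD
differences), and absolute strand ERPs run ~55–60 ms below the published
table (refractoriness is gated by endocardial recovery). All *relative*
pharmacology — monotone dose effects on QT/ERP/CV, the wavelength ordering
between the drugs, ERP synergy of combined I~Kr~ + I~Na~ block, reverse
rate dependence — holds and is tested.

## Tissue models and biomarkers

The transmural strand is 25 ENDO, 35 MCELL and 40 EPI cells over 15 mm
(dx = 0.15 mm), isotropic monodomain except a five-fold diffusion reduction
at the single MCELL–EPI interface, I~Kr~ conductance ratio 1.0 : 1.0 : 1.6
(ENDO : MCELL : EPI), stimulated at the endocardial end. The pseudo-ECG is
the far-field unipolar potential of the fiber at an electrode 2 cm beyond
the epicardial end. Strand runs initialise every cell from its cell type's
single-cell paced steady state (drug included) and then pace the coupled
fiber for 4 beats; the final beat is analysed.

* **QT**: from the first post-stimulus deflection to the intersection with
  the baseline of the tangent at the steepest point of the *terminal*
  descending limb of the T wave (the portion below half T amplitude). With
  discrete-region transmural heterogeneity the T wave can be shouldered;
  anchoring the tangent on the terminal limb — as the clinical tangent
  method does — makes the measurement continuous under parameter changes,
  where a global-steepest-slope rule jumps between limbs.
* **CV**: activation-time difference (maximal dV/dt instant) between two
  interior cells ≥ 20 cells from the boundaries; planar-wave CV scales as
  √D as expected for a continuous cable.
* **ERP**: shortest S1–S2 coupling interval whose premature endocardial
  stimulus still propagates to the epicardial end, by bisection (1 ms
  default resolution) after an S1 conditioning train.
* **TDR**: range of per-cell repolarization instants (APD90-end, including
  activation delay). **WL** = CV × ERP.

The 3D wedge of the original study is out of scope (its diffusion-tensor
geometry is unavailable); re-entry is studied on a deliberately scaled 2D
sheet: 80–100 nodes square at 0.25 mm spacing with coupling reduced 20-fold
so that the re-entrant wavelength fits the domain. Re-entry is initiated by
the phase-distribution method: each node's full state vector is set to a
point on a reference paced cycle according to an Archimedean-spiral phase
map. The pseudo-ECG dominant frequency is the largest peak of a
Hann-tapered periodogram in 0.5–20 Hz, and the lifespan is the last
upstroke crossing at a 3 × 3 probe grid. On this scale only *dose trends*
are meaningful (drug application slows or extinguishes the spiral); the
multi-wavelet fibrillatory regime of the full wedge does not occur on a
small isotropic sheet, and absolute dominant-frequency values are not
comparable.

## Synthetic data and what passing tests show

`gen_block_dataset()` generates the voltage-clamp observations the
calibration consumes — tail-current dose–response points and tonic +
use-dependence series — from known binding constants, with additive
Gaussian noise on fractional block (σ = 0.02 by default, comparable to
published scatter; clipped to [0, 1] with the clipping rate reported).
`gen_fixture_waveform()` supplies analytic waveforms (trapezoid AP,
two-Gaussian pseudo-ECG, amplitude-modulated sine) whose APD90/QT/dominant
frequency are known in closed form, used to validate the biomarker
extraction independently of the physiology. These fixtures emulate the
*statistical structure* the fitting assumes — independent Gaussian errors,
log-spaced design — not the correlated, protocol-specific errors of real
patch-clamp data; a passing round-trip therefore demonstrates
identifiability of the procedure, not accuracy on any particular laboratory
dataset.

## Numerical choices and problem sizes

Fixed choices, stated once: cell/strand step 0.005 ms, 2D step 0.02 ms
(both well inside CFL and step-halving convergence); voltage table range
−150…+100 mV at 0.02 mV; Markov rates capped at 25 ms⁻¹ (reached only far
outside the physiological range); 100 pre-pacing beats and 4 coupled strand
beats for headline numbers, 60/3 for trend tests; ERP bisection 1 ms (2 ms
in trend tests, whose margins are tens of ms); re-entry windows 1.2–2.2 s
with the spectrum computed over the active portion. The bounded Nelder–Mead
used for all fits runs on logistic-transformed parameters with multi-start
(seeded, reproducible) and reports convergence and bounds.

## Known limitations

* Binding kinetics (as opposed to affinities) of the hERG drug models are
  under-identified by equilibrium dose–response data; drug-treated QT
  predictions inherit that uncertainty (~15% span for quinidine at 2 µM).
* I~to~ pore block mildly *shortens* APD in this lineage, so the combined
  I~Kr~+I~Na~ share of disopyramide's QT prolongation evaluates slightly
  above 100% rather than ~93%.
* No temperature dependence (all kinetics are body-temperature by
  construction), no mixed WT/mutant tetramer stoichiometry, no Purkinje
  system or realistic torso geometry; the 2D re-entry analog supports trend
  statements only.
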