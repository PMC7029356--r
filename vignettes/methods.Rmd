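---
title: "Identifying ion-channel drug effects from voltage and calcium waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying ion-channel drug effects from voltage and calcium waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Cardiomyocytes derived from human induced pluripotent stem cells
(hiPSC-CMs) are attractive for cardiotoxicity screening, but they are
electrophysiologically immature: channel densities and cell geometry
differ substantially from adult ventricular myocytes, so a drug response
observed in an hiPSC-CM microtissue cannot be read off directly as an
adult response. `cardioinverse` implements a model-based route around
this: paired membrane-potential and cytosolic Ca²⁺ waveforms recorded
under a dose-escalation protocol are inverted into a mechanistic
action-potential (AP) model, the drug's effect on each targeted channel
is quantified as an IC50, and — under the assumption that a drug blocks
an *individual channel* identically at both maturity stages — the fitted
effect is transferred to an adult parameterization through a maturation
map.

# The base model

## Membrane currents

The membrane potential obeys `dv/dt = -sum(I_x)` with thirteen currents:
I_Na, I_NaL, I_CaL, I_to, I_Kr, I_Ks, I_K1, I_NaK, I_NaCa, I_pCa, I_bCa,
I_bCl and the funny current I_f, all in A/F. Every current is a product
of a lumped density parameter `g_x` and a single-channel factor
(`o_x * (v - E_x)` for gated channels, saturating kinetic forms for the
pump and exchanger). Only the densities differ between maturity stages;
the single-channel models are shared. This factorization is what makes
the maturation map a simple per-parameter rescaling.

The gating formulations are adapted from the ten Tusscher (2004) and
Grandi (2010) adult ventricular models and, for I_f, the Paci (2013)
hiPSC-CM model, with the following deliberate departures, made so that
*both* shipped presets remain stable under the aggressive parameter
perturbations the inversion performs:

* **I_Kr rectification.** The slow secondary gate of the ten Tusscher
  formulation suppresses I_Kr so strongly at depolarized potentials that
  a parameterization whose repolarization reserve rests on I_Kr (as the
  hiPSC preset's does) cannot repolarize at all. It is replaced by a
  fast (τ = 4 ms) hERG-like rectification gate,
  `x_inf = 1/(1 + exp((v + 20)/15))`: suppressed during the plateau,
  resurgent as the potential falls.
* **I_Ks activation** is accelerated (base time constant divided by 8)
  so I_Ks contributes within a single AP.
* **I_CaL Ca²⁺-dependent inactivation** is a smooth Hill function of
  *dyadic* Ca²⁺, `f_Ca,inf = 0.02 + 0.98/(1 + (c_d/k_fCa)^2)` with
  `k_fCa = 1.5 µM` and τ = 5 ms. The low floor is required: with weaker
  Ca²⁺-dependent inactivation the hiPSC preset admits a pathological
  fixed point near 0 mV in which a sustained L-type window current, a
  standing RyR release and the resulting forward-mode Na⁺/Ca²⁺-exchange
  current depolarize the cell indefinitely.

## Intracellular Ca²⁺

Five compartments are modeled — dyad, subsarcolemmal (SL) space, bulk
cytosol, junctional SR and network SR — each with free and (except the
nSR) buffered Ca²⁺, linked by diffusion fluxes, SERCA uptake into the
nSR and RyR release. Two structural choices give the release model *high
gain* and *graded release*:

1. RyR release is directed into the SL space, not the dyad, so the
   dyadic concentration remains an almost pure readout of the L-type
   trigger flux, and
2. release is the product of an open probability
   `p = c_d³/(c_d³ + κ³)` and an *availability* fraction `r` that is
   consumed in proportion to the released Ca²⁺
   (`dr/dt = -J_RyR/β + η p (1 - r)`) — channels can only pass a
   limited amount of Ca²⁺ before deactivating, and recover while the
   dyadic concentration decays.

Numerically important orderings: the release half-activation κ (3 µM)
sits *above* the L-type inactivation scale k_fCa (1.5 µM), so L-type
inactivation always engages before sustained release can self-maintain;
the availability recovery rate η = 0.1/ms is slow enough that a
sustained-release equilibrium has low availability. Buffer kinetics use
first-order on/off rates per compartment with dissociation constants of
0.6 µM (cytosolic, troponin-like), 13 µM (dyad/SL, sarcolemmal-site-like)
and 0.65 mM (junctional SR, calsequestrin-like); the on-rates are capped
(2.5–10 /mM/ms) so that the fastest buffering rate stays well inside the
stability region of the fixed-step integrator.

## Presets and the maturation map

The *default base model* is the adult parameterization. The hiPSC-CM
preset is derived from it through fixed maturation factors
`(1 + λ) p_hiPSC = p_adult` — e.g. the adult fast-sodium and
inward-rectifier densities are 3.0× and 3.2× the hiPSC values, the adult
transient-outward density 9.5×, while the hiPSC funny-current density is
100× the adult one and its surface-to-volume ratio is 0.9 /µm against
the adult 0.6 /µm (t-tubules roughly double the adult membrane area).
`build_maturation_map()` recovers the diagonal map Q from any two
parameter sets; applying Q to a *drugged* hiPSC parameterization
predicts the drugged adult cell, which is exactly how
`predict_adult_response()` operates.

At 1 Hz pacing the adult preset rests at −84 mV with APD80 ≈ 156 ms;
the hiPSC preset rests at −80 mV with APD80 ≈ 200 ms, a slower upstroke
and a smaller Ca²⁺ transient, and it is not spontaneously active (the
package studies paced preparations). On the voltage-clamp grid from
−50 to 80 mV the integrated RyR release exceeds the integrated L-type
trigger at all plateau potentials (high gain; minimum ratio ≈ 2.4 adult,
≈ 1.2 hiPSC) and the release peak tracks the trigger peak along the
ascending limb (graded release).

# Drug model and cost function

A channel blocker scales each targeted conductance by
`1/(1 + D/IC50)`; at `D = IC50` the conductance is halved. The package
works with the reciprocal potency `ε = 1/IC50`, which is zero for "no
effect" and grows with effect size — the natural parameterization for a
continuation that starts from the unperturbed model. Only ε_CaL, ε_NaL
and ε_Kr are fitted: those are the currents the screening literature
identifies as the dominant torsadogenic targets, and the optical data
carry little information about the others.

The misfit between model and data is a weighted sum of squared
*relative* differences of waveform characteristics: AP durations at 30,
50 and 80 % repolarization, Ca²⁺ transient durations at 20–80 % decay,
maximum upstroke slopes of both signals, Ca²⁺ amplitude and baseline,
and the area measure Int30 (integral of `v - v_rest` where v exceeds the
30 %-repolarization level — chosen for consistency with the APD30
geometry). APD80 and CaD80 carry weight 5, the intermediate Ca²⁺
durations 0.5, everything else 1. All duration measures use linear
interpolation at level crossings and are invariant to time shifts and
positive rescaling, which is what makes them usable on normalized
optical data. A failed simulation or an AP with no detectable upstroke
replaces every term of that dose with a penalty of 10, which dominates
any realistic relative difference. Regularization terms are not applied
by default.

# The continuation inversion

Fitting λ (density adjustments) and ε (potencies) jointly over all doses
is a rugged optimization problem. The package solves it by continuation:
the target characteristics are blended,
`R_θ = (1 - θ) R(default model) + θ R(data)`, so that at θ = 0 the
optimum is exactly λ = ε = 0, and θ is stepped to 1 in M steps. At each
step, budget-limited Nelder–Mead descents are run from the incumbent and
from random starts drawn uniformly in `λ ± 0.2` (clipped to
(−0.95, 20)) and log-uniformly in `[ε/5, 5ε]`; the best point becomes
the next incumbent. ε is optimized in log space. When the incumbent ε is
zero the start distribution is centered on a floor of `0.01/D_max` — a
just-detectable block at the top dose; a much smaller floor would leave
the continuation unable to climb to physiological potencies within few
steps, because each step can only move ε by about the ×5 sampling range.

The reference configuration follows common practice for a many-core
machine (M = 20 steps, 63 starts, 5 simplex iterations early and 25
late). The *scaled-down* configuration used throughout the package's
own studies — chosen once as the smallest budget that reproduces the
synthetic-study potencies, and used for all results quoted here — is
M = 5 steps, 5 starts, 8/20 simplex iterations, with only the three ε
free and six paced beats per simulation; the single- and two-channel
studies converge with an even lighter budget (4 steps, 3 starts, 6/15
iterations), while the three-channel Flecainide study genuinely needs
the full scaled-down budget. Everything is deterministic given the
seed; starts are drawn from R's RNG.

# The simulated drug studies

The five shipped synthetic studies perturb the hiPSC preset with a
background density change λ_CaL = λ_NaL = λ_Kr = 0.1, apply the block
for each dose, pace at 1 Hz and record the sixth AP after every
parameter change: Nifedipine (pure I_CaL, IC50 10 nM, doses
3/30/300/3000 nM), Lidocaine (pure I_NaL, 10 µM), Cisapride (pure I_Kr,
10 nM), Flecainide (CaL 25 µM, NaL 20 µM, Kr 10 µM) and Verapamil
(CaL 200 nM, Kr 500 nM). No noise is added; generation is fully
deterministic.

Only the Nifedipine ladder is fixed by convention. For the others the
package uses a four-point geometric ladder from 1/8 to 1.6 times the
geometric-mean IC50 of the drug's targets. The upper cap is a model
property: beyond roughly twice the IC50 of a *pure* hERG blocker the
hiPSC preset loses its repolarization reserve and the paced AP
degenerates into an alternans-like regime — dose points in that regime
carry no usable waveform information, much as saturating doses in a real
dose-escalation study do not.

With the scaled-down inversion the synthetic studies recover the
generating potencies of the well-identified targets within a factor of
two (typically within ~25 %: e.g. Verapamil I_CaL ≈ 236 nM against the
generating 200 nM). The late sodium current is the documented hard
case — its contribution to the waveform is small, consistent with its
low identifiability index — so for Lidocaine the package asserts only
that the *largest* fitted block falls on I_NaL, not its magnitude.

# Identifiability

Sampling all thirteen currents of one measurement beat at 1 ms into a
matrix and taking its SVD ranks directions in conductance space by their
effect on the waveform. Perturbing the densities along each right
singular vector (`λ = ω v_i`, ω on a 0–1 grid in steps of 0.1) and
scoring the AP change (APD30/50/80 and Int30; APD80 weighted 5) defines
the *unidentifiable space*: vectors whose maximum score stays below
0.05. The identifiability index of current j is the distance of its unit
vector from that space: `k = ||e_j - P e_j||`, 1 = identifiable, 0 = not.

On the hiPSC preset this analysis finds I_CaL, I_Kr and I_NaCa highly
identifiable (k ≈ 0.94/0.99/0.89) and I_Na, I_to, I_pCa, I_bCa and
I_bCl essentially unidentifiable — I_Na because the upstroke velocity is
deliberately absent from the scan cost, mirroring the resolution limit
of optical recordings. The inversion presets therefore keep the weakly
identified densities fixed; the vector with the largest singular value
is dominated by I_Na and scores a *small* perturbation cost, the known
exception to the rule that large singular values mean large waveform
effects.

# Numerical choices

* **Integrator.** A fixed-step Rush–Larsen scheme in C++ (exact
  exponential updates for the 14 gates and the RyR availability at
  frozen rates; forward Euler for potential, concentrations and
  buffers), default step 0.02 ms, output sampling 1 ms. The scheme is
  robust under the random parameter excursions of the multi-start
  search, where adaptive implicit solvers fail unpredictably, and its
  cost is strictly proportional to simulated time. Halving the step
  changes APD80 of a conditioned beat by under 0.15 ms for both presets.
* **Blow-up detection.** |v| > 500 mV or a non-finite state aborts the
  integration with a structured error carrying the last valid time; the
  cost function converts this into the penalty value.
* **Initial conditions.** Each preset ships the state reached after 200
  conditioning beats at 1 Hz, regenerable with `steady_state()`.
* **Caching.** Within one inversion, per-dose simulations are memoized
  on the exact parameter vector; with λ fixed this removes every
  repeated control simulation.
* **Serialization.** JSON envelopes write doubles with 17 significant
  digits, so dataset round trips are bit-exact.

# What the synthetic studies do and do not show

The generator reproduces the *structure* of a microphysiological
dose-escalation experiment — paired waveforms, a control plus an
escalating ladder, background cell-line variability in the three target
densities — but not photon noise, motion artifacts, dye dynamics or
frame-rate limits, and its traces come from the same model family the
inversion fits (no model misspecification). Passing the recovery tests
therefore demonstrates that the pipeline is correct and well-conditioned
on in-model data; accuracy on real optical recordings additionally
depends on the preprocessing (3-point median filter, dF/dt-max
alignment, beat averaging — `preprocess_optical()`) and on the adequacy
of the base model itself, which the tests cannot certify.

# Known limitations

* Intracellular Na⁺ and K⁺ are constants; drugs whose signature is a
  slow Na⁺ load are outside the model class.
* Simple conductance block only — no state-dependent or use-dependent
  (Markov) drug models.
* The availability-based release model is built for stability, not as a
  mechanistic account of RyR gating.
* Spatial (tissue-level) effects and spontaneous beating are out of
  scope; all protocols are paced single-cell.
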