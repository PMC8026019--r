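---
title: "Methods: whole-body PBPK modelling of metformin in mouse and human"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body PBPK modelling of metformin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Metformin is a hydrophilic, permanently cationic drug: it is not metabolized,
does not bind plasma proteins appreciably, crosses membranes almost entirely
through organic-cation transporters (OCT1-3, PMAT, MATE1/2-K), and is
eliminated exclusively by the kidney. These properties fix the model
structure used here.

The body is a set of organ compartments connected by arterial and venous
plasma. Most organs (lungs, heart, brain, muscle, adipose, stomach wall,
liver, and a lumped "remainder") are **flow-limited (well-stirred)**: the
drug equilibrates between tissue and perfusing plasma instantaneously
relative to the plasma flow `Q`, so the tissue amount `A_t` in a tissue of
volume `V_t` with partition coefficient `K_t:p` obeys

    dA_t/dt = Q * C_in  -  (Q / K_t:p) * C_t,      C_t = A_t / V_t

where `C_in` is the afferent plasma concentration (arterial for most organs,
mixed portal + hepatic-arterial for the liver, venous for the lungs). Because
arterial and venous plasma are distinct compartments, each tissue is wired
with this *pair of directional clearances* rather than one net exchange
term; the primitive net rate `Q*(C_source - C_tissue/Ktp)` is still exposed
as `flow_exchange_rate()`.

Two organs are **permeability-limited**, with carrier kinetics instead of
flow equilibration:

* **Small intestine** (absorption): intestinal lumen, enterocytes, and an
  intestinal vascular space. Oral doses enter the stomach lumen, empty into
  the intestinal lumen at the first-order gastric rate, and leave to feces at
  the first-order transit rate. Absorption happens only from the intestinal
  lumen — saturable apical uptake into enterocytes (PMAT/OCT3; reaction
  03.2), basolateral efflux to blood (OCT1; 03.3), a saturable and a linear
  paracellular route straight to blood (03.4, 03.7), and linear diffusion
  into enterocytes (03.6). Enterocytes also exchange passively with the
  vascular space with the intestinal `K_t:p` as the equilibrium ratio
  (03.5). The stomach wall sees drug only through its blood flow: there is
  deliberately no lumen-to-stomach-tissue path.
* **Kidney** (elimination): kidney plasma, kidney tissue, and the proximal
  tubular lumen. Renal clearance is glomerular filtration
  (`Q_GFR * C_kidney_plasma`, reaction 13.6) plus active secretion: OCT2
  uptake from kidney plasma into tissue (13.4) and MATE1/MATE2-K efflux into
  the tubular lumen (13.5), both Michaelis-Menten; passive exchange between
  kidney plasma and tissue carries the renal `K_t:p` (13.3). Tubular content
  flows to the cumulative urine compartment at the urine flow rate. Distal
  tubule and collecting duct are not represented (no reabsorption is
  expected for a permanent cation).

The human model adds a red-blood-cell compartment that exchanges with venous
plasma by two slow first-order clearances (no transporters are expressed on
erythrocytes; uptake is diffusion-like). RBCs are excluded from the flow
topology. That gives 20 compartments for the mouse and 21 for the human.

**Units** are fixed internally: nmol (amount), mL (volume), h (time),
nmol/mL (concentration). Doses are accepted in mg of metformin
*hydrochloride* — the clinical unit — and converted with the fixed salt
factor 0.7784 (1000 mg HCl = 778.4 mg free base) and molar mass
129.16 g/mol. The ODE state is amount per compartment, which makes mass
balance a plain row sum; urine and feces are explicit amount sinks, so the
summed state must equal the administered dose at all times after the last
dose (checked to 1e-6 relative, typically ~1e-14).

## Parameters: what is fixed and what is reconstructed

Fixed, externally given constants: the estimated partition-coefficient set
(intestine 4.6, stomach 3.2, liver 5.5, lungs 3.0, brain 0.8, muscle 4.1,
adipose 0.7, heart 2.5, remainder 0.8, kidney 4.5; assumed identical across
species because metformin does not bind plasma proteins), the
tissue-composition ("calculated") comparison values, the mouse-to-human
scale-up coefficients (0.7 on the five absorption reactions 03.2, 03.3,
03.4, 03.6, 03.7; 320 on the two active renal reactions 13.4, 13.5), the
intestinal surface areas (3e4 cm2 mouse; 71e4 cm2 human — published figures
give both 70 and 71 m2, and the value actually used in the scale-up, 71 m2,
is the default; it is carried as a configuration parameter), the monolayer
protein density 0.2 mg/cm2, and the salt factor and molar mass above.

Everything else — tissue volumes and plasma flows, GFR and urine flow, gut
motility rates, the transporter Vmax/Km values, the passive exchange
permeabilities, and the RBC clearances — is a **synthetic reconstruction**:
the original deposited parameter tables are not reproduced here. Standard
reference physiology (0.04 kg mouse, 70 kg human) was combined with
Caco-2-style intestinal kinetics carried per mg of monolayer protein and
rescaled per surface area, and the free kinetic magnitudes were calibrated
*once* against the published headline pharmacokinetics of metformin —
mouse oral 50 mg/kg: ~61% of dose in urine by 24 h, plasma Cmax ~27 nmol/mL;
human oral 500 mg: plasma Cmax ~6.1 nmol/mL, AUC24 ~42 nmol*h/mL, ~51% of
dose in urine, slow RBC kinetics with ~22 h half-life; dose-dependent
absorption from 500 to 1500 mg — and then frozen. The human intestinal
protein density is exposed as its own adjustable "Proctor coefficient"
(default 1.75 mg/cm2 from the same calibration), because strict per-area
scaling of the monolayer kinetics cannot carry a 400-fold dose increase
across a 24-fold area increase while preserving the absorbed fraction.

Two published headline values are *structurally* out of reach of this model
family, and the defaults do not chase them:

* a human kidney-tissue Cmax of ~840 nmol/mL together with a mouse kidney
  curve ~15x plasma: with both renal reactions scaled by one elimination
  coefficient, the kidney tissue:plasma ratio is nearly species-invariant,
  so the human kidney here peaks near 90 nmol/mL (~15x plasma), not 840;
* a human plasma terminal half-life of 3.7 h alongside a muscle half-life of
  5.5 h: muscle holds the largest share of the distribution volume, so in a
  flow-limited topology the plasma terminal phase is dragged toward the
  muscle washout (~5.4 h here).

Renal clearance is flow-limited in both species (extraction ratio ~0.8):
raising the intrinsic OCT2 capacity far above the renal plasma flow is what
lets a single x320 coefficient reproduce both the mouse clearance
(~90 mL/h active) and the human clearance (~30 L/h total, i.e. ~500 mL/min).

## Simulation engine

The reaction list is compiled once into index vectors and a stoichiometry
matrix, so the right-hand side is a handful of vectorized operations; the
system is integrated with deSolve's stiff-capable `lsoda`. Dose events are
discontinuities: boluses are applied with solver events (integration
restarts), oral doses into the stomach lumen, intravenous boluses into
venous plasma; doses at t = 0 are folded into the initial state. Defaults:
relative tolerance 1e-8, absolute tolerance 1e-10 nmol (floored at 1e-12 of
the administered dose so therapeutic runs are not asked for sub-molecule
accuracy), output grid 0.01 h — peak times are reported to better than
0.1 h. Small negative amounts within the tolerance floor are clipped to
zero; anything beyond it is a hard error, because silent clipping hides
model bugs. Halving tolerances or doubling the output grid changes every
reported summary by well under 0.1%.

## Non-compartmental summaries

AUC is the linear trapezoid on the given grid (on the dense simulation grid
the lin-up/log-down refinement changes nothing at the 0.1% level, so the
simple rule is used for observed and simulated curves alike). Cmax/Tmax take
the global maximum with ties broken by the earliest time; on dense simulated
curves the peak is refined by a parabola through the three points around the
grid maximum, so Tmax does not jump with the output grid. The terminal
half-life is `ln 2 / lambda_z`, with `lambda_z` chosen by maximizing the
adjusted R-squared over all suffix windows of at least three positive
points strictly after Tmax — the usual NCA best-fit convention, implemented
with suffix cumulative sums so dense grids cost O(n). Multi-dose summaries
report one Cmax/Tmax per regimen (so Tmax can fall in a late interval),
`Cmean` as AUC over the final complete interval divided by tau, and a
steady-state time: the start of the first interval whose peak changes by
less than 1% from the previous one, or, for a compartment still accumulating
when dosing stops (RBCs), the time of its global maximum.

## Parameter estimation

The objective is the sum over non-excluded observations of
`w * (simulated - observed)^2` with per-curve weight `1/mean(observed)^2`;
observed curves span ~0.7 to ~2000 nmol/mL, and cumulative urine amounts are
their own curves, so each curve contributes on a comparable scale. The mouse
oral preprocessing rule flags (never deletes) the whole stomach curve and
the 2 h venous-plasma/portal-vein/brain points before fitting.

Optimization is multistart bounded Levenberg-Marquardt (`minpack.lm`) in
log-parameter space (positivity plus a 0.4-500 parameter scale spread), with
log-space Latin-hypercube starts from a seeded RNG; the first start is
always the user's start vector, and the run is bit-for-bit reproducible from
the seed. One numerical detail matters: the finite-difference step is set
well above the ODE-solver noise floor (`epsfcn = 1e-6`), otherwise the
Jacobian is dominated by integration noise and the optimizer stalls far from
the optimum. During fitting the solver runs with a coarser grid and
tolerance (residuals only need the solution at the observation times).

Identifiability: each partition coefficient needs its tissue observed, so
the all-tissue `preset_recovery()` design (which adds lungs and stomach to
the nine-tissue oral harvest) is used for recovery experiments. On
noiseless data all ten partition coefficients come back within 0.001% from
a neutral start, and the two human scale-up coefficients within 0.01% from
the plasma/RBC/urine design alone.

## Synthetic data

`generate_dataset()` samples any simulation at the sparse grids of the
source designs — mouse organ harvests at 0.5/1/2/4/8/24 h, human plasma/RBC
at 1/2/3/4/6/10/24 h with urine collections at 4/6/10/24 h, pre-dosed and
twice-daily designs — and applies multiplicative lognormal noise
`exp(N(0, sigma))` with `sigma = sqrt(log(1 + cv^2))`, so the requested CV
is exact. Default CV 10%, typical bioanalytical assay precision. Urine and
feces observations are cumulative amounts (nmol), matching how excretion
data are reported. Ground truth travels with the dataset.

What this does *not* emulate: between-subject variability (every dataset is
one "mean subject"), correlated or heteroscedastic assay error, sampling-time
jitter, or model misspecification. Passing parameter-recovery tests
therefore shows the estimation machinery is correct and the design
identifiable — not that fitting real cohort data would recover transporter
parameters with this precision.

## Scenarios

`scenario_modify_tissue()` changes one tissue's volume with its blood flow
scaled by the volume ratio, so cardiac output and lung flow rise by the same
absolute increment and the remainder tissue is untouched (the body grows by
the added tissue). With twice-daily 500 mg dosing, adding 20 L of muscle
damps the plasma oscillation amplitude by ~21% while moving the mean by
under 0.1%; adding 60 L of adipose damps the adipose oscillation ~18% —
partition-coefficient differences (muscle 4.1 vs adipose 0.7) make muscle a
much stronger buffer.

## Resolved design questions

* The well-stirred tissue ODE is the standard flow-limited form; it is never
  written out in the source material, only implied by the symbol legend.
* Urine is a cumulative amount sink; urine-flow bookkeeping (`Q_urine`, the
  tubular-to-urine clearance) supports concentration comparisons if needed.
* The inulin-space correction is implemented as division by the
  intracellular fraction FI (the published tissue values were *corrected*
  concentrations); the direction is an argument because both conventions
  appear in the literature. The per-organ FI table is not published, so the
  packaged values are synthetic stand-ins.
* AUC_tissue/AUC_plasma equals `K_t:p` exactly only for flow-limited tissues
  referenced to their afferent plasma (arterial for most, venous for lungs,
  the flow-weighted inflow for liver); permeability-limited organs retain
  active-transport terms in that ratio even when linearized, so the
  invariance check covers the eight flow-limited tissues.
* Body-weight scaling is linear on volumes, flows, GFR, urine flow,
  intestinal area and organ-level transport capacities; a fully linear model
  variant is then exactly invariant under dose-per-kg scaling, which is the
  property that makes "weight" a clean personalization parameter.

## Problem sizes in the test suite

The suite simulates at the reporting resolution (0.01 h grid) for 24-168 h
courses, runs the ten-parameter recovery once from a neutral start (about
10 s), the two-parameter scale-up recovery (about 2 s), and Monte-Carlo
noise checks with 1000 draws of a one-compartment curve; the full suite
completes in well under two minutes on one CPU.
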