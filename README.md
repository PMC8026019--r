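# mfpbpk — whole-body PBPK modelling of metformin in mouse and human

Metformin, the first-line drug for type 2 diabetes, acts in tissues —
intestine, liver, muscle, kidney — whose drug concentrations cannot be
measured in people; only plasma, red blood cells and urine are accessible.
Physiologically based pharmacokinetic (PBPK) modelling bridges that gap:
organs are represented as compartments with real volumes and plasma flows,
tissue uptake is summarized by tissue:plasma partition coefficients
(`K_t:p`) estimated where tissue data *do* exist (mouse organ-harvest
studies), and the mouse model is scaled up to a human whose predictions can
be checked against plasma/RBC/urine data. This package is for
pharmacometricians and quantitative pharmacologists who want that whole
pipeline — model assembly, ODE simulation with dosing events,
non-compartmental analysis, parameter estimation, and scenario analysis —
as tested, scriptable R.

## The model

* 20 compartments (mouse) / 21 (human, adding red blood cells), connected
  by arterial and venous plasma; lungs carry the full cardiac output.
* Flow-limited organs follow the well-stirred form
  `dA_t/dt = Q·C_in − (Q/K_t:p)·C_t`.
* The small intestine is permeability-limited: oral doses transit
  stomach lumen → intestinal lumen → feces at first-order rates, and are
  absorbed from the intestinal lumen by saturable carrier uptake
  (`V_max·S/(K_m+S)`, PMAT/OCT3), OCT1 efflux to blood, and
  saturable + linear paracellular routes (Caco-2-derived kinetics rescaled
  per intestinal surface area).
* The kidney is permeability-limited: renal clearance is
  `CL_renal = Q_GFR + CL_active`, with the active part carried by OCT2
  uptake into tubular cells and MATE1/MATE2-K efflux into the proximal
  tubular lumen, which drains to cumulative urine.
* Mouse → human scale-up: `K_t:p` values transfer unchanged; an absorption
  coefficient (0.7) multiplies the five intestinal absorption reactions and
  an elimination coefficient (320) the two active renal reactions; volumes,
  flows and transport capacities scale linearly with body weight.
* Internal units: nmol, mL, h. Doses are entered as mg of metformin
  hydrochloride (1000 mg ↔ 778.4 mg free base, molar mass 129.16 g/mol).

The bundled default parameterization is a calibrated synthetic
reconstruction (the deposited supplementary tables are not redistributed);
see the methods vignette (`vignettes/mfpbpk-methods.Rmd`) for what is fixed,
what was calibrated against published headline values, and the model
family's known structural limits.

## Worked example

```r
library(mfpbpk)

human <- build_human_model()                       # 21 compartments, 70 kg
sim   <- simulate_pbpk(human, dose_schedule(0, 500, "PO"), duration = 48)
pk_summary_table(sim, 500)
```

yields (selected tissues):

```
        tissue  auc24    cmax  tmax amount_at_cmax_mg t_half
 venous_plasma   43.9   6.380  2.61             1.566   5.61
           rbc   17.9   0.924 12.30             0.279  19.56
        muscle  174.8  15.983  5.03            57.802   5.45
   enterocytes 2331.9 648.099  1.88            54.410   5.56
         liver  457.4  93.320  2.20            21.696   5.60
 kidney_tissue  570.2  86.568  2.76             3.131   5.61
fraction of dose in urine by 24 h: 48.5%
```

Read: a single 500 mg oral dose of metformin hydrochloride gives a plasma
peak of 6.4 nmol/mL (~0.8 mg/L) at 2.6 h; the intestine and kidney see
concentrations two orders of magnitude higher than plasma (absorption and
excretion organs); muscle holds the largest tissue amount (~58 mg at peak);
red blood cells load slowly and release with a ~20 h half-life; about half
the dose is absorbed, and all of what is absorbed leaves in urine.

Other entry points: `build_mouse_model()`, `scenario_modify_tissue()`
(e.g. +20 L muscle for an athlete), `generate_dataset()` +
`fit_pbpk()` for parameter estimation with known ground truth,
`load_model_config()` for YAML/CSV parameterizations, and an
`inst/cli/mfpbpk` Rscript exposing `simulate`, `nca`, `synth` and `fit`
subcommands.

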