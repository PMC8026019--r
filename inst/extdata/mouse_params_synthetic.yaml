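species: mouse
physiology:
  body_weight: 0.04
  cardiac_output: 1193.0
  volumes:
    lungs: 0.29
    heart: 0.2
    brain: 0.5
    muscle: 15.4
    adipose: 2.8
    stomach: 0.24
    liver: 2.2
    kidney_plasma: 0.08
    kidney_tissue: 0.55
    kidney_tubular: 0.055
    intestine_vascular: 0.16
    enterocytes: 0.48
    intestine_lumen: 0.56
    stomach_lumen: 0.48
    arterial_plasma: 0.56
    venous_plasma: 1.04
    portal_vein: 0.16
  flows:
    heart: 78.0
    brain: 40.0
    muscle: 189.0
    adipose: 60.0
    stomach: 14.0
    kidney: 108.0
    intestine: 142.0
    liver_arterial: 24.0
  q_gfr: 14.0
  q_urine: 0.06
  k_gastric: 3.0
  k_transit: 1.0
  hematocrit: .na.real
  intestinal_area_cm2: 30000.0
  protein_per_area: 0.2
partition_coefficients:
  intestine: 4.6
  stomach: 3.2
  liver: 5.5
  lungs: 3.0
  brain: 0.8
  muscle: 4.1
  adipose: 0.7
  heart: 2.5
  remainder: 0.8
  kidney: 4.5
kinetics:
  proctor:
    v32_per_mg: 0.6
    km32: 1200.0
    v33_per_mg: 0.0825
    km33: 9000.0
    v34_per_mg: 0.15
    km34: 2000.0
    kd36_per_mg: 2.2e-05
    kd37_per_mg: 1.0e-05
  kidney:
    vmax_oct2: 400000.0
    km_oct2: 1000.0
    vmax_mate: 6280.0
    km_mate: 780.0
  ps_intestine:
    mouse: 6.0
    human: 3000.0
  ps_kidney:
    mouse: 5.0
    human: 500.0
  rbc:
    cl_in: 75.0
    cl_out: 85.0
  proctor_coefficient_human: 1.75
scale_up: ~
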