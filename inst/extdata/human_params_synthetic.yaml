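species: human
physiology:
  body_weight: 70.0
  cardiac_output: 171600.0
  volumes:
    lungs: 530.0
    heart: 330.0
    brain: 1450.0
    muscle: 28000.0
    adipose: 15000.0
    stomach: 150.0
    liver: 1800.0
    kidney_plasma: 30.0
    kidney_tissue: 280.0
    kidney_tubular: 30.0
    intestine_vascular: 300.0
    enterocytes: 650.0
    intestine_lumen: 350.0
    stomach_lumen: 250.0
    arterial_plasma: 900.0
    venous_plasma: 1900.0
    portal_vein: 70.0
    rbc: 2340.0
  flows:
    heart: 6864.0
    brain: 20592.0
    muscle: 36000.0
    adipose: 8580.0
    stomach: 1716.0
    kidney: 45000.0
    intestine: 25740.0
    liver_arterial: 11154.0
  q_gfr: 7200.0
  q_urine: 60.0
  k_gastric: 3.5
  k_transit: 0.5
  hematocrit: 0.45
  intestinal_area_cm2: 710000.0
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
scale_up:
  absorption: 0.7
  elimination: 320.0
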