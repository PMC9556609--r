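# ILLUSTRATIVE defaults for clot decomposition, not measured ground truth.
# Initial attenuation assumptions for the three histology-visible clot
# constituents would normally be seeded from tabulated mass attenuation
# coefficients (hemoglobin at MCHC density for RBC, fibrin, soft tissue for
# WBC); the uncorrected values below are synthetic stand-ins on that scale
# for examples and simulations. Formalin and iomeprol carry plausible
# fixed attenuations; iomeprol stock is 20 mg/ml.
energies: [50.0, 200.0]
materials:
- name: fibrin
  mu_low: 0.2892
  mu_high: 0.1847
  units: 1/cm
- name: RBC
  mu_low: 0.0731
  mu_high: 0.0450
  units: 1/cm
- name: WBC
  mu_low: 0.2230
  mu_high: 0.1361
  units: 1/cm
- name: formalin
  mu_low: 0.229
  mu_high: 0.138
  units: 1/cm
- name: iomeprol
  mu_low: 0.433
  mu_high: 0.152
  units: 1/cm
  stock_concentration_mg_per_ml: 20.0
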