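# Aqueous basis solutions at the default (50, 200) keV working energies.
# Attenuation endpoints of the stock solutions from dilution-series
# regression; water values are standard liquid-water attenuation at these
# energies (configuration constants, to be replaced by a site calibration).
energies: [50.0, 200.0]
materials:
- name: eosin
  mu_low: 0.290
  mu_high: 0.141
  units: 1/cm
  stock_concentration_mg_per_ml: 40.0
- name: iomeprol
  mu_low: 0.433
  mu_high: 0.152
  units: 1/cm
  stock_concentration_mg_per_ml: 20.0
- name: water
  mu_low: 0.2269
  mu_high: 0.1370
  units: 1/cm
- name: NaCl
  mu_low: 0.306
  mu_high: 0.151
  units: 1/cm
  stock_concentration_mg_per_ml: 200.0
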