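material,concentration_mg_per_ml,mu_low,mu_high,units
iomeprol,1,0.237205,0.137750,1/cm
iomeprol,5,0.278425,0.140750,1/cm
iomeprol,10,0.329950,0.144500,1/cm
iomeprol,15,0.381475,0.148250,1/cm
iomeprol,20,0.433000,0.152000,1/cm
eosin,5,0.234787,0.137500,1/cm
eosin,10,0.242675,0.138000,1/cm
eosin,20,0.258450,0.139000,1/cm
eosin,35,0.282112,0.140500,1/cm
eosin,40,0.290000,0.141000,1/cm
NaCl,50,0.246675,0.140500,1/cm
NaCl,80,0.258540,0.142600,1/cm
NaCl,100,0.266450,0.144000,1/cm
NaCl,150,0.286225,0.147500,1/cm
NaCl,200,0.306000,0.151000,1/cm
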