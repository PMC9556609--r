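specimen_id,value_low,value_high,units
mix1,0.274300,0.143000,1/cm
mix2,0.313975,0.145250,1/cm
mix3,0.232636,0.137364,1/cm
mix4,0.256967,0.141367,1/cm
mix5,0.282292,0.144417,1/cm
mix6,0.267062,0.144009,1/cm
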