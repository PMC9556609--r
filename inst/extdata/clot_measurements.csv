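specimen_id,value_low,value_high,units
clot01,0.141435,0.085226,1/cm
clot02,0.266150,0.164357,1/cm
clot03,0.166222,0.098698,1/cm
clot04,0.272794,0.167041,1/cm
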