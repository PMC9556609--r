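specimen_id,units,fibrin,RBC,WBC
clot01,percent,24.15,75.70,0.15
clot02,percent,93.13,3.07,3.80
clot03,percent,16.14,79.99,3.87
clot04,percent,89.01,6.91,4.08
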