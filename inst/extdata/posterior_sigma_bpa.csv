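analyte,prior_median,prior_q2.5,prior_q97.5,median,q2.5,q97.5
BPA,6.72,0.32,22.58,0.606,0.551,0.667
BPAG,166.68,8.36,551.93,198.85,166.50,236.14
BPAS,16.88,0.76,56.71,23.34,19.16,29.02
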