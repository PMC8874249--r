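parameter,value
molecular_weight,228.291
molecular_diffusion_volume,220.14
molar_volume,200
henry_constant,9.28e-7
degradation_rate_water,2.14e-7
degradation_rate_air,6.42e-5
log_kow,3.32
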