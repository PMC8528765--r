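characteristic,ot_mean,ot_sd,ot_n,not_mean,not_sd,not_n
treatment_length,24.09,14.25,273,32.07,14.17,140
age,36.62,12.97,273,36.75,12.99,140
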