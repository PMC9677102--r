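sex,age_lo,age_hi,c_ow,c_ob
girl,5,7,16.00,18.00
girl,7,12,16.53,18.71
boy,5,7,16.25,18.25
boy,7,12,16.78,18.96
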