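stratum,q12,q21,q23,q32
all,0.086,0.341,0.257,0.209
girls,0.066,0.379,0.295,0.290
boys,0.111,0.317,0.235,0.172
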