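# Connection probabilities of the cortical microcircuit, rows = target
# population, columns = source population (last column: thalamic input).
# Transcribed from the original microcircuit model publication (Potjans &
# Diesmann 2014, Table 5). Editable config; not a test target.
target,l23e,l23i,l4e,l4i,l5e,l5i,l6e,l6i,lth
l23e,0.101,0.169,0.044,0.082,0.032,0.0,0.008,0.0,0.0
l23i,0.135,0.137,0.032,0.052,0.075,0.0,0.004,0.0,0.0
l4e,0.008,0.006,0.050,0.135,0.007,0.0003,0.045,0.0,0.0983
l4i,0.069,0.003,0.079,0.160,0.003,0.0,0.106,0.0,0.0619
l5e,0.100,0.062,0.051,0.006,0.083,0.373,0.020,0.0,0.0
l5i,0.055,0.027,0.026,0.002,0.060,0.316,0.009,0.0,0.0
l6e,0.016,0.007,0.021,0.017,0.057,0.020,0.040,0.225,0.0512
l6i,0.036,0.001,0.003,0.001,0.028,0.008,0.066,0.144,0.0196
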