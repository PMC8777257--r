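# Cortical-microcircuit population table. Numeric values transcribed from
# the original microcircuit model publication (Potjans & Diesmann 2014,
# Cereb Cortex 24:785-806, Table 5): full population sizes for 1 mm^3 of
# cortical tissue and external-input indegrees. Editable config; not a
# test target.
name,layer,type,size,k_ext
l23e,23,excitatory,20683,1600
l23i,23,inhibitory,5834,1500
l4e,4,excitatory,21915,2100
l4i,4,inhibitory,5479,1900
l5e,5,excitatory,4850,2000
l5i,5,inhibitory,1065,1900
l6e,6,excitatory,14395,2900
l6i,6,inhibitory,2948,2100
lth,th,thalamic,902,0
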