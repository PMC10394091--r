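parameter,reported_coefficient
k1,-0.01920601
k2,-0.04182639
k3,-0.02508897
k4,-0.01293607
k5,0.04312616
k6,0
k7,0
k8,0
k9,0
k10,-0.01293607
k11,0
k12,0
k13,-0.04312616
k14,0
alpha,0
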