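metabolite_id	coef	role
glc__D[p]	10	C
o2[c]	NA	NA
nh4[p]	NA	N
pi[c]	NA	P
so4[p]	NA	S
fe3[p]	NA	NA
h2o[c]	NA	NA
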