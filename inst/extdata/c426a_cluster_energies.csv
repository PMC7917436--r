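cluster,label,population_pct,exc_eV,emi_eV,ss_cm1
CRY,,,3.17,2.78,3154
C2,OUT,5,3.27,2.88,3203
C5,OUT,17,3.23,2.84,3145
C7,IN,78,3.22,2.82,3192
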