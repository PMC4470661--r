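subject,mean_pabak,sd_pabak
1,0.83,0.06
2,0.90,0.02
3,0.79,0.06
4,0.85,0.08
5,0.81,0.04
6,0.83,0.03
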