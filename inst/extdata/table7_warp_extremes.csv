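river,pc1_max,pc1_min,pc2_max,pc2_min,psr_pc1,psr_pc2
Son,3.09,2.70,1.53,1.64,1.14,0.93
Tons,3.34,3.82,1.37,1.54,0.87,0.89
Ken,5.42,1.96,1.42,1.52,2.77,0.93
Brahmaputra,3.54,1.27,1.50,1.32,2.79,1.14
Ganga,2.32,1.28,1.15,1.28,1.81,0.90
Gomti,3.02,1.06,1.56,1.40,2.85,1.11
Gandak,4.50,1.03,1.27,1.18,4.37,1.08
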