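kinase,plus1,K_M_uM,K_M_se,k_cat_min,k_cat_se,n
Ime2,R,2.2,0.3,10.8,0.4,4
Ime2,P,44.5,12.2,3.3,0.3,4
LF4,R,1.2,0.4,5.8,0.5,3
LF4,P,2.7,0.6,7.8,0.5,3
MOK,R,41.9,10.8,5.9,0.5,4
MOK,P,37,2.7,11.7,0.3,4
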