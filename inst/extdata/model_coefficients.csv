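# Published coefficients of the six adsorption-energy models.
# basis: split43 = trained on a 43-compound training set (descriptors
#   ATSC1m, AATSC0v, MATS1m, BCUTw-1h); full54 = trained on all 54 compounds
#   (descriptors AATS1m, AATS7p, ATSC0p, AATSC1p).
# term "(Intercept)" is the constant; responses are E_ad in kcal/mol.
polymer,basis,term,coefficient
PE,split43,(Intercept),9.879
PE,split43,ATSC1m,-0.039
PE,split43,AATSC0v,-0.212
PE,split43,MATS1m,-21.91
PE,split43,BCUTw-1h,-0.638
POM,split43,(Intercept),10.889
POM,split43,ATSC1m,-0.04
POM,split43,AATSC0v,-0.217
POM,split43,MATS1m,-3.728
POM,split43,BCUTw-1h,-0.482
PVA,split43,(Intercept),10.709
PVA,split43,ATSC1m,-0.047
PVA,split43,AATSC0v,-0.157
PVA,split43,MATS1m,-6.006
PVA,split43,BCUTw-1h,-0.661
PE,full54,(Intercept),11.520
PE,full54,AATS1m,-0.090
PE,full54,AATS7p,6.934
PE,full54,ATSC0p,-4.129
PE,full54,AATSC1p,28.365
POM,full54,(Intercept),9.285
POM,full54,AATS1m,-0.068
POM,full54,AATS7p,6.050
POM,full54,ATSC0p,-3.229
POM,full54,AATSC1p,31.582
PVA,full54,(Intercept),14.772
PVA,full54,AATS1m,-0.097
PVA,full54,AATS7p,6.944
PVA,full54,ATSC0p,-3.987
PVA,full54,AATSC1p,36.499
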