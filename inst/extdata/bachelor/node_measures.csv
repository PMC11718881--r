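id,s_assoc,wd_assoc,s_affil,wd_affil,di,cluster
Bulat,0.707,2.060,1.453,2.213,1.178,1
Lepet,0.333,1.412,0.229,0.742,11.964,2
Losk,0.787,1.983,2.203,3.213,-0.333,2
Lovelas,0.665,0.815,0.046,0.214,-6.540,3
Palats,0.804,2.196,2.035,1.784,-2.792,2
Parus,0.730,2.092,1.209,0.567,2.031,1
Vernij,0.665,0.815,0.046,0.000,-5.883,3
Vitjaz,0.700,1.870,1.117,1.754,1.167,1
Zakat,0.476,1.691,2.555,0.857,-0.792,2
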