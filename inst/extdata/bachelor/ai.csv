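id,Bulat,Lepet,Losk,Lovelas,Palats,Parus,Vernij,Vitjaz,Zakat
Bulat,0,0.012,0.005,0,0.002,0.325,0,0.305,0.057
Lepet,0.012,0,0.107,0,0.082,0.012,0,0.012,0.107
Losk,0.005,0.107,0,0,0.529,0.007,0,0,0.139
Lovelas,0,0,0,0,0,0,0.665,0,0
Palats,0.002,0.082,0.529,0,0,0.015,0,0.02,0.156
Parus,0.325,0.012,0.007,0,0.015,0,0,0.357,0.012
Vernij,0,0,0,0.665,0,0,0,0,0
Vitjaz,0.305,0.012,0,0,0.02,0.357,0,0,0.005
Zakat,0.057,0.107,0.139,0,0.156,0.012,0,0.005,0
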