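id,Bulat,Lepet,Losk,Lovelas,Palats,Parus,Vernij,Vitjaz,Zakat
Bulat,0,0,0.031,0,0.092,0.415,0,0.062,0.385
Lepet,0,0,0.015,0,0.062,0,0,0,0.108
Losk,0.031,0.015,0,0,0.923,0.031,0,0,1.077
Lovelas,0,0,0,0,0,0,0.046,0,0
Palats,0.031,0.031,0.015,0,0,0,0,0,0.723
Parus,0.046,0,0,0,0,0,0,0.031,0.031
Vernij,0,0,0,0,0,0,0,0,0
Vitjaz,0.354,0,0,0,0.015,0.662,0,0,0
Zakat,0.015,0,0.077,0,0.154,0,0,0,0
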