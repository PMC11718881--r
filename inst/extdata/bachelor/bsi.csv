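id,Bulat,Lepet,Losk,Lovelas,Palats,Parus,Vernij,Vitjaz,Zakat
Bulat,0,0.43,0.391,0.205,0.406,0.607,0.204,0.579,0.39
Lepet,0.43,0,0.485,0.197,0.499,0.404,0.196,0.403,0.445
Losk,0.391,0.485,0,0.213,0.709,0.406,0.208,0.336,0.553
Lovelas,0.205,0.197,0.213,0,0.215,0.219,0.881,0.176,0.174
Palats,0.406,0.499,0.709,0.215,0,0.465,0.212,0.373,0.549
Parus,0.607,0.404,0.406,0.219,0.465,0,0.23,0.596,0.397
Vernij,0.204,0.196,0.208,0.881,0.212,0.23,0,0.186,0.169
Vitjaz,0.579,0.403,0.336,0.176,0.373,0.596,0.186,0,0.349
Zakat,0.39,0.445,0.553,0.174,0.549,0.397,0.169,0.349,0
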