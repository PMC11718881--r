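id,sire,dam,studbook_id,birth_date
Los,,,1447,
Lar,,,1608,
Zambar,,,3714,
Volokh,,,1231,
Vyshnya,,,2765,
Vesna,,,1577,
Parussa,,,1864,
Bulka,,,1382,
Vesta,,,2516,
Vira,,,601,
Vetka,,,490,
Zakat,Zambar,Vyshnya,5401,2009-05-25
Lepet,Los,Vesna,3756,2002-05-25
Palats,Los,Parussa,3502,2001-04-21
Bulat,Lar,Bulka,3099,2001-04-21
Lovelas,Los,Vesta,3521,2001-05-12
Vernij,Los,Vesta,3093,1997-06-06
Vitjaz,Lar,Vira,2906,1996-05-03
Losk,Lar,Vetka,2935,1996-05-27
Parus,Volokh,Parussa,2665,1994-05-11
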