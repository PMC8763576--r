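"protein_change","cdna_change","event_type","effect","phenotype","fxi_c","fxi_ag","allele_frequency","n_patients","aggregate","count"
"Val38Ala",,"point","missense","type_I",,,,1,FALSE,1
"Pro41Leu",,"point","missense","type_I",,,,1,FALSE,1
"Cys46Phe",,"point","missense","type_I",,,,1,FALSE,1
"Thr51Ala",,"point","missense","type_I",,,,1,FALSE,1
"Thr51Ile",,"point","missense","type_I",,,,1,FALSE,1
"Cys56Trp",,"point","missense","type_I",,,,1,FALSE,1
"Cys76Tyr",,"point","missense","type_I",,,,1,FALSE,1
"Gly97Arg",,"point","missense","type_I",,,,1,FALSE,1
"Gly97Glu",,"point","missense","type_I",,,,1,FALSE,1
"Cys110Gly",,"point","missense","type_I",,,,1,FALSE,1
"Cys140Tyr",,"point","missense","type_I",,,,1,FALSE,1
"Trp246Cys",,"point","missense","type_I",,,,1,FALSE,1
"Cys255Tyr",,"point","missense","type_I",,,,1,FALSE,1
"Arg326Cys",,"point","missense","type_I",,,,1,FALSE,1
"Gly368Ser",,"point","missense","type_I",,,,1,FALSE,1
"Cys416Tyr",,"point","missense","type_I",,,,1,FALSE,1
"Trp425Cys",,"point","missense","type_I",,,,1,FALSE,1
"Arg443Cys",,"point","missense","type_I",,,,1,FALSE,1
"Tyr445Cys",,"point","missense","type_I",,,,1,FALSE,1
"Trp515Cys",,"point","missense","type_I",,,,1,FALSE,1
"Trp519Cys",,"point","missense","type_I",,,,1,FALSE,1
"Cys545Tyr",,"point","missense","type_I",,,,1,FALSE,1
"Gly596Cys",,"point","missense","type_I",,,,1,FALSE,1
"Cys56Arg","c.166T>C","point","missense","type_I",25,30,,36,FALSE,1
"Gly368Val",,"point","missense","type_II",30,80,,1,FALSE,1
"Arg396Cys",,"point","missense","type_II",20,95,,1,FALSE,1
"Thr51Pro",,"point","missense","unknown",,,,1,FALSE,1
"Cys76Arg",,"point","missense","unknown",,,,1,FALSE,1
"Cys76Phe",,"point","missense","unknown",,,,1,FALSE,1
"Gly97Val",,"point","missense","unknown",,,,1,FALSE,1
"Cys136Arg",,"point","missense","unknown",,,,1,FALSE,1
"Tyr151Cys",,"point","missense","unknown",,,,1,FALSE,1
"Arg162Cys",,"point","missense","unknown",,,,1,FALSE,1
"Cys200Ser",,"point","missense","unknown",,,,1,FALSE,1
"Cys200Tyr",,"point","missense","unknown",,,,1,FALSE,1
"Cys230Arg",,"point","missense","unknown",,,,1,FALSE,1
"Cys230Ser",,"point","missense","unknown",,,,1,FALSE,1
"Arg268Cys",,"point","missense","unknown",,,,1,FALSE,1
"Cys374Arg",,"point","missense","unknown",,,,1,FALSE,1
"Cys500Arg",,"point","missense","unknown",,,,1,FALSE,1
"Cys500Trp",,"point","missense","unknown",,,,1,FALSE,1
"Tyr521Cys",,"point","missense","unknown",,,,1,FALSE,1
"Cys581Arg",,"point","missense","unknown",,,,1,FALSE,1
"Cys581Phe",,"point","missense","unknown",,,,1,FALSE,1
"Cys599Tyr",,"point","missense","unknown",,,,1,FALSE,1
"Phe301Leu","c.901T>C","point","missense","unknown",,,,22,FALSE,1
"Glu135*","c.403G>T","point","nonsense","type_I",,,,61,FALSE,1
"Cys136*",,"point","nonsense","type_I",,,,1,FALSE,1
"Cys146*",,"point","nonsense","type_I",,,,22,FALSE,1
"Cys327*",,"point","nonsense","type_I",,,,1,FALSE,1
"Cys599*",,"point","nonsense","type_II",,,,1,FALSE,1
"Cys56*",,"point","nonsense","unknown",,,,1,FALSE,1
"Gln106*",,"point","nonsense","unknown",,,,1,FALSE,1
"Gln281*",,"point","nonsense","unknown",,,,22,FALSE,1
"Ala100Ala",,"point","silent","unknown",,,,1,FALSE,1
"Val64Val",,"point","silent","unknown",,,,1,FALSE,1
,"31.5kb_del","deletion","undefined","unknown",,,,1,FALSE,1
"Ile308Phe",,"polymorphism","missense","polymorphism",,,0.02,1,FALSE,1
"Ile308Thr",,"polymorphism","missense","polymorphism",,,0.03,1,FALSE,1
"Cys339Phe",,"polymorphism","missense","polymorphism",,,0.012,1,FALSE,1
,,"point","missense","type_I",,,1e-04,30,TRUE,30
,,"point","missense","type_I",,,,24,TRUE,24
,,"point","missense","type_II",,,,9,TRUE,9
,,"point","missense","unknown",,,0.005,4,TRUE,4
,,"point","missense","unknown",,,1e-04,30,TRUE,30
,,"point","missense","unknown",,,,11,TRUE,11
,,"point","nonsense","type_I",,,,6,TRUE,6
,,"point","nonsense","unknown",,,1e-04,10,TRUE,10
,,"point","nonsense","unknown",,,,3,TRUE,3
,,"point","undefined","unknown",,,,17,TRUE,17
,,"deletion","undefined","type_I",,,,8,TRUE,8
,,"deletion","undefined","unknown",,,1e-04,10,TRUE,10
,,"insertion","undefined","unknown",,,,4,TRUE,4
,,"duplication","undefined","unknown",,,,4,TRUE,4
,,"polymorphism","missense","polymorphism",,,0.05,5,TRUE,5
,,"polymorphism","undefined","polymorphism",,,0.02,1,TRUE,1
,,"polymorphism","undefined","polymorphism",,,1e-04,24,TRUE,24
,,"polymorphism","undefined","polymorphism",,,,12,TRUE,12
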