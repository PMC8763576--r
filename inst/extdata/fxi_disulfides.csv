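"kind","cys1","cys2"
"bridge",20,103
"bridge",46,76
"bridge",50,56
"bridge",110,193
"bridge",136,165
"bridge",140,146
"bridge",200,283
"bridge",226,255
"bridge",230,236
"bridge",291,374
"bridge",317,346
"bridge",321,327
"bridge",380,500
"bridge",416,432
"bridge",514,581
"bridge",545,560
"bridge",571,599
"interchain",339,339
"free",29,
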