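cpg_id,weight,gene
cg90000001,0.002,SYN1
cg90000002,-0.001,SYN2
cg90000003,0.001,SYN3
cg90000004,0.003,SYN4
cg90000005,-0.002,SYN5
cg90000006,0.001,SYN6
cg90000007,0.001,SYN7
cg90000008,-0.001,SYN8
cg90000009,0.002,SYN9
cg90000010,0.001,SYN10
cg90000011,-0.003,SYN11
cg90000012,0.001,SYN12
cg90000013,0.002,SYN13
cg90000014,0.001,SYN14
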