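cpg_id,weight,gene
cg91000001,0.001,SYNN1
cg91000002,-0.002,SYNN2
cg91000003,0.001,SYNN3
cg91000004,0.002,SYNN4
cg91000005,-0.001,SYNN5
cg91000006,0.001,SYNN6
cg91000007,-0.001,SYNN7
cg91000008,0.002,SYNN8
cg91000009,0.001,SYNN9
cg91000010,-0.001,SYNN10
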