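kinase_domain,n
Front pocket,31
DFG-3,14
P-loop,9
Remote-Cys,2
Beta4-4,1
Catalytic-3,1
Hinge,2
Extended front pocket,1
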