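reaction_type,warhead_class,n
Nucleophilic Addition by Cys,Nitrile(cys),42
Nucleophilic Addition by Cys,Alkene(cys),117
Nucleophilic Addition by Cys,Carbonyl(cys),25
Nucleophilic Addition by Cys,Alkyne,1
Nucleophilic Addition by Cys,Guanyl,2
Nucleophilic Substitution (cys),Halide,15
Nucleophilic Substitution (cys),Others,16
Ring Opening by Cys,Heterocyclic,17
Disulfide Formation,Sulfydryl,10
Nucleophilic Addition by Ser,Nitrile(ser),3
Nucleophilic Addition by Ser,Carbonyl(ser),29
Nucleophilic Addition by Ser,Boronic acid,8
Nucleophilic Substitution by Ser,Phosphonyl,3
Ring Opening by Ser,Lactam,40
Ring Opening by Ser,Lactone,2
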