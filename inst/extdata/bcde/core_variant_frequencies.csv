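reaction_class,reaction_type,warhead_class,core_variant,n
Nucleophilic Addition,Nucleophilic Addition by Cys,Nitrile(cys),1,42
Nucleophilic Addition,Nucleophilic Addition by Cys,Alkene(cys),1,84
Nucleophilic Addition,Nucleophilic Addition by Cys,Alkene(cys),2,18
Nucleophilic Addition,Nucleophilic Addition by Cys,Alkene(cys),3,15
Nucleophilic Addition,Nucleophilic Addition by Cys,Carbonyl(cys),1,13
Nucleophilic Addition,Nucleophilic Addition by Cys,Carbonyl(cys),2,9
Nucleophilic Addition,Nucleophilic Addition by Cys,Carbonyl(cys),3,3
Nucleophilic Addition,Nucleophilic Addition by Cys,Alkyne,1,1
Nucleophilic Addition,Nucleophilic Addition by Cys,Guanyl,1,2
Nucleophilic Addition,Nucleophilic Addition by Ser,Nitrile(ser),1,3
Nucleophilic Addition,Nucleophilic Addition by Ser,Carbonyl(ser),1,3
Nucleophilic Addition,Nucleophilic Addition by Ser,Carbonyl(ser),2,26
Nucleophilic Addition,Nucleophilic Addition by Ser,Boronic acid,1,8
Nucleophilic Substitution,Nucleophilic Substitution (cys),Halide,1,13
Nucleophilic Substitution,Nucleophilic Substitution (cys),Halide,2,2
Nucleophilic Substitution,Nucleophilic Substitution (cys),Others,1,13
Nucleophilic Substitution,Nucleophilic Substitution (cys),Others,2,3
Nucleophilic Substitution,Nucleophilic Substitution by Ser,Phosphonyl,1,3
Ring Opening,Ring Opening by Cys,Heterocyclic,1,11
Ring Opening,Ring Opening by Cys,Heterocyclic,2,6
Ring Opening,Ring Opening by Ser,Lactam,1,39
Ring Opening,Ring Opening by Ser,Lactam,2,1
Ring Opening,Ring Opening by Ser,Lactone,1,2
Disulfide Formation,Disulfide Formation,Sulfydryl,1,10
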