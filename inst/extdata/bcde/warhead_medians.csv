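reaction_type,warhead,n,tool,measurement,median_rmsd
Nucleophilic Addition by Cys,Nitrile,42,MOE,best_scored,2.26
Nucleophilic Addition by Cys,Nitrile,42,GOLD,best_scored,1.1
Nucleophilic Addition by Cys,Nitrile,42,CovDock,best_scored,1.27
Nucleophilic Addition by Cys,Nitrile,42,ICM-Pro,best_scored,3.74
Nucleophilic Addition by Cys,Nitrile,42,MOE,best_sampled,1.6
Nucleophilic Addition by Cys,Nitrile,42,GOLD,best_sampled,0.91
Nucleophilic Addition by Cys,Nitrile,42,CovDock,best_sampled,1.24
Nucleophilic Addition by Cys,Nitrile,42,ICM-Pro,best_sampled,1.56
Nucleophilic Addition by Cys,Alkene,117,MOE,best_scored,1.99
Nucleophilic Addition by Cys,Alkene,117,GOLD,best_scored,2.47
Nucleophilic Addition by Cys,Alkene,117,CovDock,best_scored,1.47
Nucleophilic Addition by Cys,Alkene,117,ICM-Pro,best_scored,1.68
Nucleophilic Addition by Cys,Alkene,117,MOE,best_sampled,1.4
Nucleophilic Addition by Cys,Alkene,117,GOLD,best_sampled,1.59
Nucleophilic Addition by Cys,Alkene,117,CovDock,best_sampled,1.18
Nucleophilic Addition by Cys,Alkene,117,ICM-Pro,best_sampled,1.41
Nucleophilic Addition by Cys,Carbonyl,25,MOE,best_scored,2.27
Nucleophilic Addition by Cys,Carbonyl,25,GOLD,best_scored,2.12
Nucleophilic Addition by Cys,Carbonyl,25,CovDock,best_scored,2.05
Nucleophilic Addition by Cys,Carbonyl,25,ICM-Pro,best_scored,3.72
Nucleophilic Addition by Cys,Carbonyl,25,MOE,best_sampled,1.5
Nucleophilic Addition by Cys,Carbonyl,25,GOLD,best_sampled,1.77
Nucleophilic Addition by Cys,Carbonyl,25,CovDock,best_sampled,1.33
Nucleophilic Addition by Cys,Carbonyl,25,ICM-Pro,best_sampled,1.52
Nucleophilic Addition by Cys,Alkyne,1,MOE,best_scored,2.01
Nucleophilic Addition by Cys,Alkyne,1,GOLD,best_scored,0.67
Nucleophilic Addition by Cys,Alkyne,1,CovDock,best_scored,0.42
Nucleophilic Addition by Cys,Alkyne,1,ICM-Pro,best_scored,0.39
Nucleophilic Addition by Cys,Alkyne,1,MOE,best_sampled,1.9
Nucleophilic Addition by Cys,Alkyne,1,GOLD,best_sampled,0.67
Nucleophilic Addition by Cys,Alkyne,1,CovDock,best_sampled,0.35
Nucleophilic Addition by Cys,Alkyne,1,ICM-Pro,best_sampled,0.39
Nucleophilic Addition by Cys,Guanyl,2,MOE,best_scored,1.78
Nucleophilic Addition by Cys,Guanyl,2,GOLD,best_scored,1.46
Nucleophilic Addition by Cys,Guanyl,2,CovDock,best_scored,0.81
Nucleophilic Addition by Cys,Guanyl,2,ICM-Pro,best_scored,1.37
Nucleophilic Addition by Cys,Guanyl,2,MOE,best_sampled,1.4
Nucleophilic Addition by Cys,Guanyl,2,GOLD,best_sampled,0.98
Nucleophilic Addition by Cys,Guanyl,2,CovDock,best_sampled,0.81
Nucleophilic Addition by Cys,Guanyl,2,ICM-Pro,best_sampled,1.37
Nucleophilic Substitution (cys),Halide,15,MOE,best_scored,1.67
Nucleophilic Substitution (cys),Halide,15,GOLD,best_scored,2.31
Nucleophilic Substitution (cys),Halide,15,CovDock,best_scored,4.37
Nucleophilic Substitution (cys),Halide,15,ICM-Pro,best_scored,1.06
Nucleophilic Substitution (cys),Halide,15,MOE,best_sampled,1.3
Nucleophilic Substitution (cys),Halide,15,GOLD,best_sampled,2.17
Nucleophilic Substitution (cys),Halide,15,CovDock,best_sampled,4.37
Nucleophilic Substitution (cys),Halide,15,ICM-Pro,best_sampled,0.88
Nucleophilic Substitution (cys),Others,16,MOE,best_scored,2.1
Nucleophilic Substitution (cys),Others,16,GOLD,best_scored,2.19
Nucleophilic Substitution (cys),Others,16,CovDock,best_scored,2.12
Nucleophilic Substitution (cys),Others,16,ICM-Pro,best_scored,2.09
Nucleophilic Substitution (cys),Others,16,MOE,best_sampled,1.6
Nucleophilic Substitution (cys),Others,16,GOLD,best_sampled,1.47
Nucleophilic Substitution (cys),Others,16,CovDock,best_sampled,1.3
Nucleophilic Substitution (cys),Others,16,ICM-Pro,best_sampled,1.77
Ring Opening by Cys,Heterocyclic,17,MOE,best_scored,1.71
Ring Opening by Cys,Heterocyclic,17,GOLD,best_scored,1.74
Ring Opening by Cys,Heterocyclic,17,CovDock,best_scored,1.87
Ring Opening by Cys,Heterocyclic,17,ICM-Pro,best_scored,4.88
Ring Opening by Cys,Heterocyclic,17,MOE,best_sampled,1.4
Ring Opening by Cys,Heterocyclic,17,GOLD,best_sampled,1.48
Ring Opening by Cys,Heterocyclic,17,CovDock,best_sampled,1.33
Ring Opening by Cys,Heterocyclic,17,ICM-Pro,best_sampled,4.72
Disulfide Formation,Sulfydryl,10,MOE,best_scored,1.94
Disulfide Formation,Sulfydryl,10,GOLD,best_scored,2.94
Disulfide Formation,Sulfydryl,10,CovDock,best_scored,2.52
Disulfide Formation,Sulfydryl,10,ICM-Pro,best_scored,2.92
Disulfide Formation,Sulfydryl,10,MOE,best_sampled,1.3
Disulfide Formation,Sulfydryl,10,GOLD,best_sampled,2.47
Disulfide Formation,Sulfydryl,10,CovDock,best_sampled,2.52
Disulfide Formation,Sulfydryl,10,ICM-Pro,best_sampled,1.95
Nucleophilic Addition by Ser,Nitrile,3,MOE,best_scored,1.38
Nucleophilic Addition by Ser,Nitrile,3,GOLD,best_scored,2.54
Nucleophilic Addition by Ser,Nitrile,3,CovDock,best_scored,0.73
Nucleophilic Addition by Ser,Nitrile,3,ICM-Pro,best_scored,2.66
Nucleophilic Addition by Ser,Nitrile,3,MOE,best_sampled,1.3
Nucleophilic Addition by Ser,Nitrile,3,GOLD,best_sampled,1.77
Nucleophilic Addition by Ser,Nitrile,3,CovDock,best_sampled,0.52
Nucleophilic Addition by Ser,Nitrile,3,ICM-Pro,best_sampled,2.66
Nucleophilic Addition by Ser,Carbonyl,29,MOE,best_scored,1.61
Nucleophilic Addition by Ser,Carbonyl,29,GOLD,best_scored,3.54
Nucleophilic Addition by Ser,Carbonyl,29,CovDock,best_scored,3.1
Nucleophilic Addition by Ser,Carbonyl,29,ICM-Pro,best_scored,2.03
Nucleophilic Addition by Ser,Carbonyl,29,MOE,best_sampled,1.3
Nucleophilic Addition by Ser,Carbonyl,29,GOLD,best_sampled,1.58
Nucleophilic Addition by Ser,Carbonyl,29,CovDock,best_sampled,1.4
Nucleophilic Addition by Ser,Carbonyl,29,ICM-Pro,best_sampled,1.36
Nucleophilic Addition by Ser,Boronic Acid,8,MOE,best_scored,1.94
Nucleophilic Addition by Ser,Boronic Acid,8,GOLD,best_scored,2.57
Nucleophilic Addition by Ser,Boronic Acid,8,CovDock,best_scored,2.94
Nucleophilic Addition by Ser,Boronic Acid,8,ICM-Pro,best_scored,2.44
Nucleophilic Addition by Ser,Boronic Acid,8,MOE,best_sampled,1.5
Nucleophilic Addition by Ser,Boronic Acid,8,GOLD,best_sampled,1.88
Nucleophilic Addition by Ser,Boronic Acid,8,CovDock,best_sampled,2.74
Nucleophilic Addition by Ser,Boronic Acid,8,ICM-Pro,best_sampled,2.44
Nucleophilic Substitution by Ser,Phosphonyl,3,MOE,best_scored,2.32
Nucleophilic Substitution by Ser,Phosphonyl,3,GOLD,best_scored,2.33
Nucleophilic Substitution by Ser,Phosphonyl,3,CovDock,best_scored,5.81
Nucleophilic Substitution by Ser,Phosphonyl,3,ICM-Pro,best_scored,1.68
Nucleophilic Substitution by Ser,Phosphonyl,3,MOE,best_sampled,1.5
Nucleophilic Substitution by Ser,Phosphonyl,3,GOLD,best_sampled,2.08
Nucleophilic Substitution by Ser,Phosphonyl,3,CovDock,best_sampled,3.25
Nucleophilic Substitution by Ser,Phosphonyl,3,ICM-Pro,best_sampled,1.68
Ring Opening by Ser,Lactam,40,MOE,best_scored,1.73
Ring Opening by Ser,Lactam,40,GOLD,best_scored,2.95
Ring Opening by Ser,Lactam,40,CovDock,best_scored,1.7
Ring Opening by Ser,Lactam,40,ICM-Pro,best_scored,2.53
Ring Opening by Ser,Lactam,40,MOE,best_sampled,1.5
Ring Opening by Ser,Lactam,40,GOLD,best_sampled,1.62
Ring Opening by Ser,Lactam,40,CovDock,best_sampled,1.7
Ring Opening by Ser,Lactam,40,ICM-Pro,best_sampled,1.48
Ring Opening by Ser,Lactone,2,MOE,best_scored,2.09
Ring Opening by Ser,Lactone,2,GOLD,best_scored,2.56
Ring Opening by Ser,Lactone,2,CovDock,best_scored,2.52
Ring Opening by Ser,Lactone,2,ICM-Pro,best_scored,5.66
Ring Opening by Ser,Lactone,2,MOE,best_sampled,1.5
Ring Opening by Ser,Lactone,2,GOLD,best_sampled,1.6
Ring Opening by Ser,Lactone,2,CovDock,best_sampled,1.6
Ring Opening by Ser,Lactone,2,ICM-Pro,best_sampled,4.98
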