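receptor_type,n,tool,measurement,median_rmsd
Hydrolase,204,MOE,best_scored,2.07
Hydrolase,204,GOLD,best_scored,2.33
Hydrolase,204,CovDock,best_scored,1.71
Hydrolase,204,ICM-Pro,best_scored,2.76
Hydrolase,204,MOE,best_sampled,1.54
Hydrolase,204,GOLD,best_sampled,1.51
Hydrolase,204,CovDock,best_sampled,1.39
Hydrolase,204,ICM-Pro,best_sampled,1.61
Transferase,83,MOE,best_scored,1.8
Transferase,83,GOLD,best_scored,2.24
Transferase,83,CovDock,best_scored,1.3
Transferase,83,ICM-Pro,best_scored,1.34
Transferase,83,MOE,best_sampled,1.34
Transferase,83,GOLD,best_sampled,1.46
Transferase,83,CovDock,best_sampled,1.06
Transferase,83,ICM-Pro,best_sampled,1.24
Ligase,3,MOE,best_scored,2.9
Ligase,3,GOLD,best_scored,2.63
Ligase,3,CovDock,best_scored,1.08
Ligase,3,ICM-Pro,best_scored,1.41
Ligase,3,MOE,best_sampled,1.25
Ligase,3,GOLD,best_sampled,1.04
Ligase,3,CovDock,best_sampled,0.84
Ligase,3,ICM-Pro,best_sampled,1.41
Lyase,1,MOE,best_scored,0.96
Lyase,1,GOLD,best_scored,1.23
Lyase,1,CovDock,best_scored,1.24
Lyase,1,ICM-Pro,best_scored,1.34
Lyase,1,MOE,best_sampled,0.9
Lyase,1,GOLD,best_sampled,1.17
Lyase,1,CovDock,best_sampled,1.19
Lyase,1,ICM-Pro,best_sampled,1.34
Oxidoreductase,6,MOE,best_scored,1.7
Oxidoreductase,6,GOLD,best_scored,1.44
Oxidoreductase,6,CovDock,best_scored,2.37
Oxidoreductase,6,ICM-Pro,best_scored,1.13
Oxidoreductase,6,MOE,best_sampled,1.18
Oxidoreductase,6,GOLD,best_sampled,1.06
Oxidoreductase,6,CovDock,best_sampled,2.37
Oxidoreductase,6,ICM-Pro,best_sampled,1.13
Isomerase,6,MOE,best_scored,1.49
Isomerase,6,GOLD,best_scored,1.2
Isomerase,6,CovDock,best_scored,1.02
Isomerase,6,ICM-Pro,best_scored,2.25
Isomerase,6,MOE,best_sampled,1.33
Isomerase,6,GOLD,best_sampled,0.78
Isomerase,6,CovDock,best_sampled,1.01
Isomerase,6,ICM-Pro,best_sampled,2.25
Transcription,18,MOE,best_scored,2.38
Transcription,18,GOLD,best_scored,6.15
Transcription,18,CovDock,best_scored,2.15
Transcription,18,ICM-Pro,best_scored,3.42
Transcription,18,MOE,best_sampled,1.6
Transcription,18,GOLD,best_sampled,3.03
Transcription,18,CovDock,best_sampled,1.71
Transcription,18,ICM-Pro,best_sampled,2.1
Viral Protein,4,MOE,best_scored,3.91
Viral Protein,4,GOLD,best_scored,0.81
Viral Protein,4,CovDock,best_scored,4.29
Viral Protein,4,ICM-Pro,best_scored,4.93
Viral Protein,4,MOE,best_sampled,2.97
Viral Protein,4,GOLD,best_sampled,0.81
Viral Protein,4,CovDock,best_sampled,1.3
Viral Protein,4,ICM-Pro,best_sampled,4.93
Metal binding protein,5,MOE,best_scored,1.72
Metal binding protein,5,GOLD,best_scored,5.54
Metal binding protein,5,CovDock,best_scored,5.43
Metal binding protein,5,ICM-Pro,best_scored,2.37
Metal binding protein,5,MOE,best_sampled,1.04
Metal binding protein,5,GOLD,best_sampled,4.54
Metal binding protein,5,CovDock,best_sampled,3
Metal binding protein,5,ICM-Pro,best_sampled,1.67
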