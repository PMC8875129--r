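group,compound,modifier,c0_ug_per_ml,papp_ab_mean_1e6,papp_ab_sd_1e6,papp_ba_mean_1e6,papp_ba_sd_1e6,er_reported,er_sd_reported,panel
L-PUR,puerarin,none,50,1.225,0.600,1.766,0.090,1.442,0.073,dose-response
M-PUR,puerarin,none,100,1.285,0.332,4.539,0.166,3.531,0.129,dose-response
H-PUR,puerarin,none,200,1.137,0.391,3.017,0.787,2.654,0.693,dose-response
GAS,gastrodin,none,100,2.407,0.134,2.866,0.809,1.191,0.336,dose-response
PUR+Ver,puerarin,verapamil,100,1.413,0.381,3.004,0.724,2.126,0.513,inhibitor
PUR+Cyc,puerarin,cyclosporin,100,4.759,0.405,4.014,0.565,0.843,0.119,inhibitor
GAS+Ver,gastrodin,verapamil,100,2.647,1.000,—,—,—,—,inhibitor
GAS+Cyc,gastrodin,cyclosporin,100,2.402,0.130,—,—,—,—,inhibitor
PUR+GAS,puerarin,gastrodin,100,1.425,0.412,3.108,0.982,2.181,0.689,co-administration
GAS+PUR,gastrodin,puerarin,100,2.229,0.086,2.566,0.306,1.151,0.137,co-administration
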