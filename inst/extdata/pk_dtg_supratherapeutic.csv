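compartment,group,gestation_day,mean_concentration,sem,n
plasma,dtg_oral_50,8.5,41420,3505.30,5
plasma,dtg_oral_50,17.5,30560,5877.30,5
placenta,dtg_oral_50,17.5,14671.30,NA,5
embryo_brain,dtg_oral_50,17.5,2405.60,460.35,5
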