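group,n_litters,total_implants,total_resorptions,total_viable,n_abnormal
vehicle,5,33,2,31,0
dtg,5,34,5,29,0
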