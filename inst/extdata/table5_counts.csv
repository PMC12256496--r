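model_id,tp,fn,tn,fp,total_labelled,se_printed,sp_printed,acc_printed,ba_printed,cov_printed,source
derek_nexus_34,19,1,4,9,33,95.00,30.77,69.70,62.88,100.00,performance_table
derek_nexus_17,18,2,10,3,33,90.00,76.92,84.85,83.46,100.00,performance_table
oecd_toolbox_dart,13,5,10,3,33,72.22,76.92,74.19,74.57,93.94,performance_table
vega_devtox,15,5,9,4,33,75.00,69.23,72.73,72.12,100.00,performance_table
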