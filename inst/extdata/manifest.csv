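"file","md5"
"table1_scenarios.csv","832aaa304c21c2357024e64109482097"
"table5_counts.csv","c8f16acf851e7bc4a63d7ea80e397c06"
"table6_population_stats.csv","a6f634ac823555922730ade7fbda9ebc"
"insilico_calls.csv","80cdd0ce0d6c3759bfea53ead043c0eb"
"ipp_dart_targets_synthetic.csv","671ab6ad699be28ab082b0b24001ee77"
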