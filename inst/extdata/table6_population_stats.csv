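chemical_id,population,n_total,tkvf,fold_to_non_pregnant,p_non_pregnant,fold_to_pregnant,p_pregnant,small_n,source
VPA,non_pregnant,673,1.62,1.00,,,,FALSE,population_table
VPA,pregnant,112,1.85,0.69,0.00,1.00,,FALSE,population_table
VPA,fetus,33,1.52,0.78,0.00,1.13,0.11,FALSE,population_table
Theophylline,non_pregnant,119,1.43,1.00,,,,FALSE,population_table
Theophylline,pregnant,62,1.73,1.58,0.00,1.00,,FALSE,population_table
Theophylline,fetus,26,1.81,1.33,0.11,0.84,0.11,FALSE,population_table
Salicylate,non_pregnant,57,1.96,1.00,,,,FALSE,population_table
Salicylate,pregnant,16,2.34,0.79,0.26,,,FALSE,population_table
Salicylate,fetus,3,1.95,1.95,,,,TRUE,population_table
ATRA,non_pregnant,333,2.14,1.00,,,,FALSE,population_table
ATRA,pregnant,180,1.47,0.77,0.00,1.00,,FALSE,population_table
ATRA,fetus,10,1.06,0.55,0.00,0.71,0.00,FALSE,population_table
Retinol,non_pregnant,56,2.32,1.00,,,,FALSE,population_table
Retinol,pregnant,180,1.64,0.88,0.30,,,FALSE,population_table
Retinol,fetus,10,1.86,0.82,0.32,,,FALSE,population_table
Caffeine,non_pregnant,331,1.89,1.00,,,,FALSE,population_table
Caffeine,pregnant,264,2.42,1.13,0.05,1.00,,FALSE,population_table
Caffeine,fetus,1687,2.84,0.67,0.00,0.59,0.00,FALSE,population_table
Dolutegravir,non_pregnant,278,1.87,1.00,,,,FALSE,population_table
Dolutegravir,pregnant,101,2.64,0.70,0.00,1.00,,FALSE,population_table
Dolutegravir,fetus,22,1.40,0.46,0.00,0.65,0.00,FALSE,population_table
Paraquat,non_pregnant,67,3.16,1.00,,,,FALSE,population_table
Paraquat,pregnant,4,,0.05,,1.00,,TRUE,population_table
Paraquat,fetus,3,,0.06,,1.15,,TRUE,population_table
Digoxin,non_pregnant,211,2.32,1.00,,,,FALSE,population_table
Digoxin,pregnant,106,2.35,0.55,0.00,1.00,,FALSE,population_table
Digoxin,fetus,68,2.38,0.54,0.00,0.98,0.89,FALSE,population_table
Nitrofurantoin,non_pregnant,281,3.36,1.00,,,,FALSE,population_table
Nitrofurantoin,pregnant,125,5.73,1.29,0.40,1.00,,FALSE,population_table
Nitrofurantoin,fetus,15,2.90,2.25,0.09,1.74,0.22,FALSE,population_table
Metoclopramide,non_pregnant,37,2.85,1.00,,,,FALSE,population_table
Metoclopramide,pregnant,20,2.71,1.45,0.25,1.00,,FALSE,population_table
Metoclopramide,fetus,20,1.97,1.50,0.07,1.04,0.89,FALSE,population_table
Metformin,non_pregnant,219,3.15,1.00,,,,FALSE,population_table
Metformin,pregnant,191,2.75,0.73,0.01,1.00,,FALSE,population_table
Metformin,fetus,144,2.99,0.41,0.00,0.56,0.00,FALSE,population_table
MTX,non_pregnant,242,2.74,1.00,,,,FALSE,population_table
MTX,pregnant,20,2.65,1.11,0.68,,,FALSE,population_table
Cyclophosphamide,non_pregnant,154,3.15,1.00,,,,FALSE,population_table
Cyclophosphamide,pregnant,1,,2.85,,,,TRUE,population_table
Warfarin,non_pregnant,124,1.82,1.00,,,,FALSE,population_table
Warfarin,pregnant,21,1.93,2.35,0.00,,,FALSE,population_table
Rosiglitazone,non_pregnant,233,4.34,1.00,,,,FALSE,population_table
Rosiglitazone,pregnant,31,1.71,0.19,0.00,,,FALSE,population_table
Dexamethasone,non_pregnant,99,1.99,1.00,,,,FALSE,population_table
Dexamethasone,pregnant,83,2.51,1.50,0.00,,,FALSE,population_table
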