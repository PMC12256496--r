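chemical_id,cas_number,scenario_label,risk_truth,source
"1,2-Octanediol",1117-86-8,"Cosmetic, 5% in body lotion",low,benchmark_table
2-Amino-6-chloro-4-nitrophenol,6358-09-4,"Cosmetic, 2% in hair colourant",low,benchmark_table
2-Ethylhexanoic acid (2-EHA),149-57-5,"Dietary, 3.1 mg/daily",uncertain,benchmark_table
2-Methylresorcinol,608-25-3,"Cosmetic, 1.8% in hair colourant",low,benchmark_table
Aspartame,22839-47-0,"Dietary, 2400 mg/daily",low,benchmark_table
ATRA,302-79-4,"Pharmaceutical, 0.1% cream",uncertain,benchmark_table
ATRA,302-79-4,"Pharmaceutical, 80 mg/daily",high,benchmark_table
ATRA,302-79-4,"Dietary, <10000 IU Retinol",low,benchmark_table
BHT,128-37-0,"Cosmetic, aggregate (max 0.8%)",low,benchmark_table
BP3,131-57-7,"Cosmetic, 6% in sunscreen",low,benchmark_table
Caffeine,58-08-2,"Dietary, 100 mg/daily",low,benchmark_table
Caffeine,58-08-2,"Dietary, 400 mg/daily",high,benchmark_table
Caffeine,58-08-2,"Cosmetic, 2% in shampoo",low,benchmark_table
Chlorpyrifos,2921-88-2,"Dietary, 0.0045 mg/daily",uncertain,benchmark_table
Chlorpyrifos,2921-88-2,"Prenatal Exposure",high,benchmark_table
Cyclophosphamide,6055-19-2,"Pharmaceutical, 60 mg/daily",high,benchmark_table
Cypermethrin,52315-07-8,"Dietary, 0.3 mg/daily",low,benchmark_table
DBP,84-74-2,"Dietary, 0.6 mg/daily",low,benchmark_table
DEET,134-62-3,"Pharmaceutical, 15% in insect repellant",low,benchmark_table
DEP,84-66-2,"Cosmetic, aggregate (max 10%)",low,benchmark_table
DES,56-53-1,"Pharmaceutical, 0.5 mg/daily",high,benchmark_table
Dexamethasone,50-02-2,"Pharmaceutical, 0.75 mg/daily",high,benchmark_table
Digoxin,20830-75-5,"Pharmaceutical, 0.024 mg/daily",low,benchmark_table
Dolutegravir,1051375-16-6,"Pharmaceutical, 50 mg/daily",high,benchmark_table
Ethylzingerone,569646-79-3,"Cosmetic, aggregate (max 2%)",low,benchmark_table
Fenazaquin,120928-09-8,"Dietary, 3 mg/daily",low,benchmark_table
Glutaraldehyde,111-30-8,"Dietary, 9.6 mg/daily",low,benchmark_table
Glutaraldehyde,111-30-8,"Cosmetic, 0.1% in body lotion",low,benchmark_table
HC Red 3,2871-01-4,"Cosmetic, 3% in hair colourant",low,benchmark_table
Metformin,657-24-9,"Pharmaceutical, 2000 mg/daily",low,benchmark_table
Metoclopramide,364-62-5,"Pharmaceutical, 60 mg/daily",high,benchmark_table
Metoclopramide,364-62-5,"Pharmaceutical, 10 mg/daily",uncertain,benchmark_table
MTX,59-05-2,"Pharmaceutical, 10 mg/weekly",high,benchmark_table
Nitrofurantoin,67-20-9,"Pharmaceutical, 200 mg/daily",high,benchmark_table
Panthenol,16485-10-2,"Cosmetic, 5.3% in body lotion",low,benchmark_table
Paraquat,4685-14-7,"Dietary, 0.27 mg/daily",low,benchmark_table
Retinol,68-26-8,"Cosmetic, 0.05% in body lotion",low,benchmark_table
Retinol,68-26-8,"Dietary, <10000 IU",low,benchmark_table
Rosiglitazone,122320-73-4,"Pharmaceutical, 4 mg/daily",high,benchmark_table
Cyclamate,139-05-9,"Dietary, 420 mg/daily",low,benchmark_table
Salicylate,69-72-7,"Cosmetic, aggregate (max 3%)",low,benchmark_table
Salicylate,69-72-7,"Pharmaceutical, 162.5 mg/daily",uncertain,benchmark_table
Salicylate,69-72-7,"Pharmaceutical, 800-6000 mg/daily",high,benchmark_table
Thalidomide,50-35-1,"Pharmaceutical, 50 mg/daily",high,benchmark_table
Theophylline,58-55-9,"Pharmaceutical, 800 mg/daily",high,benchmark_table
Theophylline,58-55-9,"Dietary, 0.14 mg/daily",low,benchmark_table
VPA,99-66-1,"Pharmaceutical, 600 mg/daily",high,benchmark_table
VPA,99-66-1,"Pharmaceutical, 3600 mg/daily",high,benchmark_table
Warfarin,81-81-2,"Pharmaceutical, 5 mg/daily",high,benchmark_table
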