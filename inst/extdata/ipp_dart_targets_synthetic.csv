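"target_id","category","source"
"adenosine_A2A","dart_targeted","synthetic_annotation"
"dopamine_D2","dart_targeted","synthetic_annotation"
"NMDA_receptor","dart_targeted","synthetic_annotation"
"monoamine_oxidase_A","dart_targeted","synthetic_annotation"
"thyroid_peroxidase","dart_targeted","synthetic_annotation"
"serotonin_HTR2B","dart_targeted","synthetic_annotation"
"estrogen_receptor_alpha","dart_targeted","synthetic_annotation"
"androgen_receptor","dart_targeted","synthetic_annotation"
"glucocorticoid_receptor","dart_targeted","synthetic_annotation"
"retinoic_acid_receptor","dart_targeted","synthetic_annotation"
"target_01","dart_targeted","synthetic_annotation"
"target_02","dart_targeted","synthetic_annotation"
"target_03","dart_targeted","synthetic_annotation"
"target_04","dart_targeted","synthetic_annotation"
"target_05","dart_targeted","synthetic_annotation"
"target_06","dart_targeted","synthetic_annotation"
"target_07","dart_targeted","synthetic_annotation"
"target_08","dart_targeted","synthetic_annotation"
"target_09","dart_targeted","synthetic_annotation"
"target_10","dart_targeted","synthetic_annotation"
"target_11","dart_targeted","synthetic_annotation"
"target_12","dart_targeted","synthetic_annotation"
"target_13","dart_targeted","synthetic_annotation"
"target_14","dart_targeted","synthetic_annotation"
"target_15","dart_targeted","synthetic_annotation"
"target_16","dart_targeted","synthetic_annotation"
"target_17","dart_targeted","synthetic_annotation"
"target_18","broad","synthetic_annotation"
"target_19","dart_targeted","synthetic_annotation"
"target_20","broad","synthetic_annotation"
"target_21","dart_targeted","synthetic_annotation"
"target_22","broad","synthetic_annotation"
"target_23","dart_targeted","synthetic_annotation"
"target_24","broad","synthetic_annotation"
"target_25","dart_targeted","synthetic_annotation"
"target_26","broad","synthetic_annotation"
"target_27","dart_targeted","synthetic_annotation"
"target_28","broad","synthetic_annotation"
"target_29","dart_targeted","synthetic_annotation"
"target_30","broad","synthetic_annotation"
"target_31","dart_targeted","synthetic_annotation"
"target_32","broad","synthetic_annotation"
"target_33","dart_targeted","synthetic_annotation"
"target_34","broad","synthetic_annotation"
"target_35","dart_targeted","synthetic_annotation"
"target_36","broad","synthetic_annotation"
"target_37","dart_targeted","synthetic_annotation"
"target_38","broad","synthetic_annotation"
"target_39","dart_targeted","synthetic_annotation"
"target_40","broad","synthetic_annotation"
"target_41","dart_targeted","synthetic_annotation"
"target_42","broad","synthetic_annotation"
"target_43","dart_targeted","synthetic_annotation"
"target_44","broad","synthetic_annotation"
"target_45","dart_targeted","synthetic_annotation"
"target_46","broad","synthetic_annotation"
"target_47","dart_targeted","synthetic_annotation"
"target_48","broad","synthetic_annotation"
"target_49","dart_targeted","synthetic_annotation"
"target_50","broad","synthetic_annotation"
"target_51","dart_targeted","synthetic_annotation"
"target_52","broad","synthetic_annotation"
"target_53","dart_targeted","synthetic_annotation"
"target_54","broad","synthetic_annotation"
"target_55","dart_targeted","synthetic_annotation"
"target_56","broad","synthetic_annotation"
"target_57","dart_targeted","synthetic_annotation"
"target_58","broad","synthetic_annotation"
"target_59","dart_targeted","synthetic_annotation"
"target_60","broad","synthetic_annotation"
"target_61","dart_targeted","synthetic_annotation"
"target_62","broad","synthetic_annotation"
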