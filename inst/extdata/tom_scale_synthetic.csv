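study_id,group_id,task,n_correct,n_total
synthetic,age3,DB,47,80
synthetic,age3,KA,45,80
synthetic,age3,FB,26,80
synthetic,age4,DB,48,80
synthetic,age4,KA,39,80
synthetic,age4,FB,31,80
synthetic,age5,DB,70,80
synthetic,age5,KA,57,80
synthetic,age5,FB,56,80
synthetic,age6,DB,76,80
synthetic,age6,KA,69,80
synthetic,age6,FB,69,80
synthetic,western_preschool,DB,67,80
synthetic,western_preschool,KA,55,80
synthetic,western_preschool,FB,48,80
synthetic,eastern_preschool,DB,62,80
synthetic,eastern_preschool,KA,73,80
synthetic,eastern_preschool,FB,42,80
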