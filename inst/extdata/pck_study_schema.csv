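name,column_label,fluid,units,published_n
kidney_mass,Kidney mass (g),tissue,g,27
kidney_body_ratio,Kidney/ Body mass,derived,dimensionless ratio,27
ngal_serum,"NGAL, serum (ug/mL)",serum,ug/mL,24
ngal_urine,"NGAL, urine (ug)",urine,ug per 24 h,25
kim1_urine,"Kim-1, urine (ug)",urine,ug per 24 h,12
cystatin_c_serum,"Cystatin C, serum (ug/mL)",serum,ug/mL,25
cystatin_c_urine,"Cystatin C, urine (ug)",urine,ug per 24 h,24
il18_serum,"IL-18, serum (ug/mL)",serum,ug/mL,27
il18_urine,"IL 18, urine (ug)",urine,ug per 24 h,23
scr,SCr (mg/dL),serum,mg/dL,27
bun,BUN (mg/dL),serum,mg/dL,27
proteinuria,Proteinuria (mg),urine,mg per 24 h,24
microalbuminuria,Microalbuminuria (ug),urine,ug per 24 h,24
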