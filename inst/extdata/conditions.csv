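code,name,resolvable,cluster
anxiety,Anxiety,FALSE,A
depression,Depression,TRUE,A
heart_failure,Heart failure,FALSE,B
atrial_fibrillation,Atrial fibrillation,TRUE,B
ckd,Chronic kidney disease,TRUE,B
chd,Coronary heart disease,FALSE,B
stroke_tia,Stroke or TIA,FALSE,B
pad,Peripheral arterial disease,FALSE,B
dementia,Dementia,FALSE,B
osteoporosis,Osteoporosis,FALSE,B
osteoarthritis,Osteoarthritis,FALSE,C
cancer,Cancer,TRUE,C
chronic_pain,Chronic pain,TRUE,C
hypertension,Hypertension,TRUE,C
diabetes_t2,Type 2 diabetes,TRUE,C
liver_disease,Chronic liver disease,FALSE,D
viral_hepatitis,Viral hepatitis,FALSE,D
alcohol_dependency,Alcohol dependency,TRUE,E
substance_dependency,Substance dependency,TRUE,E
hiv,HIV,FALSE,E
asthma,Asthma,TRUE,F
copd,COPD,FALSE,F
epilepsy,Epilepsy,TRUE,F
morbid_obesity,Morbid obesity,TRUE,F
ibd,Inflammatory bowel disease,FALSE,F
rheumatoid_arthritis,Rheumatoid arthritis,FALSE,F
sickle_cell,Sickle cell disease,FALSE,F
lupus,Systemic lupus erythematosus,FALSE,F
multiple_sclerosis,Multiple sclerosis,FALSE,F
serious_mental_illness,Serious mental illness,FALSE,F
learning_disability,Learning disability,FALSE,F
diabetes_t1,Type 1 diabetes,FALSE,F
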