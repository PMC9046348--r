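item,category,sex,low,high,high_inclusive,is_flag,special,units,sample_min,sample_max
bmi,clinical,,18,25,FALSE,FALSE,,kg/m2,15,40
wbc,clinical,,4000,,FALSE,FALSE,,cells/ul,1500,11000
mchc,clinical,M,27.8,33.8,FALSE,FALSE,,g/dl,24,36
mchc,clinical,F,26.9,33.3,FALSE,FALSE,,g/dl,24,36
bun,clinical,,8,23,FALSE,FALSE,,mg/dl,3,40
creatinine,clinical,,0.6,1.2,FALSE,FALSE,,mg/dl,0.3,2.5
calcium,clinical,,9.2,10.8,FALSE,FALSE,,mg/dl,8,12
chloride,clinical,,96,106,FALSE,FALSE,,mEq/l,90,115
total_protein,clinical,,6,7.8,FALSE,FALSE,,mg,5,9
albumin,clinical,,3.5,,FALSE,FALSE,,mg,2.5,5
fibrinogen,clinical,,,3.25,FALSE,FALSE,,g/l,1.5,6
egfr,clinical,,60,,FALSE,FALSE,,ml/min,20,120
hemoglobin,clinical,M,12,,FALSE,FALSE,,umol/l,6,18
hemoglobin,clinical,F,10,,FALSE,FALSE,,umol/l,6,18
ast,clinical,,,31,FALSE,FALSE,,U/l,10,120
alt,clinical,,,31,FALSE,FALSE,,U/l,10,120
alp,clinical,,38,126,FALSE,FALSE,,U/l,20,250
potassium,clinical,,3.5,5.3,FALSE,FALSE,,mEq/l,2.8,6.5
bilirubin,clinical,,,1.1,FALSE,FALSE,,mg/dl,0.2,3
triglycerides,clinical,,,150,TRUE,FALSE,,mg/dl,50,400
cholesterol,clinical,,,200,FALSE,FALSE,,mg/dl,120,320
hdl,clinical,M,40,,FALSE,FALSE,,mg/dl,20,90
hdl,clinical,F,50,,FALSE,FALSE,,mg/dl,20,90
glucose,clinical,,,200,FALSE,FALSE,,mg/dl,60,350
weight_loss,clinical,,,,FALSE,TRUE,,boolean,0,1
platelets,clinical,,150,,FALSE,FALSE,,billion/l,40,450
hcv,comorbidity,,,,FALSE,TRUE,,boolean,0,1
diabetes,comorbidity,,,,FALSE,TRUE,,boolean,0,1
copd,comorbidity,,,,FALSE,TRUE,,boolean,0,1
malignancy,comorbidity,,,,FALSE,TRUE,,boolean,0,1
myocardial_infarction,comorbidity,,,,FALSE,TRUE,,boolean,0,1
renal_disease,comorbidity,,,,FALSE,TRUE,,boolean,0,1
hypertension,comorbidity,,,,FALSE,FALSE,bp,boolean+mmHg,0,1
hyperlipidemia,comorbidity,,,,FALSE,TRUE,,boolean,0,1
cerebrovascular_accident,comorbidity,,,,FALSE,TRUE,,boolean,0,1
sensory_neuropathy,comorbidity,,,,FALSE,TRUE,,boolean,0,1
neuropathic_pain,comorbidity,,,,FALSE,TRUE,,boolean,0,1
smoking,comorbidity,,,,FALSE,TRUE,,boolean,0,1
current_cd4,hiv,,500,,FALSE,FALSE,,cells/ul,50,1500
nadir_cd4,hiv,,200,,FALSE,FALSE,,cells/ul,0,800
hiv_rna,hiv,,,40,FALSE,FALSE,,copies/ml,0,100000
disease_duration,hiv,,,10,FALSE,FALSE,,years,0.5,30
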