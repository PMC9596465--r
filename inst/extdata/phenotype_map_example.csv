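phenotype,keyword
heart failure,heart failure
heart failure,cardiac failure
heart failure,cardiac asthma
myocardial infarction,myocardial infarction
myocardial infarction,post-myocardial
coronary artery disease,coronary arteriosclerosis
coronary artery disease,coronary heart disease
coronary artery disease,myocardial ischemia
angina,angina
hypertension,hypertension
hypertension,hypertensive
hypertension,increase in blood pressure
atrial fibrillation,atrial fibrillation
atrial fibrillation,atrial flutter
arrhythmia,arrhythmia
arrhythmia,premature ventricular
arrhythmia,premature cardiac
tachycardia,tachycardia
bradycardia,bradycardia
cardiomyopathy,cardiomyopath
valve disease,valve insufficiency
valve disease,valve stenosis
valve disease,valve disorder
valve disease,valve disease
aortic stenosis,aortic valve stenosis
aortic stenosis,aortic stenosis
aneurysm,aneurysm
stroke,stroke
stroke,cerebrovascular accident
cerebrovascular disease,cerebral atherosclerosis
cerebrovascular disease,cerebrovascular
atherosclerosis,atherosclerosis
atherosclerosis,arteriosclerosis
peripheral vascular disease,peripheral vascular
peripheral vascular disease,varicosity
pulmonary hypertension,pulmonary hypertension
pulmonary embolism,pulmonary embolism
pulmonary embolism,thromboembolism
thrombosis,thrombus
thrombosis,thrombosis
edema,edema
edema,swelling
dyspnea,dyspnea
dyspnea,shortness of breath
syncope,syncope
dizziness,dizziness
dizziness,vertigo
anemia,anemia
diabetes,diabetes
diabetes,diabetic
hyperglycemia,hyperglycemia
hyperlipidemia,hyperlipidemia
hyperlipidemia,dyslipidemia
hyperlipidemia,lipid metabolism
obesity,obesity
obesity,overweight
kidney disease,kidney disease
kidney disease,nephropathy
kidney disease,renal failure
kidney disease,nephrosclerosis
liver disease,liver disease
liver disease,hepatitis
liver disease,cirrhosis
copd,chronic obstructive pulmonary
copd,emphysema
respiratory failure,respiratory insufficiency
respiratory failure,respiratory failure
pneumonia,pneumonia
sleep apnea,apnea
thyroid disorder,thyroid
thyroid disorder,goiter
gastric disease,gastritis
gastric disease,stomach disease
gastric disease,duodenal ulcer
hernia,hernia
pain,pain
hypertrophy,hypertrophy
cardiomegaly,cardiomegaly
cardiomegaly,cardiac dilatation
pericarditis,pericarditis
myocarditis,myocarditis
endocarditis,endocarditis
congenital heart disease,congenital heart
congenital heart disease,septal defect
pregnancy,pregnancy
pregnancy,childbirth
cancer,neoplasm
cancer,carcinoma
cancer,lymphoma
autoimmune disease,lupus
autoimmune disease,rheumatoid
autoimmune disease,autoimmune
retinal disease,retinal
retinal disease,retinopathy
gout,hyperuricemia
gout,gout
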