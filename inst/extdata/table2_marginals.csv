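# Cohort descriptive frequencies, 590-patient UGIB cohort. Variables whose
# categories partition the cohort (age, symptom, medication, endoscopy_time,
# transfusion, hemostasis, mortality30) sum to 590; gender prints only the
# female row and history categories overlap.
variable,category,n,percent
gender,female,215,36.4
age,lt60,166,28.1
age,60to79,133,22.5
age,ge80,291,49.3
history,liver_disease,41,6.9
history,renal_disease,3,0.5
history,heart_disease,337,57.1
history,metastatic_malignancy,6,1.0
symptom,melena,288,48.8
symptom,hematemesis,147,24.9
symptom,hematochezia,135,22.9
symptom,syncope,20,3.4
medication,none,272,46.1
medication,antiplatelet,202,34.2
medication,anticoagulant,90,15.3
medication,nsaids,26,4.4
endoscopy_time,lt6h,233,39.5
endoscopy_time,6to24h,208,35.3
endoscopy_time,24to48h,143,24.2
endoscopy_time,after48h,4,0.7
endoscopy_time,none,2,0.3
transfusion,no,141,23.9
transfusion,yes,449,76.1
hemostasis,none,386,65.4
hemostasis,endoscopic,191,32.4
hemostasis,radiologic,13,2.2
hemostasis,surgery,0,0.0
mortality30,survival,565,95.8
mortality30,death,25,4.2
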