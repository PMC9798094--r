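pt
Agranulocytosis
Febrile neutropenia
Neutropenia
Thrombocytopenia
Pancytopenia
Torsade de pointes
Ventricular tachycardia
Cardiac failure
Arrhythmia
Atrial fibrillation
Cardiac arrest
Hypoplastic left heart syndrome
Atrial septal defect
Congenital hypothyroidism
Spina bifida
Deafness
Adrenal insufficiency
Cushing's syndrome
Inappropriate antidiuretic hormone secretion
Adrenocortical insufficiency acute
Hyperthyroidism
Hypopituitarism
Chloropsia
Toxic optic neuropathy
Visual impairment
Blindness
Xanthopsia
Pancreatitis acute
Gastrointestinal haemorrhage
Ileus
Multiple organ dysfunction syndrome
Death
Sudden death
Cholestasis
Drug-induced liver injury
Hepatitis fulminant
Liver injury
Hepatocellular injury
Hepatitis
Hepatic failure
Hepatitis cholestatic
Jaundice
Graft versus host disease
Immunodeficiency
Anaphylactic reaction
Immunosuppression
Sarcoidosis
Aspergillus infection
Bronchopulmonary aspergillosis
Pneumonia fungal
Mucormycosis
Encephalitis
Pseudomonas infection
Sepsis
Septic shock
Pneumonia
Candida infection
Fungaemia
Overdose
Accidental overdose
Toxicity to various agents
QT interval prolonged
QT interval prolongation
Electrocardiogram QT prolonged
Blood bilirubin increased
Transaminases increased
Hypokalaemia
Hyponatraemia
Dehydration
Hypoglycaemia
Metabolic acidosis
Rhabdomyolysis
Myopathy
Osteonecrosis
Periostitis
Leukaemia
Neoplasm malignant
Squamous cell carcinoma
Skin cancer
Malignant melanoma
Lymphoma
Basal cell carcinoma
Myelodysplastic syndrome
Encephalopathy
Seizure
Peripheral neuropathy
Syncope
Posterior reversible encephalopathy syndrome
Abortion spontaneous
Foetal death
Premature baby
Premature labour
Ectopic pregnancy
Delirium
Hallucination
Confusional state
Suicidal ideation
Completed suicide
Renal impairment
Acute kidney injury
Renal failure
Nephropathy toxic
Priapism
Respiratory failure
Pulmonary embolism
Pleural effusion
Acute respiratory distress syndrome
Pneumonitis
Haemoptysis
Erythema multiforme
Pseudoporphyria
Dermatitis bullous
Stevens-Johnson syndrome
Toxic epidermal necrolysis
Drug reaction with eosinophilia and systemic symptoms
Liver transplant
Renal transplant
Dialysis
Hypotension
Deep vein thrombosis
Shock
Haemorrhage
Thrombosis
Circulatory collapse
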