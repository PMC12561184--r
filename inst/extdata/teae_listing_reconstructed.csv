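patient,term,grade
P01,Hypertension,3
P01,Blood bilirubin increased,3
P01,AST/ALT increased,1
P01,Anemia,1
P02,Biliary tract infection,3
P02,White blood cell count decreased,1
P03,Neutrophil count decreased,2
P03,White blood cell count decreased,2
P03,Hyperkalemia,1
P04,Platelet count decreased,2
P04,Hypoalbuminemia,2
P05,Urinary tract infection,2
P06,White blood cell count decreased,1
P06,Neutrophil count decreased,1
P06,Hypertension,1
P07,White blood cell count decreased,1
P07,Platelet count decreased,1
P07,Blood bilirubin increased,1
P08,White blood cell count decreased,1
P08,AST/ALT increased,1
P08,Peripheral sensory neuropathy,1
P09,Neutrophil count decreased,1
P09,Platelet count decreased,1
P09,Peripheral sensory neuropathy,1
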