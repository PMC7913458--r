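icd10_code,label,source
D57,Sickle-cell disorders,walker
Q05,Spina bifida,walker
A924,Rift Valley fever,orphadata-confirmed
E750,GM2 gangliosidosis,walker
G710,Muscular dystrophy,walker
I421,Obstructive hypertrophic cardiomyopathy,orphadata-confirmed
K743,Primary biliary cirrhosis,orphadata-confirmed
M315,Giant cell arteritis with polymyalgia rheumatica,walker
C946,Myelodysplastic and myeloproliferative disease not elsewhere classified,orphadata-confirmed
E840,Cystic fibrosis with pulmonary manifestations,walker
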