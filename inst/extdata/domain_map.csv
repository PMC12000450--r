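domain,from,to,eim
IBD index,K50,K51,FALSE
Cerebrovascular diseases,I60,I69,TRUE
Cerebrovascular diseases,I80,I82,TRUE
Certain infectious and parasitic diseases,A00,B99,TRUE
Neoplasms,C00,D48,TRUE
Diseases of the blood and blood-forming organs and certain disorders involving the immune mechanism,D50,D89,TRUE
"Endocrine, nutritional and metabolic diseases",E00,E90,TRUE
"Mental, behavioral and neurodevelopmental disorders",F00,F99,TRUE
Diseases of the nervous system,G00,G99,TRUE
Diseases of the eye and adnexa,H00,H59,TRUE
Diseases of the ear and mastoid process,H60,H95,TRUE
Diseases of the circulatory system,I00,I99,TRUE
Diseases of the respiratory system,J00,J99,TRUE
Diseases of the digestive system,K00,K93,TRUE
Diseases of the skin and subcutaneous tissue,L00,L99,TRUE
Diseases of the musculoskeletal system and connective tissue,M00,M99,TRUE
Diseases of the genitourinary system,N00,N99,TRUE
"Symptoms, signs and abnormal clinical and laboratory findings, not elsewhere classified",R00,R99,TRUE
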