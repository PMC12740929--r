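soc,count
Gastrointestinal disorders,808
Psychiatric disorders,781
General disorders and administration site conditions,586
Nervous system disorders,565
"Respiratory, thoracic and mediastinal disorders",530
Investigations,401
Metabolism and nutrition disorders,230
Musculoskeletal and connective tissue disorders,126
"Injury, poisoning and procedural complications",72
Cardiac disorders,15
Social circumstances,8
Infections and infestations,3
"Neoplasms benign, malignant and unspecified (incl cysts and polyps)",3
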