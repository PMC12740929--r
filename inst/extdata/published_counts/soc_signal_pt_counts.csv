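soc,count
Psychiatric disorders,13
"Respiratory, thoracic and mediastinal disorders",8
Investigations,6
General disorders and administration site conditions,5
Gastrointestinal disorders,4
Nervous system disorders,4
Cardiac disorders,3
Metabolism and nutrition disorders,3
"Injury, poisoning and procedural complications",2
Infections and infestations,1
Musculoskeletal and connective tissue disorders,1
"Neoplasms benign, malignant and unspecified (incl cysts and polyps)",1
Social circumstances,1
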