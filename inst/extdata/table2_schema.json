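[
  {"name": "Gender", "categories": ["Male", "Female"], "ordinal": false, "missing_token": "NA"},
  {"name": "Side", "categories": ["Left", "Right"], "ordinal": false, "missing_token": "NA"},
  {"name": "SurgeryAge", "categories": ["17-32", "33-54"], "ordinal": true, "missing_token": "NA"},
  {"name": "OnsetAge", "categories": ["0-1", "2-10", "11-20"], "ordinal": true, "missing_token": "NA"},
  {"name": "ElapsedTime", "categories": ["7-13", "14-19", "20-39"], "ordinal": true, "missing_token": "NA"},
  {"name": "SeizureType", "categories": ["Generalized", "PartialComplex", "Both"], "ordinal": false, "missing_token": "NA"},
  {"name": "SeizureFreq", "categories": ["Daily", "Weekly", "2-Weekly", "3-Weekly", "4-Weekly", "Other"], "ordinal": false, "missing_token": "NA"},
  {"name": "Febrile", "categories": ["Negative", "Positive"], "ordinal": false, "missing_token": "NA"},
  {"name": "VIQ", "categories": ["Low", "Normal-Low", "Normal", "Normal-High", "High"], "ordinal": true, "missing_token": "NA"},
  {"name": "PIQ", "categories": ["Low", "Normal-Low", "Normal", "Normal-High", "High"], "ordinal": true, "missing_token": "NA"},
  {"name": "FSIQ", "categories": ["Low", "Normal-Low", "Normal", "Normal-High", "High"], "ordinal": true, "missing_token": "NA"},
  {"name": "MlogI", "categories": ["Low", "Normal-Low", "Normal", "Normal-High", "High"], "ordinal": true, "missing_token": "NA"},
  {"name": "MlogII", "categories": ["Low", "Normal-Low", "Normal", "Normal-High", "High"], "ordinal": true, "missing_token": "NA"},
  {"name": "MvisI", "categories": ["Low", "Normal-Low", "Normal", "Normal-High", "High"], "ordinal": true, "missing_token": "NA"},
  {"name": "MvisII", "categories": ["Low", "Normal-Low", "Normal", "Normal-High", "High"], "ordinal": true, "missing_token": "NA"},
  {"name": "Sczi", "categories": ["Negative", "Positive"], "ordinal": false, "missing_token": "NA"},
  {"name": "Cdi", "categories": ["Negative", "Positive"], "ordinal": false, "missing_token": "NA"},
  {"name": "Depi", "categories": ["Negative", "Positive"], "ordinal": false, "missing_token": "NA"},
  {"name": "PStyle", "categories": ["EB1", "EB2", "EB3"], "ordinal": true, "missing_token": "NA"}
]
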