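# Shared symptom value set: concept codes used both for coded-data value
# sets (ICD-10-CM Condition codes) and as the normalization target of the
# note-text extractor. Surface forms are matched case-insensitively at
# word boundaries.
system: ICD-10-CM
concepts:
  - code: R50.9
    label: fever
    forms: [fever, fevers, febrile]
  - code: R68.83
    label: chills
    forms: [chills, shivering, rigors]
  - code: R05
    label: cough
    forms: [cough, coughs]
  - code: R06.0
    label: dyspnea
    forms: [dyspnea, shortness of breath, breathless]
  - code: R51
    label: headache
    forms: [headache, headaches, cephalalgia]
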