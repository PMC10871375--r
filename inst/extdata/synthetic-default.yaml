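# Default synthetic-network configuration: a five-site network over a
# 12-month window with note-mention sensitivity (0.9) deliberately above
# ICD coding sensitivity (0.5), so text-derived symptom detection
# outperforms coded detection by construction.
n_patients: 1000
n_sites: 5
study_window: ["2021-01", "2021-12"]
disease_prevalence: 0.3
icd_coding_sensitivity: 0.5
note_mention_sensitivity: 0.9
negated_mention_rate: 0.2
disease_coding_sensitivity: 1.0
hypertension_prevalence: 0.25
mean_extra_encounters: 0.3
seed: 20210101
symptom_profile:
  - {code: R50.9, label: fever, pDisease: 0.60, pHealthy: 0.05}
  - {code: R68.83, label: chills, pDisease: 0.40, pHealthy: 0.03}
  - {code: R05, label: cough, pDisease: 0.70, pHealthy: 0.10}
  - {code: R06.0, label: dyspnea, pDisease: 0.30, pHealthy: 0.04}
  - {code: R51, label: headache, pDisease: 0.35, pHealthy: 0.10}
vitals_model:
  hypertensive: {sysMean: 150, sysSd: 10, diaMean: 95, diaSd: 8}
  normal: {sysMean: 118, sysSd: 8, diaMean: 75, diaSd: 6}
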