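# Vital-sign hypertension phenotype: an encounter qualifies at the
# critical values of 140/90 mm Hg — systolic >= 140 OR diastolic >= 90,
# both comparators inclusive. A medication exclusion hook is present but
# ships without an authoritative code list (empty exclusion).
name: hypertension
study_period: ["2021-01", "2021-12"]
count_unit: encounters
include_comparison: true
value_sets: {}
case_definition:
  inclusion:
    any:
      - {type: numeric_threshold, code: "8480-6", cmp: ">=", value: 140}
      - {type: numeric_threshold, code: "8462-4", cmp: ">=", value: 90}
variables:
  - {name: hypertensive, kind: boolean, source: case}
  - {name: age_group, kind: binned, source: age, edges: [0, 5, 12, 18, 65, 90]}
  - {name: month, kind: month, source: month}
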