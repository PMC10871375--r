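# Reviewed de-identification template. Allow-list semantics: any field not
# named here is dropped. Actions: keep | drop | generalize_date_to_month |
# pseudonymize. Ids and references are pseudonymized with the keyed
# codebook so joins survive; dates are truncated to month; names,
# addresses, telecoms and note bodies are never listed and therefore never
# leave the site stage.
Patient:
  id: pseudonymize
  gender: keep
  birthDate: generalize_date_to_month
Encounter:
  id: pseudonymize
  subject.reference: pseudonymize
  class: keep
  status: keep
  period.start: generalize_date_to_month
Condition:
  id: pseudonymize
  subject.reference: pseudonymize
  encounter.reference: pseudonymize
  code: keep
  recordedDate: generalize_date_to_month
Observation:
  id: pseudonymize
  subject.reference: pseudonymize
  encounter.reference: pseudonymize
  meta: keep
  status: keep
  code: keep
  valueQuantity: keep
  effectiveDateTime: generalize_date_to_month
DocumentReference:
  id: pseudonymize
  subject.reference: pseudonymize
  context.encounter: pseudonymize
  status: keep
  date: generalize_date_to_month
MedicationRequest:
  id: pseudonymize
  subject.reference: pseudonymize
  encounter.reference: pseudonymize
  status: keep
  medicationCodeableConcept: keep
  authoredOn: generalize_date_to_month
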