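# Default deidentification rule set: pseudonymize the patient identifier,
# strip free-text quasi-identifiers, keep the analysis fields. Rules are
# applied per resource type; fields not named fall under default_action.
default_action: keep
rules:
  - resource_type: Patient
    field_path: identifier
    action: pseudonymize
    domain: patient
  - resource_type: Patient
    field_path: quasi_identifier
    action: remove
  - resource_type: Patient
    field_path: gender
    action: keep
  - resource_type: Condition
    field_path: code
    action: keep
  - resource_type: Condition
    field_path: onsetDateTime
    action: keep
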