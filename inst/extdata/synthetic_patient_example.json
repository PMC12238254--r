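{
  "id": "SYN-EXAMPLE-001",
  "age_years": 23.4,
  "sex": "female",
  "deformity_labels": ["ClassIII", "Asymmetry"],
  "anb_deg": -2.8,
  "treatment_duration_months": 26.0,
  "enrollment_index": 1,
  "record_seed": 424243
}
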