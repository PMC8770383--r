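{
  "comment": "Age-sex specific hemoglobin cutoffs (g/dL) defining anemia, per the 2015 Japanese Society for Dialysis Therapy renal-anemia guideline. Anemia means Hb strictly below the cutoff.",
  "male": {"lt60": 13.5, "60to69": 12.0, "ge70": 11.0},
  "female": {"lt60": 11.5, "60to69": 10.5, "ge70": 10.5}
}
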