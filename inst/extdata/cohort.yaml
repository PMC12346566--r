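# Default synthetic prescribing cohort (see ?cohort_config).
n: 2000
comorbidity_rate: 0.15
prevalence:
  COPD: 0.30
  asthma: 0.20
  URTI: 0.15
  pneumonia: 0.12
  healthy: 0.10
  bronchiolitis: 0.06
  bronchiectasis: 0.04
  LRTI: 0.03
anticoagulant_rate: 0.10
label_noise: 0
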