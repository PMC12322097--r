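# Prior means (log-odds per encoded column) and a common prior variance for
# the Bayesian D-efficient design search. Shaped like pilot-scale estimates:
# monotone accuracy preferences, mild preferences elsewhere.
mean:
  ppv_20: -1.5
  ppv_40: -1.0
  ppv_60: -0.5
  npv_96: -1.2
  npv_99: -0.5
  npv_99.5: -0.25
  wait_1_2wk: -0.05
  cancers_per10: 0.3
  site_yes: 0.4
  form_faecal: -0.15
  form_urine: 0.0
  form_breath: 0.0
  early_yes: 0.3
variance: 0.04
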