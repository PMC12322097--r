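# Benchmark and comparator test profiles for preference ranking.
#
# The benchmark is shaped like the blood-based multi-cancer test evaluated in
# the SYMPLIFY study: PPV 76%, NPV 98%, results in 1-2 weeks, identifies the
# cancer site, detects early-stage disease; it covers over 50 cancer types,
# clamped here to the design maximum of 25. PPV/NPV are off-grid and are
# evaluated by piecewise-linear interpolation between level coefficients.
#
# Comparator accuracy values are SYNTHETIC placeholders chosen to be
# clinically plausible for symptomatic primary-care use (single-cancer
# tests; FIT faecal, PSA and CA125 blood); edit to taste.
benchmark:
  ppv: 76
  npv: 98
  wait: 1-2wk
  cancers: 25
  site: "yes"
  form: blood
  early: "yes"
comparators:
  FIT:
    ppv: 20
    npv: 99.5
    wait: 1wk
    cancers: 1
    site: "yes"
    form: faecal
    early: "yes"
  PSA:
    ppv: 20
    npv: 99.0
    wait: 1wk
    cancers: 1
    site: "yes"
    form: blood
    early: "yes"
  CA125:
    ppv: 20
    npv: 99.0
    wait: 1wk
    cancers: 1
    site: "yes"
    form: blood
    early: "no"
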