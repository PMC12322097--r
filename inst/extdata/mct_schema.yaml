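# Canonical 7-attribute multi-cancer-test schema (level counts 4,4,2,4,2,4,2;
# 2048 profiles). PPV/NPV are percent; NPV is presented to GPs as risk of
# cancer after a negative test (100 - NPV).
attributes:
  - name: ppv
    coding: categorical
    numeric: yes
    levels: [20, 40, 60, 80]
    reference: 80
    arm_visibility: ppv_arm
    wording:
      gp: "Risk of cancer after a positive test"
      public: "Test gets it wrong when it tells us there is a cancer"
  - name: npv
    coding: categorical
    numeric: yes
    levels: [96, 99, 99.5, 99.9]
    reference: 99.9
    arm_visibility: npv_arm
    wording:
      gp: "Risk of cancer after a negative test"
      public: "Test gets it wrong when it tells us there is not a cancer"
  - name: wait
    coding: categorical
    numeric: no
    levels: ["1wk", "1-2wk"]
    reference: "1wk"
    wording:
      gp: "Waiting time for test results"
      public: "Waiting time for test results"
  - name: cancers
    coding: continuous
    numeric: yes
    levels: [1, 5, 10, 25]
    wording:
      gp: "Number of cancer sites tested"
      public: "Number of cancers tested for"
  - name: site
    coding: categorical
    numeric: no
    levels: ["yes", "no"]
    reference: "no"
    wording:
      gp: "Can the test identify the site?"
      public: "Test detects type of cancer?"
  - name: form
    coding: categorical
    numeric: no
    levels: [blood, faecal, urine, breath]
    reference: blood
    wording:
      gp: "Form of the test"
      public: "Form of the test"
  - name: early
    coding: categorical
    numeric: no
    levels: ["yes", "no"]
    reference: "no"
    wording:
      gp: "Can the test detect the stage of cancer?"
      public: "Test can detect cancer at an early stage?"
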