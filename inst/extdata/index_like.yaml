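# Synthetic scenario: index trial (IPD-available IgAN trial, 9-month active
# treatment plus optimized RASi background). The target moments are the
# trial's published unweighted baseline column; the generator reproduces
# them marginally and calibrate_trial_moments() can pin them exactly.
trial_id: INDEX-SYN
n_subjects: 364
allocation: 0.5
targets:
  - {name: age, kind: mean, value: 42.70, source: published baseline table}
  - {name: male, kind: proportion, value: 65.93, source: published baseline table}
  - {name: white, kind: proportion, value: 75.55, source: published baseline table}
  - {name: egfr, kind: mean, value: 57.87, source: published baseline table}
  - {name: upcr, kind: mean, value: 1.48, source: published baseline table}
  - {name: uacr, kind: threshold_proportion, threshold: 1.1, direction: greater,
     value: 40.66, source: published baseline table}
  - {name: uprot24h, kind: threshold_proportion, threshold: 1.8, direction: greater,
     value: 65.66, source: published baseline table}
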