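# Synthetic scenario: comparator trial (aggregate-only IgAN trial,
# continuous dual endothelin-angiotensin antagonist vs irbesartan). The
# target moments are the trial's published overall baseline column, which
# double as the matching targets of the anchored comparison.
trial_id: COMP-SYN
n_subjects: 404
allocation: 0.5
targets:
  - {name: age, kind: mean, value: 46.00, source: published baseline table}
  - {name: male, kind: proportion, value: 69.80, source: published baseline table}
  - {name: white, kind: proportion, value: 67.33, source: published baseline table}
  - {name: egfr, kind: mean, value: 56.95, source: published baseline table}
  - {name: upcr, kind: mean, value: 1.44, source: published baseline table}
  - {name: uacr, kind: threshold_proportion, threshold: 1.1, direction: greater,
     value: 50.00, source: published baseline table}
  - {name: uprot24h, kind: threshold_proportion, threshold: 1.8, direction: greater,
     value: 50.00, source: published baseline table}
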