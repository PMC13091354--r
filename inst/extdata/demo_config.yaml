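# Demonstration configuration: a scaled-down dual-chip layout that runs the
# whole pipeline in seconds. Omitted keys fall back to package defaults
# (full 196/144-substrate layout, 9-patient cohort, ABL inhibitor panel).
seed: 11
design:
  substrates_per_chip: {PTK: 18, STK: 12}
  cycles_per_chip: {PTK: 20, STK: 24}
cohort:
  patients:
    - {patient_id: P1, sex: M}
    - {patient_id: P2, sex: M}
    - {patient_id: P3, sex: F}
  technical_replicates: 2
uka:
  n_perm: 200
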