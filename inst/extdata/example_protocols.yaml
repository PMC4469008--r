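# Infusion protocols: the validated murine schedule plus screening examples.
- label: protocol-1
  n_doses: 3
  dose_size: 1.0e6
  interval_h: 168
  first_dose_h: 168
  ef: 0.5
- label: weekly-1e7
  n_doses: 3
  dose_size: 1.0e7
  interval_h: 168
  first_dose_h: 168
  ef: 0.5
- label: q96h-1e6
  n_doses: 4
  dose_size: 1.0e6
  interval_h: 96
  first_dose_h: 168
  ef: 0.5
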