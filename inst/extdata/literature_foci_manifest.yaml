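n_rows: 122
n_studies: 52
structure_rows:
  'SN': 30
  'SN/STN': 1
  'SN/VTA': 38
  'STN': 53
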