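# CSV dialect declarations for the two labeled competition-style formats and
# the unlabeled 24/7 format. `time` says whether the Time column carries the
# 0-based sample index or seconds; `units` the acceleration units on disk.
tdcsfog:
  sampling_rate: 128
  units: m_per_s2
  time: index
  columns: [Time, AccV, AccML, AccAP, StartHesitation, Turn, Walking]
  optional_columns: []
defog:
  sampling_rate: 100
  units: g
  time: index
  columns: [Time, AccV, AccML, AccAP, StartHesitation, Turn, Walking, Valid, Task]
  optional_columns: [Notype]
daily:
  sampling_rate: 100
  units: g
  time: index
  columns: [Time, AccV, AccML, AccAP]
  optional_columns: []
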