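# Pipeline configuration: omitted keys fall back to package defaults.
detection:
  w: 0.5
  delta: 0.01
  tau: 1
  delta_tau: 1
  ratios:
    - [1, 1]
    - [5, 4]
    - [4, 3]
    - [3, 2]
    - [5, 3]
    - [2, 1]
filter:
  relative_bandwidth: 0.15
  coarse_window_s: 0.25
overlap:
  window_s: 1
  bin_hz: 1
  harmonics: [2, 3]
cv:
  window_s: 0.25
seed: 1
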