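{
  "profile_a": {"baseline_hz": 691.2, "wander_sd_hz": 11.1, "duration_s": 20},
  "profile_b": {"baseline_hz": 479.8, "wander_sd_hz": 9.7, "duration_s": 20},
  "events": [
    {"p": 3, "q": 2, "onset_s": 4, "duration_s": 5},
    {"p": 5, "q": 3, "onset_s": 12, "duration_s": 4}
  ]
}
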