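{
  "session_id": "prof_demo_01",
  "group": "professional",
  "trial_index": 1,
  "total_targets": 3,
  "session_time_min": 4.3,
  "detected": [
    {"target_id": "stone_superior_major", "time_s": 42.0},
    {"target_id": "stone_superior_minor", "time_s": 118.5},
    {"target_id": "stone_inferior_major", "time_s": 201.0}
  ]
}
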