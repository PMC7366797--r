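[
  {
    "representative_angle": 30,
    "theta_lo": 0,
    "theta_hi": 45
  },
  {
    "representative_angle": 60,
    "theta_lo": 45,
    "theta_hi": 75
  },
  {
    "representative_angle": 90,
    "theta_lo": 75,
    "theta_hi": 105
  },
  {
    "representative_angle": 120,
    "theta_lo": 105,
    "theta_hi": 135
  },
  {
    "representative_angle": 150,
    "theta_lo": 135,
    "theta_hi": 180
  }
]
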