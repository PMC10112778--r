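[
  {"key": "intervention.cost_infusion", "low": 8000, "high": 45000},
  {"key": "intervention.comm_change_cb.mean", "low": 1.0, "high": 6.0},
  {"key": "qol.beta_comm", "low": 0.0019, "high": 0.0074},
  {"key": "intervention.cost_ae_mild", "low": 1050, "high": 4200},
  {"key": "intervention.cost_ae_severe", "low": 5785, "high": 23142},
  {"key": "intervention.p_mild_moderate", "low": 0.046, "high": 0.184},
  {"key": "intervention.p_severe", "low": 0.017, "high": 0.068}
]
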