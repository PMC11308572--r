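{
  "comment": "Virtual-trial replication settings. The trial-horizon chemotherapy effects and premenopausal enrollment share are calibrated to the published validation table, not taken from the trial itself.",
  "pre_fraction": 0.364,
  "chemo_effect": {
    "pre": [0.5221, 0.5221, 0.5221, 0.5221],
    "post": [0.9716, 0.9716, 0.9716, 0.9716]
  },
  "power_spec": {
    "p_control": 0.93,
    "detectable_difference": 0.025,
    "alpha": 0.05,
    "power": 0.8
  },
  "reference": {
    "stratum": ["overall", "pre", "post"],
    "endocrine": [93.9, 92.8, 94.4],
    "chemo_endocrine": [94.9, 96.1, 94.4],
    "difference": [1, 3.3, 0]
  }
}
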