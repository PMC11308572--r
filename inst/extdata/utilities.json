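{
  "comment": "EQ-5D-based age-band utilities for the general female population and health-state utilities for early-stage breast cancer; values as published. Age bands outside 20-79 use the nearest tabulated value.",
  "age_band_utility": {
    "breaks": [20, 30, 40, 50, 60, 70, 80],
    "values": [0.913, 0.893, 0.863, 0.837, 0.811, 0.771]
  },
  "state_utilities": {
    "invasive_breast_cancer": 0.731,
    "chemotherapy": 0.9,
    "toxicity": 0.7,
    "distant_recurrence": 0.4
  },
  "durations": {
    "chemotherapy": 0.5,
    "toxicity": 0.5,
    "distant_recurrence": 3
  },
  "recurrence_until_death": false
}
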