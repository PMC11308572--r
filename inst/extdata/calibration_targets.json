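{
  "statistic": ["drfs_5y", "drfs_5y", "drfs_5y", "drfs_10y", "drfs_10y", "drfs_10y", "drfs_10y", "drfs_10y", "drfs_10y", "life_years", "life_years", "life_years", "life_years", "life_years", "life_years", "qaly_disc_3", "qaly_disc_3", "qaly_disc_3"],
  "stratum": ["overall", "menopausal=pre", "menopausal=post", "overall", "menopausal=pre", "menopausal=pre", "menopausal=post", "race_eth=nh_black", "race_eth=nh_black", "overall", "menopausal=pre", "menopausal=post", "overall", "menopausal=pre", "menopausal=post", "overall", "menopausal=pre", "menopausal=post"],
  "arm": ["endocrine", "endocrine", "endocrine", "chemo_endocrine", "endocrine", "chemo_endocrine", "chemo_endocrine", "endocrine", "chemo_endocrine", "endocrine", "endocrine", "endocrine", "incremental", "incremental", "incremental", "incremental", "incremental", "incremental"],
  "target": [93.1, 92.4, 93.5, 81.9, 79.7, 85.3, 80.1, 74.6, 74.8, 19.6, 27.8, 15.4, -0.6, 2.1, -2, -0.4, 0.6, -1],
  "tolerance": [0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.7, 0.2, 0.2, 0.2, 0.1, 0.07, 0.1, 0.05, 0.05, 0.1],
  "weight": [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1.5, 2, 3, 3, 2, 3, 0.5]
}
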