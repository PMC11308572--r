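{
  "race_eth_weights": {
    "nh_black": 0.07,
    "hispanic": 0.1,
    "nh_white": 0.83
  },
  "age_bins": {
    "lower": [18, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95],
    "upper": [25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85, 90, 95, 100]
  },
  "age_dist_by_race": {
    "nh_black": [0.00505462039724002, 0.011564681298226, 0.0265365643588165, 0.0519953045527378, 0.0869964528815135, 0.124298072902824, 0.15165540523721, 0.158010144435746, 0.140587345346308, 0.106816895310862, 0.069304605792, 0.0383978029407502, 0.0181662088236764, 0.00733880430449842, 0.0025314937029218, 0.000745597714669436],
    "hispanic": [0.00888948290082936, 0.018486781592212, 0.0389521612895194, 0.0700834783804025, 0.107676769162538, 0.141272266550953, 0.158279375173957, 0.151434886448198, 0.123726032644609, 0.0863230555375655, 0.0514301540729752, 0.0261653568920026, 0.0113669432856622, 0.0042165501172706, 0.00133553058732459, 0.000361175363981019],
    "nh_white": [0.00351537125902048, 0.00851893172645696, 0.0205824011363665, 0.0424631071756706, 0.0748070606557202, 0.112537341855626, 0.144570575177889, 0.158597391632772, 0.148575231146488, 0.118858451333616, 0.0811976976576416, 0.0473676451055595, 0.0235958989047711, 0.0100368633615899, 0.00364547680177445, 0.00113055506903704]
  },
  "menopause": {
    "midpoint": {
      "nh_black": 49.8752844227269,
      "hispanic": 49.8752844227269,
      "nh_white": 49.8752844227269
    },
    "scale": {
      "nh_black": 2.2,
      "hispanic": 2.2,
      "nh_white": 2.2
    }
  },
  "age_band_breaks": [18, 50, 70],
  "grade_dist": {
    "nh_black": {
      "18-49": {
        "low": 0.17367833167452,
        "intermediate": 0.532418088901297,
        "high": 0.293903579424184
      },
      "50-69": {
        "low": 0.20867833167452,
        "intermediate": 0.539418088901297,
        "high": 0.251903579424184
      },
      "70+": {
        "low": 0.22367833167452,
        "intermediate": 0.537418088901297,
        "high": 0.238903579424184
      }
    },
    "hispanic": {
      "18-49": {
        "low": 0.227064497240888,
        "intermediate": 0.575887277999774,
        "high": 0.197048224759339
      },
      "50-69": {
        "low": 0.262064497240888,
        "intermediate": 0.582887277999774,
        "high": 0.155048224759339
      },
      "70+": {
        "low": 0.277064497240888,
        "intermediate": 0.580887277999774,
        "high": 0.142048224759339
      }
    },
    "nh_white": {
      "18-49": {
        "low": 0.249993488441853,
        "intermediate": 0.576387785240342,
        "high": 0.173618726317805
      },
      "50-69": {
        "low": 0.284993488441853,
        "intermediate": 0.583387785240342,
        "high": 0.131618726317805
      },
      "70+": {
        "low": 0.299993488441853,
        "intermediate": 0.581387785240342,
        "high": 0.118618726317805
      }
    }
  },
  "hormone_dist": {
    "nh_black": {
      "low": 0.86534,
      "intermediate": 0.82034,
      "high": 0.64034
    },
    "hispanic": {
      "low": 0.90435,
      "intermediate": 0.85935,
      "high": 0.67935
    },
    "nh_white": {
      "low": 0.919519518072289,
      "intermediate": 0.874519518072289,
      "high": 0.694519518072289
    }
  },
  "size_dist": {
    "nh_black": {
      "low": {
        "18-49": 0.563428719843391,
        "50-69": 0.588428719843391,
        "70+": 0.593428719843391
      },
      "intermediate": {
        "18-49": 0.473428719843391,
        "50-69": 0.498428719843391,
        "70+": 0.503428719843391
      },
      "high": {
        "18-49": 0.323428719843391,
        "50-69": 0.348428719843391,
        "70+": 0.353428719843391
      }
    },
    "hispanic": {
      "low": {
        "18-49": 0.582159644945315,
        "50-69": 0.607159644945315,
        "70+": 0.612159644945315
      },
      "intermediate": {
        "18-49": 0.492159644945315,
        "50-69": 0.517159644945315,
        "70+": 0.522159644945315
      },
      "high": {
        "18-49": 0.342159644945315,
        "50-69": 0.367159644945315,
        "70+": 0.372159644945315
      }
    },
    "nh_white": {
      "low": {
        "18-49": 0.60722995152819,
        "50-69": 0.63222995152819,
        "70+": 0.63722995152819
      },
      "intermediate": {
        "18-49": 0.51722995152819,
        "50-69": 0.54222995152819,
        "70+": 0.54722995152819
      },
      "high": {
        "18-49": 0.36722995152819,
        "50-69": 0.39222995152819,
        "70+": 0.39722995152819
      }
    }
  },
  "rs_model": {
    "cutpoints": [-5.73014005957994, -5.23224018323317, -4.75861361238856, -4.30858063929206, -3.88129917749614, -3.47574756535846, -3.09071394955781, -2.72479346543795, -2.37639305092334, -2.04374216186035, -1.72490619748729, -1.41779829665514, -1.12018432286897, -0.829675045769433, -0.543698166215995, -0.259439916638332, 0.0262603033167721, 0.317092061202443, 0.617591153500551, 0.933715258689573, 1.27396248600012, 1.65177139451154, 2.0914665206088, 2.64670067137733, 3.48756425814979],
    "eta": {
      "grade": {
        "low": -0.25,
        "intermediate": 0,
        "high": 0.45
      },
      "size_class": {
        "le_2cm": 0,
        "gt_2cm": 0.1
      },
      "hormone_sensitivity": {
        "er_and_pr_pos": 0,
        "er_or_pr_pos": 0.35
      },
      "age_band": {
        "18-49": 0.382207187187096,
        "50-69": 0,
        "70+": -0.05
      },
      "race_eth": {
        "nh_black": 0.05,
        "hispanic": 0,
        "nh_white": 0
      }
    }
  }
}
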