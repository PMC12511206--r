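# Default synthetic-cohort specifications, mirroring mct_cohort_spec() and
# quadra_cohort_spec(). Stratum n and target medians follow the audited
# cohorts; jitter and DLP-model values are calibration constants of the
# generator, not claims about the hospital data.
cohorts:
  - cohort_name: mCT
    seed: 20260101
    strata:
      - {label: "<50",    "n": 16,  target_median: 45.9, spread: 3.5, lower: 35,  upper: 50}
      - {label: "50–59",  "n": 75,  target_median: 56,   spread: 3,   lower: 50,  upper: 60}
      - {label: "60–69",  "n": 110, target_median: 65,   spread: 3,   lower: 60,  upper: 70}
      - {label: "70–79",  "n": 107, target_median: 74,   spread: 3,   lower: 70,  upper: 80}
      - {label: "80–89",  "n": 78,  target_median: 83.5, spread: 3,   lower: 80,  upper: 90}
      - {label: "90–99",  "n": 63,  target_median: 93,   spread: 3,   lower: 90,  upper: 100}
      - {label: ">100",   "n": 35,  target_median: 108,  spread: 8,   lower: 100, upper: 160}
    activity_protocol:
      rule: weight_tiered
      standard: 250
      heavy: 300
      heavy_threshold: 90
      jitter_median: 1.17
      jitter_sdlog: 0.15
    dlp_model: {intercept: 4.7970, slope: 0.016506, sdlog: 0.22}
    height_model: {mean_bmi: 26, sd_bmi: 4, min_bmi: 15, max_bmi: 45}
    height_missing_rate: 0.20041322314049587   # 97/484 -> 387 heights recorded
    gender_ratio_male: 0.5652173913043478      # 273/483 known-gender patients
    gender_unknown: 1
  - cohort_name: Quadra
    seed: 20260102
    strata:
      - {label: "<50",    "n": 39,  target_median: 46,    spread: 3.5, lower: 35,  upper: 50}
      - {label: "50–59",  "n": 99,  target_median: 56,    spread: 3,   lower: 50,  upper: 60}
      - {label: "60–69",  "n": 122, target_median: 64.8,  spread: 3,   lower: 60,  upper: 70}
      - {label: "70–79",  "n": 126, target_median: 74,    spread: 3,   lower: 70,  upper: 80}
      - {label: "80–89",  "n": 84,  target_median: 84,    spread: 3,   lower: 80,  upper: 90}
      - {label: "90–99",  "n": 43,  target_median: 93,    spread: 3,   lower: 90,  upper: 100}
      - {label: ">100",   "n": 40,  target_median: 111.5, spread: 8,   lower: 100, upper: 160}
    activity_protocol:
      rule: fixed
      standard: 150
      jitter_median: 0.9966666666666667        # median lands near 149.5 MBq
      jitter_sdlog: 0.05
    dlp_model: {intercept: 4.6831, slope: 0.018659, sdlog: 0.22}
    height_model: {mean_bmi: 26, sd_bmi: 4, min_bmi: 15, max_bmi: 45}
    height_missing_rate: 0.7576853526220614    # 419/553 -> 134 heights recorded
    gender_ratio_male: 0.5768535262206148      # 319/553
    gender_unknown: 0
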