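# Demonstration pipeline configuration: a small two-site cohort over a
# six-week 2020 window spanning all four intervention levels.
simulate: true
radius_m: 100
period_days: 30.44
max_weather_gap_days: 2
adjust: bonferroni
synthetic:
  sites:
    Cyprus:
      n_participants: 5
      home_lat: 35.17
      home_lon: 33.36
      baseline_home_fraction: 0.438
      level_home_shift: [0.414, 0.487, 0.452]
      baseline_steps: 8996
      level_steps_shift: [-2531, -3638, -3644]
      temp_mean: 16
      rh_mean: 65
      dds_days:
        "2020": 2
    Greece:
      n_participants: 5
      home_lat: 35.34
      home_lon: 25.13
      baseline_home_fraction: 0.524
      level_home_shift: [0.143, 0.231, 0.320]
      baseline_steps: 8527
      level_steps_shift: [-1191, -2337, -1961]
      temp_mean: 14
      rh_mean: 68
      dds_days:
        "2020": 1
  study_windows:
    - year: 2020
      start: "2020-02-24"
      end: "2020-04-05"
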