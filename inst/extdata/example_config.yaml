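seed: 101
output_dir: chromapk-output
chromatogram:
  duration: 20.0
  sampling_rate: 5.0
  baseline_noise_sd: 0.2
  blank_region:
  - 16.0
  - 19.0
sst_limits:
  rs_min: 2.0
  t_max: 2.0
  n_min: 2000.0
schedule:
  times:
  - 0.0
  - 0.25
  - 0.5
  - 1.0
  - 3.0
  - 6.0
  - 9.0
  - 12.0
  noise_cv: 0.05
qc:
  true_recovery: 0.96
  cv: 0.04
  'n': 3.0
  periods:
  - intraday
  - interday
stability:
  true_recovery: 0.94
  cv: 0.05
  'n': 3.0
  conditions:
  - short_term
  - long_term
analytes:
  CCA:
    retention_time: 9.663
    sigma: 0.08
    tau: 0.0
    peak_area: 4.0
    window:
    - 9.4
    - 9.9
    cal_levels:
    - 0.015
    - 0.03
    - 0.06
    - 0.125
    - 0.5
    - 4.0
    cal_slope: 0.2227
    cal_intercept: 0.0158
    qc_levels:
    - 0.5
    - 1.0
    - 2.0
    - 4.0
    stability_levels:
    - 0.12
    - 4.0
    lloq: 0.01
    height_response_slope: 900.0
  ATV:
    retention_time: 10.998
    sigma: 0.085
    tau: 0.062
    peak_area: 3.0
    window:
    - 10.7
    - 11.3
    cal_levels:
    - 0.005
    - 0.01
    - 0.02
    - 0.04
    - 0.08
    - 0.16
    - 0.32
    - 0.64
    - 1.28
    - 2.56
    cal_slope: 0.3404
    cal_intercept: 0.0017
    qc_levels:
    - 0.2
    - 0.3
    - 1.0
    - 2.5
    stability_levels:
    - 0.5
    - 2.5
    lloq: 0.005
    height_response_slope: 1800.0
  IS:
    retention_time: 11.802
    sigma: 0.09
    tau: 0.0
    peak_area: 6.0
    window:
    - 11.5
    - 12.1
  CLP:
    retention_time: 12.682
    sigma: 0.06
    tau: 0.1
    peak_area: 5.0
    window:
    - 12.4
    - 13.0
    cal_levels:
    - 0.008
    - 0.016
    - 0.032
    - 0.064
    - 0.128
    - 0.25
    - 0.5
    - 1.0
    - 2.0
    cal_slope: 0.3789
    cal_intercept: 0.0004
    qc_levels:
    - 0.25
    - 0.5
    - 1.0
    - 2.0
    lloq: 0.008
    height_response_slope: 1500.0
subjects:
  patient1:
    CLP:
      A: 0.13
      ka: 12.0
      ke: 0.81
      dose_mg: 75.0
    CCA:
      A: 5.1
      ka: 3.2
      ke: 0.15
      dose_mg: 75.0
    ATV:
      A: 0.13
      ka: 0.85
      ke: 0.08
      dose_mg: 20.0
  patient2:
    CLP:
      A: 0.1
      ka: 12.0
      ke: 0.58
      dose_mg: 75.0
    CCA:
      A: 5.9
      ka: 2.9
      ke: 0.23
      dose_mg: 75.0
    ATV:
      A: 0.21
      ka: 0.9
      ke: 0.08
      dose_mg: 40.0
  patient3:
    CLP:
      A: 0.09
      ka: 12.0
      ke: 1.02
      dose_mg: 75.0
    CCA:
      A: 4.0
      ka: 3.3
      ke: 0.13
      dose_mg: 75.0
    ATV:
      A: 0.26
      ka: 0.8
      ke: 0.07
      dose_mg: 80.0
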