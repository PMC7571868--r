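# Default subject-level simulation priors for the two study populations.
# Two-element fields [lo, hi] are uniform priors sampled once per subject;
# scalar fields are fixed. Units: seconds, Hz, mmHg; jitter SDs as noted.
# The clinical profile draws wider morphology-jitter priors and admits
# paced and ectopic (PVC) beats; the non-clinical profile is purely
# intrinsic sinus rhythm.
nonclinical:
  length_s: 300.0
  fs: 1000.0
  ecg_fs: 1000.0
  heart_rate_bpm: [60.0, 80.0]
  rr_jitter_sd_s: [0.020, 0.050]
  amp_jitter_sd: [0.030, 0.080]        # lognormal SD of per-beat amplitude scale
  phase_jitter_sd_s: [0.002, 0.005]    # per-component timing jitter
  shape_ar_coef: 0.8
  shape_innov_sd: [0.010, 0.030]       # AR(1) innovation of log width scale
  resp_rate_hz: [0.20, 0.30]
  resp_depth: [0.05, 0.15]
  pvc_prob: [0.0, 0.0]
  paced_subject_prob: 0.0
  paced_fraction: 0.0
  pacing_spike_amp: 6.0
  noise_sd: [0.020, 0.050]             # white noise on the BCG channel
  drift_sd: [0.05, 0.10]               # low-frequency baseline wander
  ecg_noise_sd: [0.005, 0.020]
  ecg_shape_sd: 0.02                   # per-beat T-wave width log-jitter
  ecg_amp_sd: 0.05
  sbp_mean_mmhg: [105.0, 130.0]
  dbp_mean_mmhg: [65.0, 85.0]
  bp_sd_mmhg: [2.0, 4.0]               # slow beat-to-beat BP variation
  bp_noise_sd_mmhg: [1.0, 2.0]         # continuous-device measurement noise
  bp_offset_mmhg: [-15.0, 15.0]        # constant device offset to be recovered
clinical:
  length_s: 300.0
  fs: 1000.0
  ecg_fs: 1000.0
  heart_rate_bpm: [55.0, 90.0]
  rr_jitter_sd_s: [0.030, 0.080]
  amp_jitter_sd: [0.100, 0.250]
  phase_jitter_sd_s: [0.006, 0.015]
  shape_ar_coef: 0.8
  shape_innov_sd: [0.030, 0.080]
  resp_rate_hz: [0.20, 0.30]
  resp_depth: [0.10, 0.25]
  pvc_prob: [0.0, 0.08]
  paced_subject_prob: 0.2
  paced_fraction: 0.9
  pacing_spike_amp: 6.0
  noise_sd: [0.030, 0.080]
  drift_sd: [0.05, 0.15]
  ecg_noise_sd: [0.010, 0.030]
  ecg_shape_sd: 0.03
  ecg_amp_sd: 0.08
  sbp_mean_mmhg: [100.0, 140.0]
  dbp_mean_mmhg: [60.0, 90.0]
  bp_sd_mmhg: [3.0, 6.0]
  bp_noise_sd_mmhg: [1.0, 2.5]
  bp_offset_mmhg: [-15.0, 15.0]
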