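# Default pipeline configuration. Every numeric key carries its unit as a
# suffix. Unknown keys are rejected.
seed: 1
alpha: 0.05
cohort:
  n_per_group: 13
  n_veins_per_eye: 4
  n_arteries_per_eye: 4
  frame_rate_hz: 104
  modulation_frequency_hz: 1000
  pooled_corr_o2a_vv: -0.57
  pooled_corr_o2a_nfl: -0.53
  o2av_sd: 1.3
  vessel_cv: 0.10
  region_cv: 0.05
  phase_noise_sd_rad: 0.01
  track_noise_sd_um: 1
  profile_noise_frac: 0.01
  profile_blur_sd_um: 2
  pixel_pitch_um: 1
  n_spheres_per_vein: 8
  n_frames_per_track: 12
  trace_samples: 192
oximetry:
  tau0_s: 0.000637
  kq_per_mmhg_s: 381
  p50_mmhg: 40
  hill_n: 2.59
  hb_g_per_dl: 15
  hb_capacity_ml_per_g: 1.39
  solubility_ml_per_dl_per_mmhg: 0.003
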