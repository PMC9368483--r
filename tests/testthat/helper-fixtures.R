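# shared fixtures built in code

default_cst <- oximetryConstants()

# small, fast cohort config
tinyConfig <- function(seed = 1L, ...) {
  cohortConfig(seed = seed, n_spheres_per_vein = 3L, trace_samples = 64L, ...)
}

# all raw-signal noise (and optical blur) off: the regime in which the
# measurement chain must invert the forward models exactly
noiselessConfig <- function(seed = 1L, ...) {
  cohortConfig(seed = seed,
               phase_noise_sd_rad = 0, track_noise_sd_um = 0,
               profile_noise_frac = 0, profile_blur_sd_um = 0,
               n_spheres_per_vein = 3L, trace_samples = 64L, ...)
}

# both groups collapsed onto the wild-type means with (almost) zero spread;
# correlation targets go to zero because no between-group separation
# remains, and the o2av SD target scales with the degenerate marginals
degenerateCalibrations <- function() {
  wt <- defaultCalibrations()$WT
  sds0 <- setNames(rep(1e-9, length(wt@sds)), names(wt@sds))
  list(groupCalibration("WT", wt@means, sds0, wt@nAnimals),
       groupCalibration("5XFAD", wt@means, sds0, wt@nAnimals))
}

degenerateConfig <- function(seed = 4L) {
  cohortConfig(calibrations = degenerateCalibrations(), seed = seed,
               vessel_cv = 0, region_cv = 0,
               pooled_corr_o2a_vv = 0, pooled_corr_o2a_nfl = 0,
               o2av_sd = 1e-9)
}

# phase-only trace (no samples)
phaseTrace <- function(phase, f_mod) {
  new("PhosphorescenceTrace", vesselId = "ph", modulationFrequencyHz = f_mod,
      timeS = numeric(0), signal = numeric(0), phaseRad = phase)
}
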