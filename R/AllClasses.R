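#' @import methods
#' @importFrom stats approx coef cor cor.test integrate lm median optim
#'   pnorm pt qnorm qt rnorm sd setNames shapiro.test t.test uniroot var dnorm
NULL

#' Photophysical and blood-gas constants for lifetime oximetry
#'
#' Bundles the constants needed to convert a phosphorescence lifetime into
#' oxygen tension (Stern-Volmer quenching), saturation (Hill dissociation
#' curve) and blood oxygen content (hemoglobin-bound plus dissolved).
#' Units are carried in the slot names. Defaults are literature values for a
#' Pd-porphyrin probe and C57BL/6 mouse hemoglobin; they are deliberately the
#' same for every group so that between-group comparisons are unaffected by
#' their absolute accuracy.
#'
#' @slot tau0S unquenched (zero-oxygen) lifetime, seconds.
#' @slot kqPerMmHgS quenching constant, mmHg^-1 s^-1.
#' @slot p50MmHg oxygen tension at half saturation, mmHg.
#' @slot hillN Hill cooperativity coefficient (dimensionless, >= 1).
#' @slot hbGPerDl hemoglobin concentration, g/dL.
#' @slot hbCapacityMlPerG oxygen binding capacity, mLO2 per g hemoglobin.
#' @slot solubilityMlPerDlPerMmHg plasma oxygen solubility, mLO2/dL/mmHg.
#'
#' @seealso [oximetryConstants()]
#' @export
setClass("OximetryConstants",
  representation(
    tau0S = "numeric",
    kqPerMmHgS = "numeric",
    p50MmHg = "numeric",
    hillN = "numeric",
    hbGPerDl = "numeric",
    hbCapacityMlPerG = "numeric",
    solubilityMlPerDlPerMmHg = "numeric"
  )
)

setValidity("OximetryConstants", function(object) {
  vals <- c(
    tau0_s = object@tau0S, kq_per_mmhg_s = object@kqPerMmHgS,
    p50_mmhg = object@p50MmHg, hill_n = object@hillN,
    hb_g_per_dl = object@hbGPerDl,
    hb_capacity_ml_per_g = object@hbCapacityMlPerG,
    solubility_ml_per_dl_per_mmhg = object@solubilityMlPerDlPerMmHg
  )
  if (any(lengths(list(object@tau0S, object@kqPerMmHgS, object@p50MmHg,
                       object@hillN, object@hbGPerDl, object@hbCapacityMlPerG,
                       object@solubilityMlPerDlPerMmHg)) != 1L))
    return("all constants must be length-1 numeric")
  if (any(!is.finite(vals)) || any(vals <= 0))
    return(sprintf("all constants must be finite and positive (offending: %s)",
                   paste(names(vals)[!is.finite(vals) | vals <= 0],
                         collapse = ", ")))
  if (object@hillN < 1) return("hill_n must be >= 1")
  TRUE
})

#' Per-group calibration of the synthetic cohort generator
#'
#' Holds the target mean and standard deviation of every truth-level metric
#' for one experimental group, plus the nominal group size. The generator
#' draws per-animal metrics so that group sample moments converge to these
#' values. Total retinal blood flow (`trbf`) is stored for reporting but is
#' a derived quantity (sum of per-vein flows), not an independently drawn one.
#'
#' @slot group group label, e.g. "WT" or "5XFAD".
#' @slot means named numeric vector of metric means (units per metric, see
#'   [metricUnits()]).
#' @slot sds named numeric vector of metric SDs, same names as `means`.
#' @slot nAnimals nominal number of animals in the group.
#' @export
setClass("GroupCalibration",
  representation(
    group = "character",
    means = "numeric",
    sds = "numeric",
    nAnimals = "integer"
  )
)

setValidity("GroupCalibration", function(object) {
  if (length(object@group) != 1L || !nzchar(object@group))
    return("group must be a single non-empty label")
  if (is.null(names(object@means)) || is.null(names(object@sds)))
    return("means and sds must be named")
  if (!identical(sort(names(object@means)), sort(names(object@sds))))
    return("means and sds must cover the same metrics")
  if (any(!is.finite(object@means)) || any(object@means <= 0))
    return("all calibration means must be positive and finite")
  if (any(!is.finite(object@sds)) || any(object@sds <= 0))
    return("all calibration SDs must be positive (use a tiny value such as 1e-9 for a degenerate group)")
  if (length(object@nAnimals) != 1L || object@nAnimals < 2L)
    return("nAnimals must be >= 2")
  TRUE
})

#' Configuration of the synthetic cohort generator
#'
#' Describes the study conditions the generator emulates: per-group
#' calibrations, vessel counts per eye, acquisition rates, the pooled
#' (two-group) correlation targets, within-eye variability and the noise
#' model of each raw signal.
#'
#' @slot calibrations list of two [GroupCalibration-class] objects.
#' @slot nVeinsPerEye,nArteriesPerEye vessels per eye.
#' @slot frameRateHz microsphere imaging frame rate (Hz).
#' @slot modulationFrequencyHz excitation modulation frequency (Hz).
#' @slot pooledCorrO2aVv target pooled correlation between arterial oxygen
#'   content and venous velocity across both groups combined.
#' @slot pooledCorrO2aNfl target pooled correlation between arterial oxygen
#'   content and NFL/RGCL thickness.
#' @slot o2avSd target group SD of the arteriovenous oxygen content
#'   difference (mLO2/dL); calibrates the within-animal o2a~o2v correlation.
#' @slot vesselCv within-eye coefficient of variation of per-vessel values
#'   around the per-animal mean.
#' @slot regionCv nasal/temporal relative deviation of layer thickness
#'   around the per-animal mean.
#' @slot phaseNoiseSdRad additive Gaussian phase noise (radians).
#' @slot trackNoiseSdUm Gaussian centroid jitter of microsphere tracks (µm).
#' @slot profileNoiseFrac multiplicative amplitude of intensity noise on
#'   caliber profiles (fraction of peak).
#' @slot profileBlurSdUm Gaussian optical blur of caliber profiles (µm).
#' @slot pixelPitchUm sampling pitch of caliber profiles (µm).
#' @slot nSpheresPerVein microspheres tracked per vein.
#' @slot nFramesPerTrack frames per microsphere track.
#' @slot traceSamples samples per phosphorescence trace.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortConfig",
  representation(
    calibrations = "list",
    nVeinsPerEye = "integer",
    nArteriesPerEye = "integer",
    frameRateHz = "numeric",
    modulationFrequencyHz = "numeric",
    pooledCorrO2aVv = "numeric",
    pooledCorrO2aNfl = "numeric",
    o2avSd = "numeric",
    vesselCv = "numeric",
    regionCv = "numeric",
    phaseNoiseSdRad = "numeric",
    trackNoiseSdUm = "numeric",
    profileNoiseFrac = "numeric",
    profileBlurSdUm = "numeric",
    pixelPitchUm = "numeric",
    nSpheresPerVein = "integer",
    nFramesPerTrack = "integer",
    traceSamples = "integer",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  if (length(object@calibrations) != 2L ||
      !all(vapply(object@calibrations, is, logical(1), "GroupCalibration")))
    return("calibrations must be a list of two GroupCalibration objects")
  g <- vapply(object@calibrations, function(x) x@group, character(1))
  if (anyDuplicated(g)) return("group labels must differ")
  if (object@frameRateHz <= 0) return("frame_rate_hz must be > 0")
  if (object@modulationFrequencyHz <= 0)
    return("modulation_frequency_hz must be > 0")
  for (r in c(object@pooledCorrO2aVv, object@pooledCorrO2aNfl))
    if (!is.finite(r) || abs(r) >= 1)
      return("pooled correlation targets must lie in (-1, 1)")
  if (!is.finite(object@o2avSd) || object@o2avSd <= 0)
    return("o2av_sd must be > 0")
  if (object@nVeinsPerEye < 1L) return("n_veins_per_eye must be >= 1")
  if (object@nArteriesPerEye < 1L) return("n_arteries_per_eye must be >= 1")
  if (object@vesselCv < 0 || object@regionCv < 0)
    return("vessel_cv and region_cv must be >= 0")
  if (object@phaseNoiseSdRad < 0 || object@trackNoiseSdUm < 0 ||
      object@profileNoiseFrac < 0 || object@profileBlurSdUm < 0)
    return("noise standard deviations must be >= 0")
  if (object@pixelPitchUm <= 0) return("pixel_pitch_um must be > 0")
  if (object@nSpheresPerVein < 0L) return("n_spheres_per_vein must be >= 0")
  if (object@nFramesPerTrack < 2L) return("n_frames_per_track must be >= 2")
  if (object@traceSamples < 8L) return("trace_samples must be >= 8")
  TRUE
})

#' Frequency-domain phosphorescence record of one vessel
#'
#' A modulated-excitation emission record from which the phosphorescence
#' lifetime is estimated. The lifetime appears as a phase lag of the emission
#' relative to the excitation reference: `tau = tan(phase) / (2*pi*f_mod)`.
#'
#' @slot vesselId vessel identifier.
#' @slot modulationFrequencyHz excitation modulation frequency (Hz).
#' @slot timeS sample times (s).
#' @slot signal emission samples (a.u.), same length as `timeS`.
#' @slot phaseRad optional precomputed phase (radians); `NA_real_` when the
#'   phase must be estimated from the samples.
#' @export
setClass("PhosphorescenceTrace",
  representation(
    vesselId = "character",
    modulationFrequencyHz = "numeric",
    timeS = "numeric",
    signal = "numeric",
    phaseRad = "numeric"
  )
)

setValidity("PhosphorescenceTrace", function(object) {
  if (object@modulationFrequencyHz <= 0)
    return("modulation frequency must be > 0")
  if (length(object@timeS) != length(object@signal))
    return("timeS and signal must have equal length")
  if (!is.na(object@phaseRad) &&
      (object@phaseRad <= 0 || object@phaseRad >= pi / 2))
    return("precomputed phase must lie in (0, pi/2) for a physical lifetime")
  if (length(object@timeS) == 0L && is.na(object@phaseRad))
    return("trace must carry samples or a precomputed phase")
  TRUE
})

#' Time-stamped positions of one microsphere within one vein
#'
#' @slot trackId,veinId identifiers.
#' @slot frameIndex strictly increasing integer frame indices.
#' @slot xUm,yUm centroid coordinates (µm).
#' @slot frameRateHz acquisition frame rate (Hz).
#' @export
setClass("MicrosphereTrack",
  representation(
    trackId = "character",
    veinId = "character",
    frameIndex = "integer",
    xUm = "numeric",
    yUm = "numeric",
    frameRateHz = "numeric"
  )
)

setValidity("MicrosphereTrack", function(object) {
  n <- length(object@frameIndex)
  if (n < 2L) return("track must span at least 2 frames")
  if (length(object@xUm) != n || length(object@yUm) != n)
    return("frameIndex, xUm and yUm must have equal length")
  if (any(diff(object@frameIndex) <= 0L))
    return("frame indices must be strictly increasing")
  if (object@frameRateHz <= 0) return("frame rate must be > 0")
  TRUE
})

#' Cross-vessel angiographic intensity profile
#'
#' A 1-D intensity cut across a vessel on a uniform position grid; the vessel
#' caliber is the full width at half maximum of the background-subtracted
#' profile.
#'
#' @slot vesselId vessel identifier.
#' @slot positionUm uniform position grid (µm).
#' @slot intensity intensities (a.u.).
#' @export
setClass("CaliberProfile",
  representation(
    vesselId = "character",
    positionUm = "numeric",
    intensity = "numeric"
  )
)

setValidity("CaliberProfile", function(object) {
  n <- length(object@positionUm)
  if (n < 8L) return("profile needs at least 8 samples")
  if (length(object@intensity) != n)
    return("positionUm and intensity must have equal length")
  dp <- diff(object@positionUm)
  if (any(dp <= 0)) return("positions must be strictly increasing")
  if (diff(range(dp)) > 1e-9 * mean(dp))
    return("position grid must be uniform")
  TRUE
})

#' One synthetic animal: truth-level metrics and raw-style signals
#'
#' @slot animalId identifier.
#' @slot group group label.
#' @slot truth named numeric vector of per-animal truth metrics (drawn and
#'   derived).
#' @slot vessels data.frame of per-vessel truths (vessel_id, type,
#'   diameter_um, velocity_mm_s, content_ml_dl, po2_mmhg).
#' @slot traces list of [PhosphorescenceTrace-class], one per vessel.
#' @slot tracks list (one entry per vein) of lists of
#'   [MicrosphereTrack-class].
#' @slot profiles list of [CaliberProfile-class], one per vessel.
#' @slot boundariesNasal,boundariesTemporal layer boundary depths (µm) from
#'   the inner limiting membrane outward.
#' @export
setClass("SyntheticAnimal",
  representation(
    animalId = "character",
    group = "character",
    truth = "numeric",
    vessels = "data.frame",
    traces = "list",
    tracks = "list",
    profiles = "list",
    boundariesNasal = "numeric",
    boundariesTemporal = "numeric"
  )
)

setValidity("SyntheticAnimal", function(object) {
  for (b in list(object@boundariesNasal, object@boundariesTemporal)) {
    if (length(b)) {
      if (abs(b[1]) > 1e-12) return("first boundary depth must be 0")
      if (any(diff(b) <= 0))
        return("boundary depths must be strictly increasing")
    }
  }
  TRUE
})

#' A synthetic two-group cohort
#'
#' Container returned by [generateCohort()]: the animals (with raw signals),
#' the generating configuration, and the truth-level per-animal table.
#'
#' @slot animals list of [SyntheticAnimal-class].
#' @slot config the [CohortConfig-class] used.
#' @slot truthTable data.frame of per-animal truth metrics (one row per
#'   animal; includes derived TRBF, O2AV, DO2, MO2, OEF).
#' @export
setClass("SyntheticCohort",
  representation(
    animals = "list",
    config = "CohortConfig",
    truthTable = "data.frame"
  )
)

#' Cohort statistics report
#'
#' Per-metric group summaries, two-group pooled-variance t-tests, pooled
#' Pearson correlations, post-hoc power results, advisory normality checks
#' and the number of hypothesis tests performed (no multiplicity correction
#' is applied).
#'
#' @slot summaries data.frame: metric, group, n, mean, sd.
#' @slot tests data.frame: metric, t, df, p, significant.
#' @slot correlations data.frame: pair, n, r, p.
#' @slot powers data.frame: design, label, effect, n, power.
#' @slot normality data.frame: metric, group, n, shapiro_p (advisory only).
#' @slot alpha significance level used.
#' @slot nTests number of p-values computed.
#' @export
setClass("CohortStatsReport",
  representation(
    summaries = "data.frame",
    tests = "data.frame",
    correlations = "data.frame",
    powers = "data.frame",
    normality = "data.frame",
    alpha = "numeric",
    nTests = "integer"
  )
)
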