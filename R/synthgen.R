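## Synthetic two-group cohort generator --------------------------------------

#' Pooled two-group correlation implied by a within-group correlation
#'
#' For a two-group mixture in which metrics x and y have group means/SDs from
#' the calibrations and a common within-group correlation `w`, the pooled
#' (groups-combined) correlation is
#' `(sum_g l_g w sx_g sy_g + cov_between) / sqrt(varx * vary)` with mixture
#' weights `l_g = n_g / N`. Between-group separation alone already induces a
#' pooled correlation; `w` supplies the remainder.
#'
#' @param w within-group correlation (common to both groups).
#' @param calibrations list of two [GroupCalibration-class] objects.
#' @param metric_x,metric_y metric names.
#' @param n_per_group integer vector of length 2 (defaults to the calibrated
#'   group sizes).
#' @return pooled correlation in (-1, 1).
#' @export
pooledCorrelation <- function(w, calibrations, metric_x, metric_y,
                              n_per_group = NULL) {
  if (is.null(n_per_group))
    n_per_group <- vapply(calibrations, function(x) x@nAnimals, integer(1))
  l <- n_per_group / sum(n_per_group)
  mx <- vapply(calibrations, function(g) g@means[[metric_x]], numeric(1))
  my <- vapply(calibrations, function(g) g@means[[metric_y]], numeric(1))
  sx <- vapply(calibrations, function(g) g@sds[[metric_x]], numeric(1))
  sy <- vapply(calibrations, function(g) g@sds[[metric_y]], numeric(1))
  mxb <- sum(l * mx); myb <- sum(l * my)
  cv <- sum(l * w * sx * sy) + sum(l * (mx - mxb) * (my - myb))
  vx <- sum(l * sx^2) + sum(l * (mx - mxb)^2)
  vy <- sum(l * sy^2) + sum(l * (my - myb)^2)
  cv / sqrt(vx * vy)
}

#' Calibrate the within-group correlation for a pooled target
#'
#' One-dimensional root search for the within-group correlation `w` such
#' that [pooledCorrelation()] equals `target` at the calibrated group
#' means/SDs. Errors if no `w` in (-1, 1) can reach the target (the
#' between-group component bounds the attainable pooled range).
#'
#' @param target desired pooled correlation.
#' @inheritParams pooledCorrelation
#' @return within-group correlation in (-1, 1).
#' @examples
#' calibrateWithinGroupCorrelation(-0.57, defaultCalibrations(), "o2a", "v_v")
#' @export
calibrateWithinGroupCorrelation <- function(target, calibrations,
                                            metric_x, metric_y,
                                            n_per_group = NULL) {
  f <- function(w) pooledCorrelation(w, calibrations, metric_x, metric_y,
                                     n_per_group) - target
  lo <- -1 + 1e-9; hi <- 1 - 1e-9
  if (f(lo) * f(hi) > 0)
    stop("pooled correlation target ", target, " for ", metric_x, " vs ",
         metric_y, " is unattainable with any within-group correlation")
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# Latent normal (mu, sigma) whose >0 truncation has mean m and sd s.
# For m/s >= 6 the truncation is numerically irrelevant and (m, s) is
# returned unchanged.
.truncMatch <- function(m, s) {
  if (m / s >= 6) return(c(mu = m, sigma = s))
  momf <- function(par) {
    mu <- par[1]; sig <- exp(par[2])
    a <- -mu / sig
    lam <- exp(dnorm(a, log = TRUE) - pnorm(a, lower.tail = FALSE,
                                            log.p = TRUE))
    tm <- mu + sig * lam
    tv <- sig^2 * (1 + a * lam - lam^2)
    (tm - m)^2 + (sqrt(tv) - s)^2
  }
  fit <- optim(c(m, log(s)), momf, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 10000))
  if (fit$value > 1e-10)
    stop("could not moment-match a positive truncated normal to mean ", m,
         " and sd ", s)
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Build a cohort generator configuration
#'
#' The defaults encode the study conditions of a two-group (wild-type vs
#' 5XFAD) retinal physiology experiment: 13 animals per group, 4 veins and
#' 4 arteries per eye, microsphere imaging at 104 Hz, and pooled
#' correlation targets of -0.57 (arterial oxygen content vs venous velocity)
#' and -0.53 (arterial oxygen content vs NFL/RGCL thickness). The
#' within-group correlations needed to reach the pooled targets are solved at
#' build time by [calibrateWithinGroupCorrelation()].
#'
#' @param calibrations list of two [GroupCalibration-class] objects.
#' @param n_veins_per_eye,n_arteries_per_eye vessels per eye.
#' @param frame_rate_hz microsphere frame rate (Hz).
#' @param modulation_frequency_hz excitation modulation frequency (Hz).
#' @param pooled_corr_o2a_vv,pooled_corr_o2a_nfl pooled correlation targets.
#' @param o2av_sd target group SD of the arteriovenous content difference
#'   (mLO2/dL); sets the within-animal o2a~o2v correlation.
#' @param vessel_cv within-eye CV of vessel values around the animal mean.
#' @param region_cv nasal/temporal relative deviation of layer thickness.
#' @param phase_noise_sd_rad,track_noise_sd_um,profile_noise_frac raw-signal
#'   noise levels.
#' @param profile_blur_sd_um optical blur of caliber profiles (µm).
#' @param pixel_pitch_um profile sampling pitch (µm).
#' @param n_spheres_per_vein,n_frames_per_track,trace_samples signal sizes.
#' @param seed integer RNG seed.
#' @return a [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(seed = 1)
#' @export
cohortConfig <- function(calibrations = defaultCalibrations(),
                         n_veins_per_eye = 4L,
                         n_arteries_per_eye = 4L,
                         frame_rate_hz = 104,
                         modulation_frequency_hz = 1000,
                         pooled_corr_o2a_vv = -0.57,
                         pooled_corr_o2a_nfl = -0.53,
                         o2av_sd = 1.3,
                         vessel_cv = 0.10,
                         region_cv = 0.05,
                         phase_noise_sd_rad = 0.01,
                         track_noise_sd_um = 1,
                         profile_noise_frac = 0.01,
                         profile_blur_sd_um = 2,
                         pixel_pitch_um = 1,
                         n_spheres_per_vein = 8L,
                         n_frames_per_track = 12L,
                         trace_samples = 192L,
                         seed = 1L) {
  new("CohortConfig",
      calibrations = calibrations,
      nVeinsPerEye = as.integer(n_veins_per_eye),
      nArteriesPerEye = as.integer(n_arteries_per_eye),
      frameRateHz = frame_rate_hz,
      modulationFrequencyHz = modulation_frequency_hz,
      pooledCorrO2aVv = pooled_corr_o2a_vv,
      pooledCorrO2aNfl = pooled_corr_o2a_nfl,
      o2avSd = o2av_sd,
      vesselCv = vessel_cv,
      regionCv = region_cv,
      phaseNoiseSdRad = phase_noise_sd_rad,
      trackNoiseSdUm = track_noise_sd_um,
      profileNoiseFrac = profile_noise_frac,
      profileBlurSdUm = profile_blur_sd_um,
      pixelPitchUm = pixel_pitch_um,
      nSpheresPerVein = as.integer(n_spheres_per_vein),
      nFramesPerTrack = as.integer(n_frames_per_track),
      traceSamples = as.integer(trace_samples),
      seed = as.integer(seed))
}

# within-group correlation matrix over the drawn metrics. Three calibrated
# correlations, all anchored at o2a (a star structure: the remaining pairs
# are conditionally independent given o2a, so their correlations are
# products of loadings):
#   o2a ~ v_v       from the pooled-correlation target,
#   o2a ~ nfl_rgcl  from the pooled-correlation target,
#   o2a ~ o2v       from the arteriovenous-difference SD of the first
#                   group's calibration (var(o2av) = sa^2 + sv^2 -
#                   2 rho sa sv), which is far below the independent-draw
#                   value in calibrated cohorts.
.withinCorrMatrix <- function(config) {
  m <- .drawnMetrics
  R <- diag(length(m)); dimnames(R) <- list(m, m)
  w1 <- calibrateWithinGroupCorrelation(config@pooledCorrO2aVv,
                                        config@calibrations, "o2a", "v_v")
  w2 <- calibrateWithinGroupCorrelation(config@pooledCorrO2aNfl,
                                        config@calibrations, "o2a",
                                        "nfl_rgcl")
  cal1 <- config@calibrations[[1L]]
  sa <- cal1@sds[["o2a"]]; sv <- cal1@sds[["o2v"]]
  w3 <- (sa^2 + sv^2 - config@o2avSd^2) / (2 * sa * sv)
  if (abs(w3) >= 1)
    stop("o2av_sd = ", config@o2avSd, " is incompatible with the o2a/o2v ",
         "group SDs (implied correlation ", round(w3, 3), ")")
  load <- c(v_v = w1, nfl_rgcl = w2, o2v = w3)
  for (k in names(load))
    R["o2a", k] <- R[k, "o2a"] <- load[[k]]
  pairs <- utils::combn(names(load), 2L)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    R[a, b] <- R[b, a] <- load[[a]] * load[[b]]
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12)
    stop("within-group correlation matrix is not positive semi-definite; ",
         "relax the pooled correlation or o2av_sd targets")
  R
}

# draw n per-animal truth vectors for one group: Gaussian copula with
# moment-matched >0-truncated-normal marginals. Metrics whose truncation
# probability is negligible reduce exactly to correlated normals; metrics
# with appreciable mass below zero (e.g. venous oxygen content) get the
# truncated-normal quantile map, so every marginal is strictly positive with
# exactly the calibrated mean and SD, and no rejection step is needed.
.drawGroupTruth <- function(cal, R, n) {
  m <- .drawnMetrics
  lat <- vapply(m, function(k) .truncMatch(cal@means[[k]], cal@sds[[k]]),
                numeric(2))
  mu <- lat["mu", ]; sig <- lat["sigma", ]
  Z <- matrix(rnorm(n * length(m)), n) %*% chol(R)
  X <- matrix(NA_real_, n, length(m), dimnames = list(NULL, m))
  for (j in seq_along(m)) {
    p0 <- pnorm(-mu[j] / sig[j])
    if (p0 < 1e-12) {
      X[, j] <- mu[j] + sig[j] * Z[, j]
    } else {
      u <- p0 + pnorm(Z[, j]) * (1 - p0)
      X[, j] <- mu[j] + sig[j] * qnorm(u)
    }
  }
  X
}

# centered multiplicative deviations: k values around `center` with CV `cv`
# whose mean is exactly `center`; all strictly positive
.centeredAround <- function(center, k, cv) {
  if (k == 1L || cv == 0) return(rep(center, k))
  repeat {
    z <- rnorm(k)
    z <- z - mean(z)
    v <- center * (1 + cv * z)
    if (all(v > 0)) return(v)
  }
}

#' Synthesize a frequency-domain phosphorescence trace for a known PO2
#'
#' Forward model of lifetime oximetry: the Stern-Volmer relation gives the
#' lifetime `tau = tau0 / (1 + kq * tau0 * PO2)`; the emission then lags the
#' modulated excitation by `phase = arctan(2*pi*f_mod*tau)`. Gaussian phase
#' noise (if any) is added before the sinusoid is sampled, so a noiseless
#' trace inverts exactly through [estimateLifetime()].
#'
#' @param po2_truth true oxygen tension (mmHg), >= 0.
#' @param modulation_frequency_hz excitation modulation frequency (Hz).
#' @param constants an [OximetryConstants-class].
#' @param phase_noise_sd_rad SD of additive phase noise (radians).
#' @param n_samples samples in the trace.
#' @param n_cycles modulation cycles covered.
#' @param amplitude,offset sinusoid amplitude and DC offset (a.u.).
#' @param vessel_id identifier stored on the trace.
#' @return a [PhosphorescenceTrace-class].
#' @examples
#' tr <- synthesizePhaseTrace(30)
#' lifetimeToPO2(estimateLifetime(tr))
#' @export
synthesizePhaseTrace <- function(po2_truth,
                                 modulation_frequency_hz = 1000,
                                 constants = oximetryConstants(),
                                 phase_noise_sd_rad = 0,
                                 n_samples = 192L,
                                 n_cycles = 4,
                                 amplitude = 1,
                                 offset = 1.5,
                                 vessel_id = "vessel") {
  stopifnot(length(po2_truth) == 1L, is.finite(po2_truth), po2_truth >= 0)
  t0 <- constants@tau0S
  tau <- t0 / (1 + constants@kqPerMmHgS * t0 * po2_truth)
  phase <- atan(2 * pi * modulation_frequency_hz * tau)
  if (phase_noise_sd_rad > 0)
    phase <- phase + rnorm(1L, 0, phase_noise_sd_rad)
  phase <- min(max(phase, 1e-9), pi / 2 - 1e-9)
  tt <- (seq_len(n_samples) - 1L) *
    (n_cycles / (modulation_frequency_hz * n_samples))
  sig <- offset + amplitude *
    cos(2 * pi * modulation_frequency_hz * tt - phase)
  new("PhosphorescenceTrace", vesselId = vessel_id,
      modulationFrequencyHz = modulation_frequency_hz,
      timeS = tt, signal = sig, phaseRad = NA_real_)
}

#' Synthesize microsphere tracks for a known blood velocity
#'
#' Each sphere advances along a straight vessel axis by
#' `velocity / frame_rate` per frame (converted to µm), with optional
#' isotropic Gaussian centroid jitter. Track orientation and origin are
#' random, so velocity estimation must be rotation-invariant.
#'
#' @param velocity_truth true velocity (mm/s), > 0.
#' @param n_spheres number of spheres; 0 returns an empty list.
#' @param frame_rate_hz acquisition rate (Hz).
#' @param noise_sd_um centroid jitter SD (µm).
#' @param n_frames frames per track (>= 2).
#' @param vein_id identifier stored on the tracks.
#' @return list of [MicrosphereTrack-class].
#' @examples
#' trk <- synthesizeTracks(10.4, n_spheres = 1, frame_rate_hz = 104)
#' trackVelocity(trk[[1]])
#' @export
synthesizeTracks <- function(velocity_truth,
                             n_spheres = 8L,
                             frame_rate_hz = 104,
                             noise_sd_um = 0,
                             n_frames = 12L,
                             vein_id = "vein") {
  stopifnot(length(velocity_truth) == 1L, is.finite(velocity_truth),
            velocity_truth > 0, frame_rate_hz > 0, n_frames >= 2L)
  if (n_spheres == 0L) return(list())
  step_um <- velocity_truth / frame_rate_hz * 1000
  lapply(seq_len(n_spheres), function(i) {
    theta <- runif(1L, 0, 2 * pi)
    origin <- runif(2L, -50, 50)
    d <- step_um * (seq_len(n_frames) - 1L)
    x <- origin[1L] + cos(theta) * d
    y <- origin[2L] + sin(theta) * d
    if (noise_sd_um > 0) {
      x <- x + rnorm(n_frames, 0, noise_sd_um)
      y <- y + rnorm(n_frames, 0, noise_sd_um)
    }
    new("MicrosphereTrack", trackId = sprintf("%s_s%02d", vein_id, i),
        veinId = vein_id, frameIndex = seq_len(n_frames),
        xUm = x, yUm = y, frameRateHz = frame_rate_hz)
  })
}

#' Synthesize an angiographic cross-vessel intensity profile
#'
#' The vessel lumen is a boxcar of width `diameter_truth`. With optical blur
#' the profile is the boxcar convolved with a Gaussian (error-function
#' edges); without blur it is the pixel-integrated boxcar, a trapezoid whose
#' linear edge ramps span two pixel pitches so that linear interpolation of
#' the half-maximum crossings recovers the true edges exactly for any grid
#' offset. In both cases the noise-free full width at half maximum equals
#' the true diameter (to within edge-interaction terms that are negligible
#' when `diameter >> blur`).
#'
#' @param diameter_truth true lumen diameter (µm); must be at least two
#'   pixel pitches.
#' @param pixel_pitch_um sampling pitch (µm).
#' @param blur_sd_um Gaussian blur SD (µm); 0 for the pixel-limited case.
#' @param noise_frac additive intensity noise SD as a fraction of amplitude.
#' @param background,amplitude intensity baseline and peak height (a.u.).
#' @param center_offset_um vessel center relative to the grid center; `NULL`
#'   draws a random sub-pixel offset.
#' @param vessel_id identifier stored on the profile.
#' @return a [CaliberProfile-class].
#' @examples
#' pr <- synthesizeCaliberProfile(30, blur_sd_um = 0, center_offset_um = 0)
#' profileDiameter(pr)
#' @export
synthesizeCaliberProfile <- function(diameter_truth,
                                     pixel_pitch_um = 1,
                                     blur_sd_um = 2,
                                     noise_frac = 0,
                                     background = 0.1,
                                     amplitude = 1,
                                     center_offset_um = NULL,
                                     vessel_id = "vessel") {
  stopifnot(length(diameter_truth) == 1L, is.finite(diameter_truth))
  if (diameter_truth < 2 * pixel_pitch_um)
    stop("diameter ", diameter_truth, " um is below two pixel pitches (",
         2 * pixel_pitch_um, " um): profile would be degenerate")
  if (is.null(center_offset_um))
    center_offset_um <- runif(1L, -0.5, 0.5) * pixel_pitch_um
  half_span <- diameter_truth + 8 * blur_sd_um + 10 * pixel_pitch_um
  x <- seq(-half_span, half_span, by = pixel_pitch_um)
  u <- x - center_offset_um
  if (blur_sd_um > 0) {
    core <- pnorm((diameter_truth / 2 - u) / blur_sd_um) -
      pnorm((-diameter_truth / 2 - u) / blur_sd_um)
  } else {
    p <- pixel_pitch_um
    core <- pmin(pmax((diameter_truth / 2 + p - abs(u)) / (2 * p), 0), 1)
  }
  intensity <- background + amplitude * core
  if (noise_frac > 0)
    intensity <- intensity + rnorm(length(x), 0, noise_frac * amplitude)
  new("CaliberProfile", vesselId = vessel_id,
      positionUm = x, intensity = intensity)
}

# vessel-level truths for one animal, and its derived metrics
.drawAnimalVessels <- function(truth, config, constants) {
  ka <- config@nArteriesPerEye; kv <- config@nVeinsPerEye
  cv <- config@vesselCv
  art_content <- .centeredAround(truth[["o2a"]], ka, cv)
  ven_content <- .centeredAround(truth[["o2v"]], kv, cv)
  ven_vel <- .centeredAround(truth[["v_v"]], kv, cv)
  art_diam <- .centeredAround(truth[["d_a"]], ka, cv)
  ven_diam <- .centeredAround(truth[["d_v"]], kv, cv)
  vessels <- data.frame(
    vessel_id = c(sprintf("A%d", seq_len(ka)), sprintf("V%d", seq_len(kv))),
    type = c(rep("artery", ka), rep("vein", kv)),
    diameter_um = c(art_diam, ven_diam),
    velocity_mm_s = c(rep(NA_real_, ka), ven_vel),
    content_ml_dl = c(art_content, ven_content),
    stringsAsFactors = FALSE)
  vessels$po2_mmhg <- contentToPO2(vessels$content_ml_dl, constants)
  vessels
}

.deriveAnimalMetrics <- function(truth, vessels) {
  vv <- vessels[vessels$type == "vein", ]
  trbf <- totalFlow(veinFlow(vv$velocity_mm_s, vv$diameter_um))
  o2av <- truth[["o2a"]] - truth[["o2v"]]
  dm <- deliveryMetabolism(trbf, truth[["o2a"]], o2av)
  irl <- truth[["nfl_rgcl"]] + truth[["ipl"]] + truth[["inl"]]
  trt_hist <- irl + truth[["opl"]] + truth[["onl"]] + truth[["prl"]]
  c(truth,
    o2av = o2av, trbf = trbf,
    do2 = dm[["do2"]], mo2 = dm[["mo2"]], oef = dm[["oef"]],
    irl = irl, trt_hist = trt_hist)
}

.layerOrder <- c("nfl_rgcl", "ipl", "inl", "opl", "onl", "prl")

.animalBoundaries <- function(truth, config) {
  layers <- truth[.layerOrder]
  eps <- rnorm(length(layers), 0, config@regionCv)
  nasal <- unname(layers * (1 + eps))
  temporal <- unname(layers * (1 - eps))
  list(nasal = cumsum(c(0, nasal)), temporal = cumsum(c(0, temporal)))
}

.generateAnimals <- function(config, n_per_group, signals, constants) {
  validObject(config)
  set.seed(config@seed)
  R <- .withinCorrMatrix(config)
  if (is.null(n_per_group))
    n_per_group <- vapply(config@calibrations, function(x) x@nAnimals,
                          integer(1))
  if (length(n_per_group) == 1L)
    n_per_group <- rep(n_per_group, 2L)
  animals <- list()
  for (gi in seq_along(config@calibrations)) {
    cal <- config@calibrations[[gi]]
    X <- .drawGroupTruth(cal, R, n_per_group[gi])
    for (ai in seq_len(nrow(X))) {
      truth <- X[ai, ]
      vessels <- .drawAnimalVessels(truth, config, constants)
      truth <- .deriveAnimalMetrics(truth, vessels)
      bnd <- .animalBoundaries(truth, config)
      an <- new("SyntheticAnimal",
                animalId = sprintf("%s_%02d", cal@group, ai),
                group = cal@group,
                truth = truth,
                vessels = vessels,
                traces = list(), tracks = list(), profiles = list(),
                boundariesNasal = bnd$nasal,
                boundariesTemporal = bnd$temporal)
      if (signals) an <- .attachSignals(an, config, constants)
      animals[[length(animals) + 1L]] <- an
    }
  }
  animals
}

.attachSignals <- function(animal, config, constants) {
  vs <- animal@vessels
  animal@traces <- lapply(seq_len(nrow(vs)), function(i)
    synthesizePhaseTrace(vs$po2_mmhg[i],
                         modulation_frequency_hz = config@modulationFrequencyHz,
                         constants = constants,
                         phase_noise_sd_rad = config@phaseNoiseSdRad,
                         n_samples = config@traceSamples,
                         vessel_id = vs$vessel_id[i]))
  names(animal@traces) <- vs$vessel_id
  veins <- vs[vs$type == "vein", ]
  animal@tracks <- lapply(seq_len(nrow(veins)), function(i)
    synthesizeTracks(veins$velocity_mm_s[i],
                     n_spheres = config@nSpheresPerVein,
                     frame_rate_hz = config@frameRateHz,
                     noise_sd_um = config@trackNoiseSdUm,
                     n_frames = config@nFramesPerTrack,
                     vein_id = veins$vessel_id[i]))
  names(animal@tracks) <- veins$vessel_id
  animal@profiles <- lapply(seq_len(nrow(vs)), function(i)
    synthesizeCaliberProfile(vs$diameter_um[i],
                             pixel_pitch_um = config@pixelPitchUm,
                             blur_sd_um = config@profileBlurSdUm,
                             noise_frac = config@profileNoiseFrac,
                             vessel_id = vs$vessel_id[i]))
  names(animal@profiles) <- vs$vessel_id
  animal
}

.truthTable <- function(animals) {
  rows <- lapply(animals, function(a)
    cbind(data.frame(animal_id = a@animalId, group = a@group,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(a@truth))))
  do.call(rbind, rows)
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-animal truth metrics from group-calibrated (positivity-
#' respecting) multivariate normals, distributes them over vessels with a
#' configurable within-eye CV (vessel values are centered so their mean is
#' exactly the animal truth), derives flow and oxygen delivery metrics, and
#' synthesizes the raw-style signals: a phosphorescence trace per vessel,
#' microsphere tracks per vein, a caliber profile per vessel and
#' nasal/temporal layer boundary depths. Fully deterministic given the
#' config seed.
#'
#' @param config a [CohortConfig-class].
#' @param n_per_group animals per group (length 1 or 2); default from the
#'   calibrations.
#' @param constants an [OximetryConstants-class] used for the
#'   content-to-tension inversion and the trace forward model.
#' @return a [SyntheticCohort-class].
#' @examples
#' coh <- generateCohort(cohortConfig(seed = 7), n_per_group = 2)
#' cohortTruth(coh)[, 1:6]
#' @export
generateCohort <- function(config = cohortConfig(), n_per_group = NULL,
                           constants = oximetryConstants()) {
  animals <- .generateAnimals(config, n_per_group, signals = TRUE,
                              constants = constants)
  new("SyntheticCohort", animals = animals, config = config,
      truthTable = .truthTable(animals))
}

#' Generate truth-level metrics only (no raw signals)
#'
#' Fast path used for large-sample calibration checks: identical statistical
#' model to [generateCohort()] but skips signal synthesis.
#'
#' @inheritParams generateCohort
#' @return data.frame, one row per animal.
#' @export
generateTruthTable <- function(config = cohortConfig(), n_per_group = NULL,
                               constants = oximetryConstants()) {
  .truthTable(.generateAnimals(config, n_per_group, signals = FALSE,
                               constants = constants))
}

#' @describeIn generateCohort extract the truth-level per-animal table.
#' @param cohort a [SyntheticCohort-class].
#' @export
cohortTruth <- function(cohort) cohort@truthTable

#' @describeIn generateCohort extract the animal list.
#' @export
cohortAnimals <- function(cohort) cohort@animals
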