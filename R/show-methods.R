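## show() methods --------------------------------------------------------------

setMethod("show", "OximetryConstants", function(object) {
  cat("OximetryConstants\n",
      sprintf("  tau0: %g us, kq: %g /mmHg/s\n",
              object@tau0S * 1e6, object@kqPerMmHgS),
      sprintf("  dissociation: P50 %g mmHg, Hill n %g\n",
              object@p50MmHg, object@hillN),
      sprintf("  Hb %g g/dL x %g mLO2/g; solubility %g mLO2/dL/mmHg\n",
              object@hbGPerDl, object@hbCapacityMlPerG,
              object@solubilityMlPerDlPerMmHg), sep = "")
})

setMethod("show", "GroupCalibration", function(object) {
  cat(sprintf("GroupCalibration '%s' (n = %d), %d metrics\n",
              object@group, object@nAnimals, length(object@means)))
  df <- data.frame(mean = object@means, sd = object@sds)
  print(df)
})

setMethod("show", "CohortConfig", function(object) {
  g <- vapply(object@calibrations, function(x)
    sprintf("%s(n=%d)", x@group, x@nAnimals), character(1))
  cat("CohortConfig\n",
      "  groups: ", paste(g, collapse = " vs "), "\n",
      sprintf("  vessels/eye: %d arteries, %d veins; frame rate %g Hz; f_mod %g Hz\n",
              object@nArteriesPerEye, object@nVeinsPerEye,
              object@frameRateHz, object@modulationFrequencyHz),
      sprintf("  pooled corr targets: o2a~v_v %.2f, o2a~nfl_rgcl %.2f\n",
              object@pooledCorrO2aVv, object@pooledCorrO2aNfl),
      sprintf("  seed: %d\n", object@seed), sep = "")
})

setMethod("show", "PhosphorescenceTrace", function(object) {
  cat(sprintf(
    "PhosphorescenceTrace '%s': %d samples at f_mod %g Hz%s\n",
    object@vesselId, length(object@timeS), object@modulationFrequencyHz,
    if (is.na(object@phaseRad)) ""
    else sprintf(" (precomputed phase %.4f rad)", object@phaseRad)))
})

setMethod("show", "MicrosphereTrack", function(object) {
  cat(sprintf("MicrosphereTrack '%s' in %s: %d frames at %g Hz\n",
              object@trackId, object@veinId, length(object@frameIndex),
              object@frameRateHz))
})

setMethod("show", "CaliberProfile", function(object) {
  cat(sprintf("CaliberProfile '%s': %d samples, pitch %.3g um\n",
              object@vesselId, length(object@positionUm),
              diff(object@positionUm[1:2])))
})

setMethod("show", "SyntheticAnimal", function(object) {
  cat(sprintf("SyntheticAnimal '%s' (%s): %d vessels, %d traces, %d veins with tracks\n",
              object@animalId, object@group, nrow(object@vessels),
              length(object@traces), length(object@tracks)))
})

setMethod("show", "SyntheticCohort", function(object) {
  tb <- table(vapply(object@animals, function(a) a@group, character(1)))
  cat("SyntheticCohort:",
      paste(sprintf("%s n=%d", names(tb), tb), collapse = ", "),
      sprintf("| seed %d\n", object@config@seed))
})

setMethod("show", "CohortStatsReport", function(object) {
  cat(sprintf("CohortStatsReport: %d metrics summarised, %d tests (alpha = %g)\n",
              length(unique(object@summaries$metric)), object@nTests,
              object@alpha))
  if (nrow(object@tests)) {
    sig <- object@tests$metric[object@tests$significant]
    cat("  significant:",
        if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  }
  if (nrow(object@correlations)) {
    cat("  correlations:\n")
    for (i in seq_len(nrow(object@correlations)))
      cat(sprintf("    %s: r = %.2f (n = %d, p = %.3g)\n",
                  object@correlations$pair[i], object@correlations$r[i],
                  object@correlations$n[i], object@correlations$p[i]))
  }
  if (nrow(object@powers)) {
    cat("  post-hoc power:\n")
    for (i in seq_len(nrow(object@powers)))
      cat(sprintf("    %s [%s]: %.0f%%\n", object@powers$label[i],
                  object@powers$design[i], 100 * object@powers$power[i]))
  }
})
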