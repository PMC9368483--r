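## Measurement chain: raw signals -> per-vessel -> per-animal metrics ---------

#' Measure one synthetic animal from its raw signals
#'
#' Runs the full measurement chain: lifetime estimation and Stern-Volmer /
#' dissociation-curve conversion per vessel trace, FWHM caliber per profile,
#' per-vein velocity from microsphere tracks, then the eye-level aggregates
#' (mean diameters and velocity, oxygen contents, per-vein flows, TRBF,
#' DO2/MO2/OEF) and the morphometry (region-averaged layer thicknesses).
#'
#' @param animal a [SyntheticAnimal-class].
#' @param constants an [OximetryConstants-class].
#' @return list with `vessels` (per-vessel data.frame) and `metrics` (named
#'   numeric vector of per-animal measured metrics).
#' @export
measureAnimal <- function(animal, constants = oximetryConstants()) {
  vs <- animal@vessels
  n <- nrow(vs)
  diam <- vapply(seq_len(n), function(i)
    profileDiameter(animal@profiles[[vs$vessel_id[i]]]), numeric(1))
  # a noisy phase can imply a lifetime beyond the unquenched limit for a
  # vessel at near-zero oxygen tension; such a vessel yields no physical
  # PO2 and is dropped from the eye averages rather than aborting the eye
  po2 <- vapply(seq_len(n), function(i)
    tryCatch(
      lifetimeToPO2(estimateLifetime(animal@traces[[vs$vessel_id[i]]]),
                    constants),
      error = function(e) {
        warning("vessel ", vs$vessel_id[i], " of ", animal@animalId,
                ": ", conditionMessage(e), "; recorded as missing",
                call. = FALSE)
        NA_real_
      }), numeric(1))
  content <- rep(NA_real_, n)
  content[!is.na(po2)] <- oxygenContent(po2[!is.na(po2)], constants)
  is_vein <- vs$type == "vein"
  vel <- rep(NA_real_, n)
  vel[is_vein] <- vapply(vs$vessel_id[is_vein], function(vid)
    veinVelocity(animal@tracks[[vid]]), numeric(1))

  vessels <- data.frame(
    animal_id = animal@animalId, group = animal@group,
    vessel_id = vs$vessel_id, type = vs$type,
    diameter_um = diam, velocity_mm_s = vel,
    po2_mmhg = po2, content_ml_dl = content,
    stringsAsFactors = FALSE)

  oc <- oxygenContents(content[!is_vein], content[is_vein])
  trbf <- totalFlow(veinFlow(vel[is_vein], diam[is_vein]))
  dm <- deliveryMetabolism(trbf, oc[["o2a"]], oc[["o2av"]])
  thick <- regionAverage(layerThicknesses(animal@boundariesNasal),
                         layerThicknesses(animal@boundariesTemporal))
  metrics <- c(
    d_a = mean(diam[!is_vein]), d_v = mean(diam[is_vein]),
    v_v = mean(vel[is_vein]), trbf = trbf,
    oc, dm, thick,
    trt_oct = animal@truth[["trt_oct"]],
    animal@truth[c("abeta42_retina", "abeta40_retina",
                   "abeta42_brain", "abeta40_brain")])
  list(vessels = vessels, metrics = metrics)
}

#' Measure a synthetic cohort
#'
#' Applies [measureAnimal()] to every animal and assembles the results as a
#' [SummarizedExperiment::SummarizedExperiment]: one assay `"measured"`
#' (metrics x animals), group labels in `colData`, and the per-vessel table,
#' the truth table and the generating config in `metadata`.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param constants an [OximetryConstants-class].
#' @return a `SummarizedExperiment`.
#' @examples
#' coh <- generateCohort(cohortConfig(seed = 3), n_per_group = 2)
#' se <- measureCohort(coh)
#' animalTable(se)[, 1:5]
#' @export
measureCohort <- function(cohort, constants = oximetryConstants()) {
  res <- lapply(cohort@animals, measureAnimal, constants = constants)
  mat <- vapply(res, function(r) r$metrics,
                numeric(length(res[[1L]]$metrics)))
  colnames(mat) <- vapply(cohort@animals, function(a) a@animalId,
                          character(1))
  groups <- vapply(cohort@animals, function(a) a@group, character(1))
  perVessel <- do.call(rbind, lapply(res, function(r) r$vessels))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(measured = mat),
    colData = S4Vectors::DataFrame(animal_id = colnames(mat),
                                   group = groups),
    metadata = list(perVessel = perVessel,
                    truth = cohort@truthTable,
                    config = cohort@config))
}

#' Per-animal measured metrics as a data.frame
#'
#' @param se a `SummarizedExperiment` from [measureCohort()].
#' @return data.frame with `animal_id`, `group` and one column per metric.
#' @export
animalTable <- function(se) {
  mat <- SummarizedExperiment::assay(se, "measured")
  cd <- SummarizedExperiment::colData(se)
  cbind(data.frame(animal_id = cd$animal_id, group = cd$group,
                   stringsAsFactors = FALSE),
        as.data.frame(t(mat)))
}

#' Per-vessel measured table of a cohort experiment
#'
#' @param se a `SummarizedExperiment` from [measureCohort()].
#' @return data.frame of per-vessel measurements.
#' @export
vesselTable <- function(se) S4Vectors::metadata(se)$perVessel
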