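## Metric dictionary ---------------------------------------------------------

# metrics drawn per animal by the generator (trbf is derived, not drawn)
.drawnMetrics <- c("d_a", "d_v", "v_v", "o2a", "o2v",
                   "nfl_rgcl", "ipl", "inl", "opl", "onl", "prl",
                   "trt_oct",
                   "abeta42_retina", "abeta40_retina",
                   "abeta42_brain", "abeta40_brain")

.derivedMetrics <- c("o2av", "trbf", "do2", "mo2", "oef",
                     "irl", "trt_hist")

#' Units of the per-animal metrics
#'
#' @return named character vector mapping metric name to unit.
#' @examples
#' metricUnits()[["trbf"]]
#' @export
metricUnits <- function() {
  c(d_a = "um", d_v = "um", v_v = "mm/s", trbf = "uL/min",
    o2a = "mLO2/dL", o2v = "mLO2/dL", o2av = "mLO2/dL",
    do2 = "nLO2/min", mo2 = "nLO2/min", oef = "",
    nfl_rgcl = "um", ipl = "um", inl = "um", opl = "um", onl = "um",
    prl = "um", irl = "um", trt_hist = "um", trt_oct = "um",
    abeta42_retina = "pg/mg", abeta40_retina = "pg/mg",
    abeta42_brain = "pg/mg", abeta40_brain = "pg/mg")
}

#' Group calibration constructor
#'
#' @param group group label.
#' @param means,sds named numeric vectors over the drawn metrics (see
#'   [drawnMetrics()]) plus optionally `trbf` (stored for reporting only).
#' @param n_animals nominal group size.
#' @return a [GroupCalibration-class].
#' @export
groupCalibration <- function(group, means, sds, n_animals) {
  new("GroupCalibration", group = group,
      means = means[order(names(means))],
      sds = sds[order(names(sds))],
      nAnimals = as.integer(n_animals))
}

#' Names of the metrics drawn per animal
#' @return character vector.
#' @export
drawnMetrics <- function() .drawnMetrics

#' Default study calibrations: wild-type and 5XFAD groups at 3 months
#'
#' Group means and SDs of the hemodynamic metrics (arterial/venous diameter,
#' venous velocity), vascular oxygen contents, histological layer
#' thicknesses, OCT total retinal thickness and amyloid-beta levels for
#' 13-animal wild-type and 5XFAD transgenic cohorts. For layers reported as
#' unchanged in the transgenic group (IPL, INL, PRL) the wild-type values are
#' reused. TRBF is carried for reporting but is derived from per-vein
#' velocity and diameter by the generator rather than drawn.
#'
#' @return named list with elements `WT` and `5XFAD`
#'   ([GroupCalibration-class]).
#' @examples
#' defaultCalibrations()$WT
#' @export
defaultCalibrations <- function() {
  wt_means <- c(
    d_a = 27, d_v = 30, v_v = 10.5, trbf = 1.73,
    o2a = 6.5, o2v = 2.8,
    nfl_rgcl = 16.2, ipl = 36.7, inl = 31.0, opl = 14.6, onl = 44.3,
    prl = 29.1, trt_oct = 242,
    abeta42_retina = 2.4, abeta40_retina = 2.5,
    abeta42_brain = 1.4, abeta40_brain = 9.3)
  wt_sds <- c(
    d_a = 2, d_v = 3, v_v = 3.1, trbf = 0.52,
    o2a = 1.4, o2v = 1.9,
    nfl_rgcl = 4.2, ipl = 4.0, inl = 4.4, opl = 2.0, onl = 4.6,
    prl = 3.9, trt_oct = 11,
    abeta42_retina = 0.8, abeta40_retina = 0.2,
    abeta42_brain = 0.5, abeta40_brain = 3.0)
  fad_means <- c(
    d_a = 27, d_v = 33, v_v = 6.6, trbf = 1.63,
    o2a = 7.8, o2v = 4.3,
    nfl_rgcl = 15.1, ipl = 36.7, inl = 31.0, opl = 17.2, onl = 47.6,
    prl = 29.1, trt_oct = 235,
    abeta42_retina = 5.4, abeta40_retina = 4.9,
    abeta42_brain = 6.1, abeta40_brain = 8.2)
  fad_sds <- c(
    d_a = 3, d_v = 3, v_v = 1.4, trbf = 0.50,
    o2a = 1.2, o2v = 1.6,
    nfl_rgcl = 2.8, ipl = 4.0, inl = 4.4, opl = 1.3, onl = 2.7,
    prl = 3.9, trt_oct = 6,
    abeta42_retina = 2.6, abeta40_retina = 1.5,
    abeta42_brain = 1.9, abeta40_brain = 1.2)
  list(WT = groupCalibration("WT", wt_means, wt_sds, 13L),
       `5XFAD` = groupCalibration("5XFAD", fad_means, fad_sds, 13L))
}
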