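## Retinal layer morphometry --------------------------------------------------

#' Layer thicknesses from boundary depths
#'
#' Boundary depths run from the inner limiting membrane (depth 0) outward
#' through the outer edges of NFL/RGCL, IPL, INL, OPL, ONL and PRL; each
#' layer thickness is the difference of consecutive depths. The combined
#' nerve fiber / ganglion cell layer is reported via the inner-retina
#' identity `NFL/RGCL = IRL - (IPL + INL)`, where IRL is the inner retina
#' (ILM to the outer INL boundary). The thickness record also carries
#' `irl` and the histological total `trt_hist` (sum of all six layers, equal
#' to the outermost depth).
#'
#' @param depths numeric vector of 7 strictly increasing boundary depths
#'   (µm), first element 0.
#' @return named numeric vector with elements `nfl_rgcl`, `ipl`, `inl`,
#'   `opl`, `onl`, `prl`, `irl`, `trt_hist`.
#' @examples
#' layerThicknesses(cumsum(c(0, 16.2, 36.7, 31.0, 14.6, 44.3, 29.1)))
#' @export
layerThicknesses <- function(depths) {
  depths <- unname(depths)
  if (length(depths) != 7L)
    stop("expected 7 boundary depths (ILM plus 6 outer layer edges)")
  if (abs(depths[1L]) > 1e-9)
    stop("first boundary (inner limiting membrane) must be at depth 0")
  if (any(diff(depths) <= 0))
    stop("boundary depths must be strictly increasing from inner to outer retina")
  th <- diff(depths)
  irl <- depths[4L]                     # ILM -> outer INL edge
  nfl_rgcl <- irl - (th[2L] + th[3L])   # IRL - (IPL + INL)
  c(nfl_rgcl = nfl_rgcl, ipl = th[2L], inl = th[3L],
    opl = th[4L], onl = th[5L], prl = th[6L],
    irl = irl, trt_hist = depths[7L])
}

#' Average thickness records over nasal and temporal regions
#'
#' Element-wise arithmetic mean of two thickness records. If one region is
#' missing (`NULL`), the other is returned unchanged with a warning — a
#' robustness fallback for low-quality eyes.
#'
#' @param nasal,temporal named numeric vectors from [layerThicknesses()].
#' @return named numeric vector of region-averaged thicknesses.
#' @export
regionAverage <- function(nasal, temporal) {
  if (is.null(nasal) && is.null(temporal))
    stop("both regions are missing")
  if (is.null(nasal) || is.null(temporal)) {
    warning("one region missing; using the single available region")
    return(if (is.null(nasal)) temporal else nasal)
  }
  if (!identical(names(nasal), names(temporal)))
    stop("thickness records must have identical layer names")
  (nasal + temporal) / 2
}

#' Fraction of the inner retina occupied by the NFL/RGCL
#'
#' `100 * nfl_rgcl / irl` (percent). At wild-type calibration means this is
#' approximately 19%.
#'
#' @param record named numeric vector with `nfl_rgcl` and `irl` elements
#'   (as produced by [layerThicknesses()]).
#' @return percentage.
#' @examples
#' innerRetinaFraction(c(nfl_rgcl = 16.2, irl = 16.2 + 36.7 + 31.0))
#' @export
innerRetinaFraction <- function(record) {
  if (!all(c("nfl_rgcl", "irl") %in% names(record)))
    stop("record must contain nfl_rgcl and irl")
  if (record[["irl"]] <= 0) stop("inner retina thickness must be > 0")
  100 * record[["nfl_rgcl"]] / record[["irl"]]
}
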