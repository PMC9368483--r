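## Per-eye flow and oxygen delivery metrics ----------------------------------

#' Volumetric blood flow of one vein
#'
#' `Q = V * (pi/4) * D^2`, with the unit conversion
#' `mm/s * um^2 -> uL/min` equal to `6e-5` (1 mm/s * 1 um^2 =
#' 1e-15 m^3/s = 6e-5 uL/min). Vectorised over veins.
#'
#' @param v velocity (mm/s), >= 0.
#' @param d diameter (µm), > 0.
#' @return flow (µL/min).
#' @examples
#' veinFlow(10.5, 30)  # 0.4453
#' @export
veinFlow <- function(v, d) {
  stopifnot(is.numeric(v), is.numeric(d))
  if (any(!is.finite(v)) || any(v < 0)) stop("velocity must be >= 0")
  if (any(!is.finite(d)) || any(d <= 0)) stop("diameter must be > 0")
  v * (pi / 4) * d^2 * 6e-5
}

#' Total retinal blood flow
#'
#' Arithmetic sum of per-vein flows. An empty vector yields the
#' missing-value sentinel `NA_real_` with a warning.
#'
#' @param flows per-vein flows (µL/min).
#' @return TRBF (µL/min).
#' @export
totalFlow <- function(flows) {
  if (length(flows) == 0L) {
    warning("no vein flows available; returning NA")
    return(NA_real_)
  }
  sum(flows)
}

#' Eye-level arterial and venous oxygen contents
#'
#' Arterial (o2a) and venous (o2v) contents are unweighted means over the
#' eye's arteries and veins; the arteriovenous difference is
#' `o2av = o2a - o2v`. A negative difference is physiologically pathological
#' and is flagged with a warning but returned.
#'
#' @param arterial,venous per-vessel oxygen contents (mLO2/dL).
#' @return named numeric vector `c(o2a, o2v, o2av)`, `NA` when either class
#'   of vessel is missing.
#' @examples
#' oxygenContents(6.5, 2.8)  # o2av = 3.7
#' @export
oxygenContents <- function(arterial, venous) {
  arterial <- arterial[is.finite(arterial)]
  venous <- venous[is.finite(venous)]
  if (length(arterial) == 0L || length(venous) == 0L) {
    warning("need at least one artery and one vein; returning NA")
    return(c(o2a = NA_real_, o2v = NA_real_, o2av = NA_real_))
  }
  o2a <- mean(arterial); o2v <- mean(venous)
  o2av <- o2a - o2v
  if (o2av < 0)
    warning("negative arteriovenous oxygen content difference (",
            format(o2av), " mLO2/dL)")
  c(o2a = o2a, o2v = o2v, o2av = o2av)
}

#' Oxygen delivery, metabolism and extraction fraction
#'
#' `DO2 = TRBF * O2A` and `MO2 = TRBF * O2AV`, with the unit conversion
#' `uL/min * mLO2/dL -> nLO2/min` equal to 10; `OEF = MO2 / DO2`, which
#' reduces algebraically to `O2AV / O2A` and is therefore independent of
#' flow. These are computed per eye first; group means of DO2/MO2/OEF are
#' means of per-eye values, not products of group means.
#'
#' @param trbf total retinal blood flow (µL/min), >= 0.
#' @param o2a arterial oxygen content (mLO2/dL).
#' @param o2av arteriovenous content difference (mLO2/dL).
#' @return named numeric vector `c(do2, mo2, oef)` (nLO2/min, nLO2/min,
#'   dimensionless); `oef` is `NA` when `do2` is 0 (and `mo2` is then
#'   required to be 0 as well).
#' @examples
#' deliveryMetabolism(1.73, 6.5, 3.7)
#' @export
deliveryMetabolism <- function(trbf, o2a, o2av) {
  stopifnot(length(trbf) == 1L, length(o2a) == 1L, length(o2av) == 1L)
  if (!is.finite(trbf) || trbf < 0) stop("trbf must be >= 0")
  do2 <- trbf * o2a * 10
  mo2 <- trbf * o2av * 10
  if (do2 == 0 && mo2 != 0)
    stop("zero oxygen delivery with nonzero metabolism is inconsistent")
  oef <- if (do2 > 0) mo2 / do2 else NA_real_
  c(do2 = do2, mo2 = mo2, oef = oef)
}
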