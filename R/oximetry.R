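#' Construct the oximetry constants block
#'
#' Defaults describe a Pd-porphyrin phosphorescent probe (unquenched lifetime
#' 637 µs, quenching constant 381 mmHg^-1 s^-1) and the C57BL/6 mouse
#' hemoglobin dissociation curve (P50 = 40 mmHg, Hill n = 2.59), with
#' 15 g/dL hemoglobin binding 1.39 mLO2/g and a plasma solubility of
#' 0.003 mLO2/dL/mmHg.
#'
#' @param tau0_s unquenched lifetime (s).
#' @param kq_per_mmhg_s quenching constant (mmHg^-1 s^-1).
#' @param p50_mmhg half-saturation oxygen tension (mmHg).
#' @param hill_n Hill coefficient.
#' @param hb_g_per_dl hemoglobin concentration (g/dL).
#' @param hb_capacity_ml_per_g O2 binding capacity (mLO2/g).
#' @param solubility_ml_per_dl_per_mmhg dissolved O2 solubility.
#' @return an [OximetryConstants-class] object.
#' @examples
#' oximetryConstants()
#' @export
oximetryConstants <- function(tau0_s = 637e-6,
                              kq_per_mmhg_s = 381,
                              p50_mmhg = 40,
                              hill_n = 2.59,
                              hb_g_per_dl = 15,
                              hb_capacity_ml_per_g = 1.39,
                              solubility_ml_per_dl_per_mmhg = 0.003) {
  new("OximetryConstants",
      tau0S = as.numeric(tau0_s),
      kqPerMmHgS = as.numeric(kq_per_mmhg_s),
      p50MmHg = as.numeric(p50_mmhg),
      hillN = as.numeric(hill_n),
      hbGPerDl = as.numeric(hb_g_per_dl),
      hbCapacityMlPerG = as.numeric(hb_capacity_ml_per_g),
      solubilityMlPerDlPerMmHg = as.numeric(solubility_ml_per_dl_per_mmhg))
}

#' @describeIn oximetryConstants accessor for the unquenched lifetime (s).
#' @param object an `OximetryConstants` object.
#' @export
tau0 <- function(object) object@tau0S

#' Estimate the phosphorescence lifetime of a trace
#'
#' For a sampled trace, the phase lag of the emission relative to the
#' excitation reference is estimated by linear least squares on cosine and
#' sine regressors at the modulation frequency (the sampled signal is exactly
#' in their span, so the noiseless fit is exact); a trace carrying a
#' precomputed phase is used directly. The lifetime follows as
#' `tau = tan(phase) / (2 * pi * f_mod)`.
#'
#' @param trace a [PhosphorescenceTrace-class].
#' @return lifetime in seconds.
#' @examples
#' tr <- synthesizePhaseTrace(30, vessel_id = "a1")
#' estimateLifetime(tr)
#' @export
setGeneric("estimateLifetime", function(trace) standardGeneric("estimateLifetime"))

#' @rdname estimateLifetime
#' @export
setMethod("estimateLifetime", "PhosphorescenceTrace", function(trace) {
  f <- trace@modulationFrequencyHz
  phi <- trace@phaseRad
  if (is.na(phi)) {
    w <- 2 * pi * f * trace@timeS
    X <- cbind(1, cos(w), sin(w))
    beta <- qr.coef(qr(X), trace@signal)
    # signal model: A*cos(w - phi) = A*cos(phi)*cos(w) + A*sin(phi)*sin(w)
    phi <- atan2(beta[3L], beta[2L])
  }
  if (!is.finite(phi) || phi <= 0 || phi >= pi / 2)
    stop("estimated phase ", format(phi),
         " rad is outside (0, pi/2): non-physical lifetime")
  unname(tan(phi) / (2 * pi * f))
})

#' Convert a phosphorescence lifetime to oxygen tension (Stern-Volmer)
#'
#' Inverts the Stern-Volmer quenching relation `1/tau = 1/tau0 + kq * PO2`:
#' `PO2 = (tau0/tau - 1) / (kq * tau0)`. PO2 is strictly decreasing in the
#' lifetime and zero at the unquenched lifetime. Lifetimes marginally above
#' `tau0` (within `clamp_tol`, a noise allowance) are clamped to PO2 = 0;
#' larger values are an error, since emission cannot outlive the unquenched
#' state.
#'
#' @param tau lifetime (s).
#' @param constants an [OximetryConstants-class].
#' @param clamp_tol relative tolerance above `tau0` clamped to PO2 = 0.
#' @return oxygen tension (mmHg).
#' @examples
#' cst <- oximetryConstants()
#' lifetimeToPO2(tau0(cst), cst)        # 0 mmHg
#' lifetimeToPO2(tau0(cst) / 2, cst)    # 1 / (kq * tau0)
#' @export
lifetimeToPO2 <- function(tau, constants = oximetryConstants(),
                          clamp_tol = 0.02) {
  stopifnot(is.numeric(tau))
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("lifetime must be positive and finite")
  t0 <- constants@tau0S
  if (any(tau > t0 * (1 + clamp_tol)))
    stop("lifetime exceeds the unquenched lifetime tau0 by more than ",
         100 * clamp_tol, "%: not a physical phosphorescence signal")
  po2 <- (t0 / tau - 1) / (constants@kqPerMmHgS * t0)
  pmax(po2, 0)
}

#' Hemoglobin oxygen saturation from oxygen tension (Hill curve)
#'
#' `SO2 = PO2^n / (P50^n + PO2^n)`; exactly 0.5 at `PO2 = P50`, 0 at zero
#' tension, approaching (never reaching) 1 at high tension.
#'
#' @param po2 oxygen tension (mmHg), vectorised.
#' @inheritParams lifetimeToPO2
#' @return saturation fraction in \[0, 1).
#' @examples
#' po2ToSO2(40)   # 0.5 at the default P50
#' @export
po2ToSO2 <- function(po2, constants = oximetryConstants()) {
  stopifnot(is.numeric(po2))
  if (any(!is.finite(po2)) || any(po2 < 0))
    stop("po2 must be >= 0 and finite")
  n <- constants@hillN
  # log-domain ratio keeps the tails accurate
  r <- exp(n * (log(po2) - log(constants@p50MmHg)))
  ifelse(po2 == 0, 0, r / (1 + r))
}

#' Blood oxygen content from oxygen tension
#'
#' Total content is hemoglobin-bound plus physically dissolved oxygen:
#' `content = capacity * [Hb] * SO2(PO2) + alpha * PO2` (mLO2/dL). Strictly
#' increasing in PO2.
#'
#' @inheritParams po2ToSO2
#' @return oxygen content (mLO2/dL).
#' @examples
#' oxygenContent(30)
#' @export
oxygenContent <- function(po2, constants = oximetryConstants()) {
  so2 <- po2ToSO2(po2, constants)
  constants@hbCapacityMlPerG * constants@hbGPerDl * so2 +
    constants@solubilityMlPerDlPerMmHg * po2
}

#' Oxygen tension from blood oxygen content (numerical inverse)
#'
#' Inverts [oxygenContent()] by bisection; the content curve is strictly
#' increasing so the root is unique. Used by the cohort generator to place
#' vessel oxygen tensions consistent with calibrated content targets.
#'
#' @param content oxygen content (mLO2/dL), vectorised.
#' @inheritParams lifetimeToPO2
#' @param po2_max upper search bound (mmHg).
#' @param tol absolute bisection tolerance (mmHg).
#' @return oxygen tension (mmHg).
#' @examples
#' contentToPO2(oxygenContent(25))  # 25
#' @export
contentToPO2 <- function(content, constants = oximetryConstants(),
                         po2_max = 1000, tol = 1e-9) {
  stopifnot(is.numeric(content))
  if (any(!is.finite(content)) || any(content < 0))
    stop("content must be >= 0 and finite")
  cmax <- oxygenContent(po2_max, constants)
  if (any(content > cmax))
    stop("content ", format(max(content)),
         " mLO2/dL exceeds the attainable maximum ", format(cmax),
         " at po2_max = ", po2_max, " mmHg")
  lo <- rep(0, length(content)); hi <- rep(po2_max, length(content))
  while (max(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    below <- oxygenContent(mid, constants) < content
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  out <- (lo + hi) / 2
  out[content == 0] <- 0
  out
}

#' Full oxygen state of a vessel
#'
#' Convenience wrapper returning tension, saturation and content together.
#'
#' @inheritParams po2ToSO2
#' @return data.frame with columns `po2_mmhg`, `so2`, `content_ml_dl`.
#' @export
oxygenState <- function(po2, constants = oximetryConstants()) {
  data.frame(po2_mmhg = po2,
             so2 = po2ToSO2(po2, constants),
             content_ml_dl = oxygenContent(po2, constants))
}
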