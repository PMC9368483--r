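## Microsphere velocimetry and angiographic caliber estimation ---------------

#' Blood velocity from one microsphere track
#'
#' Positions are projected onto the principal axis of the track (the vessel
#' is treated as locally straight), and the velocity is the magnitude of the
#' least-squares slope of the projected displacement against time. The
#' estimate is invariant to rigid rotation of the coordinate frame and to a
#' uniform temporal offset.
#'
#' @param track a [MicrosphereTrack-class].
#' @return velocity in mm/s (nonnegative).
#' @examples
#' trk <- synthesizeTracks(6.6, n_spheres = 1, frame_rate_hz = 104)[[1]]
#' trackVelocity(trk)  # 6.6
#' @export
setGeneric("trackVelocity", function(track) standardGeneric("trackVelocity"))

#' @rdname trackVelocity
#' @export
setMethod("trackVelocity", "MicrosphereTrack", function(track) {
  t_s <- track@frameIndex / track@frameRateHz
  if (diff(range(t_s)) <= 0) stop("track spans zero time")
  xy <- cbind(track@xUm, track@yUm)
  xyc <- sweep(xy, 2L, colMeans(xy))
  ax <- eigen(crossprod(xyc), symmetric = TRUE)$vectors[, 1L]
  proj <- xyc %*% ax
  tc <- t_s - mean(t_s)
  slope_um_s <- sum(tc * proj) / sum(tc^2)
  abs(slope_um_s) / 1000
})

#' Mean venous velocity from the tracks of one vein
#'
#' Unweighted mean of per-track velocities. An empty track list yields the
#' missing-value sentinel `NA_real_` with a warning, so downstream eye-level
#' averaging can drop the vein explicitly.
#'
#' @param tracks list of [MicrosphereTrack-class] for one vein.
#' @return velocity in mm/s, or `NA_real_` when no track is available.
#' @export
veinVelocity <- function(tracks) {
  if (length(tracks) == 0L) {
    warning("no microsphere tracks for this vein; returning NA")
    return(NA_real_)
  }
  mean(vapply(tracks, trackVelocity, numeric(1)))
}

#' Vessel diameter as the full width at half maximum of a profile
#'
#' The background is the median intensity of the profile edges (outer 10%
#' of samples on each side), the peak is the profile maximum, and the
#' diameter is the distance between the two linearly interpolated crossings
#' of `background + (peak - background)/2` on either side of the peak. The
#' estimate is invariant to affine intensity scaling.
#'
#' @param profile a [CaliberProfile-class].
#' @return diameter in µm.
#' @examples
#' pr <- synthesizeCaliberProfile(30, blur_sd_um = 0, center_offset_um = 0)
#' profileDiameter(pr)  # 30
#' @export
setGeneric("profileDiameter", function(profile) standardGeneric("profileDiameter"))

#' @rdname profileDiameter
#' @export
setMethod("profileDiameter", "CaliberProfile", function(profile) {
  x <- profile@positionUm
  y <- profile@intensity
  n <- length(x)
  ne <- max(2L, floor(0.1 * n))
  bg <- median(c(y[seq_len(ne)], y[seq.int(n - ne + 1L, n)]))
  ipk <- which.max(y)
  peak <- y[ipk]
  if (!(peak > bg) || (peak - bg) < 1e-9 * max(abs(peak), 1))
    stop("profile has no dominant peak above background")
  half <- bg + (peak - bg) / 2

  cross <- function(idx_from, idx_to) {
    idx <- if (idx_from <= idx_to) seq.int(idx_from, idx_to)
           else seq.int(idx_from, idx_to, by = -1L)
    below <- which(y[idx] < half)
    if (length(below) == 0L) return(NA_real_)
    i2 <- idx[below[1L]]                     # first sample below half
    i1 <- i2 + sign(idx_from - idx_to)       # neighbour toward the peak
    x[i1] + (half - y[i1]) * (x[i2] - x[i1]) / (y[i2] - y[i1])
  }
  xl <- cross(ipk, 1L)
  xr <- cross(ipk, n)
  if (is.na(xl) || is.na(xr))
    stop("no half-maximum crossing found on one side of the peak")
  xr - xl
})
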