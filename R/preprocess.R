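# Intensity normalization, in-plane resizing, training-time augmentation.
#
# Normalization is percentile-based and per series per study: I_min = I_3,
# I_max = I_97 + alpha * (I_97 - I_3) with alpha = 0 for ADC and alpha = 1
# for DWI, so that strongly hyperintense restricted-diffusion voxels on DWI
# are not saturated. Intensities are clamped to [I_min, I_max] and scaled
# linearly to [0, 1].

#' Per-volume intensity percentiles
#'
#' Computes the 3rd and 97th percentiles of the intensity distribution over
#' all voxels of a series (brain and background alike), using the
#' linear-interpolation percentile definition.
#'
#' @param volume 3D array with at least one finite voxel.
#' @return numeric(2): \code{c(I3 = ..., I97 = ...)}.
#' @export
computePercentiles <- function(volume) {
  v <- volume[is.finite(volume)]
  if (!length(v)) stop("volume has no finite voxels")
  q <- quantile(v, c(0.03, 0.97), names = FALSE, type = 7)
  c(I3 = q[1], I97 = q[2])
}

#' Percentile intensity normalization
#'
#' Maps intensities to [0, 1]: voxels below \eqn{I_{min} = I_3} map to 0,
#' voxels above \eqn{I_{max} = I_{97} + \alpha (I_{97} - I_3)} map to 1, and
#' the rest map linearly. The map is monotone non-decreasing. A constant
#' volume maps to all zero.
#'
#' @param volume 3D array of finite intensities.
#' @param alpha non-negative series constant: 0 for ADC, 1 for DWI.
#' @param I3,I97 optional precomputed percentiles (defaults from
#'   [computePercentiles()]).
#' @return array of the same dimensions with values in [0, 1].
#' @examples
#' v <- array(seq(0, 1000, length.out = 8 * 8 * 4), c(8, 8, 4))
#' nv <- normalizeIntensities(v, alpha = 0)
#' stopifnot(min(nv) == 0, max(nv) == 1)
#' @export
normalizeIntensities <- function(volume, alpha, I3 = NULL, I97 = NULL) {
  if (alpha < 0) stop("alpha must be non-negative")
  if (any(!is.finite(volume))) stop("volume must be finite")
  if (is.null(I3) || is.null(I97)) {
    p <- computePercentiles(volume)
    I3 <- p[[1]]
    I97 <- p[[2]]
  }
  Imin <- I3
  Imax <- I97 + alpha * (I97 - I3)
  if (Imax <= Imin) {
    # degenerate (constant) intensity distribution
    return(array(0, dim = dim(volume)))
  }
  out <- (pmin(pmax(volume, Imin), Imax) - Imin) / (Imax - Imin)
  array(out, dim = dim(volume))
}

#' Resize the axial plane of a volume
#'
#' Resamples each axial slice to \code{targetXY}; the number of slices is
#' never changed (no z resampling). Images use bilinear interpolation; masks
#' use nearest neighbour so the output stays binary.
#'
#' @param volume 3D array.
#' @param targetXY integer(2) output in-plane grid.
#' @param isMask logical.
#' @return array of dim \code{c(targetXY, dim(volume)[3])}.
#' @export
resizeInplane <- function(volume, targetXY, isMask = FALSE) {
  if (any(targetXY <= 0)) stop("target dimensions must be positive")
  d <- dim(volume)
  if (d[1] == targetXY[1] && d[2] == targetXY[2]) return(volume)
  out <- EBImage::resize(volume, w = targetXY[1], h = targetXY[2],
                         filter = if (isMask) "none" else "bilinear")
  out <- array(out, dim = c(targetXY[1], targetXY[2], d[3]))
  if (isMask) out <- array(as.numeric(out > 0.5), dim = dim(out))
  out
}

#' Construct an AugmentationConfig
#'
#' @param maxRotationDeg in-plane rotation bound in degrees (default 10).
#' @param maxTranslationFrac x/y translation bound as a fraction of the
#'   image dimensions (default 0.10).
#' @param scaleRange in-plane scale factor range (default 0.9-1.1).
#' @param intensityOffsetFrac bound of the random offset applied to I_min
#'   and I_max, as a fraction of I97 - I3 (default 0.2).
#' @return an \code{\linkS4class{AugmentationConfig}}.
#' @export
augmentationConfig <- function(maxRotationDeg = 10,
                               maxTranslationFrac = 0.10,
                               scaleRange = c(0.9, 1.1),
                               intensityOffsetFrac = 0.2) {
  new("AugmentationConfig", maxRotationDeg = maxRotationDeg,
      maxTranslationFrac = maxTranslationFrac,
      scaleRange = as.numeric(scaleRange),
      intensityOffsetFrac = intensityOffsetFrac)
}

# one shared in-plane affine applied to every slice of a volume.
# theta in radians, scale s, translation t (voxels); the content is rotated
# about the slice centre, scaled, then shifted. Out-of-bounds voxels are
# filled with 0 (background after normalization).
applyInplaneAffine <- function(volume, theta, s, tx, ty, isMask = FALSE) {
  d <- dim(volume)
  cx <- (d[1] + 1) / 2
  cy <- (d[2] + 1) / 2
  # inverse map: output pixel -> input pixel
  ct <- cos(theta); st <- sin(theta)
  xo <- seq_len(d[1]); yo <- seq_len(d[2])
  gx <- matrix(xo, d[1], d[2]) - cx - tx
  gy <- matrix(yo, d[1], d[2], byrow = TRUE) - cy - ty
  sx <- (ct * gx + st * gy) / s + cx
  sy <- (-st * gx + ct * gy) / s + cy
  out <- array(0, dim = d)
  if (isMask) {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2]
    idx <- cbind(ix[ok], iy[ok])
    for (z in seq_len(d[3])) {
      sl <- matrix(0, d[1], d[2])
      sl[ok] <- volume[, , z][idx]
      out[, , z] <- sl
    }
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    inb <- function(ix, iy) ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2]
    corners <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
    wts <- list((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
    for (z in seq_len(d[3])) {
      sl <- volume[, , z]
      acc <- matrix(0, d[1], d[2])
      for (k in 1:4) {
        ix <- x0 + corners[[k]][1]; iy <- y0 + corners[[k]][2]
        ok <- inb(ix, iy)
        v <- matrix(0, d[1], d[2])
        v[ok] <- sl[cbind(ix[ok], iy[ok])]
        acc <- acc + wts[[k]] * v
      }
      out[, , z] <- acc
    }
  }
  out
}

#' Training-time augmentation of a normalized study
#'
#' One geometric draw (rotation up to +/-\code{maxRotationDeg} in plane,
#' x/y translation up to \code{maxTranslationFrac} of the image dimensions,
#' a shared x/y scale factor from \code{scaleRange}) is applied identically
#' to the DWI, ADC and mask volumes; the mask moves by nearest neighbour and
#' stays binary. Independently per image series, a random offset of up to
#' \code{intensityOffsetFrac * (I97 - I3)} in either direction is applied to
#' the \eqn{I_{min}} and \eqn{I_{max}} that scaled the intensities —
#' equivalent, on the already-normalized volume, to shifting by
#' \eqn{-\delta / (I_{max} - I_{min})} and re-clamping to [0, 1], which is
#' how it is realized here.
#'
#' @param dwi,adc normalized volumes (values in [0, 1]).
#' @param mask optional binary volume.
#' @param config an \code{\linkS4class{AugmentationConfig}}.
#' @param alphaDwi,alphaAdc the normalization alpha used per series (the
#'   offset in normalized units is scaled by 1/(1 + alpha)).
#' @return list: \code{dwi}, \code{adc}, \code{mask} (or NULL) and
#'   \code{draw}, a record of every sampled parameter.
#' @export
augmentStudy <- function(dwi, adc, mask = NULL,
                         config = augmentationConfig(),
                         alphaDwi = 1, alphaAdc = 0) {
  d <- dim(dwi)
  theta <- runif(1, -config@maxRotationDeg, config@maxRotationDeg) * pi / 180
  tx <- runif(1, -config@maxTranslationFrac, config@maxTranslationFrac) * d[1]
  ty <- runif(1, -config@maxTranslationFrac, config@maxTranslationFrac) * d[2]
  s <- runif(1, config@scaleRange[1], config@scaleRange[2])
  offD <- runif(1, -config@intensityOffsetFrac, config@intensityOffsetFrac)
  offA <- runif(1, -config@intensityOffsetFrac, config@intensityOffsetFrac)
  identityDraw <- theta == 0 && tx == 0 && ty == 0 && s == 1
  tf <- function(v, isMask) {
    if (identityDraw) v else applyInplaneAffine(v, theta, s, tx, ty, isMask)
  }
  dwi2 <- pmin(pmax(tf(dwi, FALSE) - offD / (1 + alphaDwi), 0), 1)
  adc2 <- pmin(pmax(tf(adc, FALSE) - offA / (1 + alphaAdc), 0), 1)
  dim(dwi2) <- d
  dim(adc2) <- d
  mask2 <- if (is.null(mask)) NULL else tf(mask, TRUE)
  list(dwi = dwi2, adc = adc2, mask = mask2,
       draw = list(thetaDeg = theta * 180 / pi, tx = tx, ty = ty, scale = s,
                   dwiOffsetFrac = offD, adcOffsetFrac = offA))
}

#' Normalize and resize a study into a network input array
#'
#' @param record a \code{\linkS4class{StudyRecord}}.
#' @param targetXY in-plane network grid.
#' @param channels \code{"both"}, \code{"dwi_only"} or \code{"adc_only"}.
#' @return array of dim \code{c(targetXY, nz, channels)} in [0, 1]; DWI is
#'   channel 1 and ADC channel 2 when both are used.
#' @export
prepareInput <- function(record, targetXY = c(256L, 256L),
                         channels = "both") {
  nz <- dim(record@dwi)[3]
  mk <- function(v, alpha) resizeInplane(normalizeIntensities(v, alpha),
                                         targetXY)
  chans <- switch(channels,
    both = list(mk(record@dwi, 1), mk(record@adc, 0)),
    dwi_only = list(mk(record@dwi, 1)),
    adc_only = list(mk(record@adc, 0)),
    stop("channels must be both, dwi_only or adc_only"))
  out <- array(0, dim = c(targetXY[1], targetXY[2], nz, length(chans)))
  for (i in seq_along(chans)) out[, , , i] <- chans[[i]]
  out
}
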