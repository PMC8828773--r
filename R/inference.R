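# Runtime model: preprocess a study, run the forward pass, derive the
# study-level call and the predicted infarct volume.

#' Construct an InferenceConfig
#'
#' @param operatingPoint probability threshold (default 0.5, the operating
#'   point balancing sensitivity and specificity). The comparison is
#'   inclusive: probability >= operating point calls positive.
#' @param channels \code{"both"} (default), \code{"dwi_only"} or
#'   \code{"adc_only"} for single-series ablation models.
#' @param targetXY in-plane grid for the forward pass.
#' @return an \code{\linkS4class{InferenceConfig}}.
#' @export
inferenceConfig <- function(operatingPoint = 0.5, channels = "both",
                            targetXY = c(256L, 256L)) {
  new("InferenceConfig", operatingPoint = operatingPoint,
      channels = channels, targetXY = as.integer(targetXY))
}

#' Study-level call from a probability map
#'
#' The study probability is the maximum voxel probability (the global
#' max-pooling classification head); the study is positive iff it reaches
#' the operating point. Raising the operating point never flips a negative
#' call to positive.
#'
#' @param probMap probability volume in [0, 1].
#' @param operatingPoint threshold in (0, 1).
#' @return list: \code{studyProbability}, \code{label}.
#' @export
classifyProbMap <- function(probMap, operatingPoint = 0.5) {
  s <- classificationHead(probMap)
  list(studyProbability = s,
       label = if (s >= operatingPoint) "positive" else "negative")
}

#' Predicted lesion volume in mL
#'
#' Aggregates supra-threshold voxels using the voxel dimensions:
#' count x dx dy dz / 1000. Non-increasing in the operating point.
#'
#' @param probMap probability volume (native grid).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param operatingPoint threshold; voxels with probability >= it count.
#' @return volume in mL.
#' @examples
#' m <- array(0, c(10, 10, 20)); m[1:100] <- 1
#' stopifnot(quantifyVolume(m, c(1, 1, 1), 0.5) == 0.1)
#' @export
quantifyVolume <- function(probMap, spacing, operatingPoint = 0.5) {
  sum(probMap >= operatingPoint) * prod(spacing) / 1000
}

#' Predict one study
#'
#' Applies per-series percentile normalization (alpha = 1 for DWI, 0 for
#' ADC), resizes in plane to the network grid, runs the forward pass in
#' inference mode, resamples the probability map back to the study's native
#' grid (bilinear), and derives the study probability, the binary call at
#' the operating point, and the predicted volume on the native grid. The
#' study probability is the maximum of the \emph{native}-grid map so that
#' the call and the volume are consistent: the predicted volume is positive
#' exactly when the call is positive. Deterministic given weights and input.
#'
#' @param record a validated \code{\linkS4class{StudyRecord}}.
#' @param model a 3D \code{\linkS4class{UNetModel}} (or 2D for slice-wise
#'   use).
#' @param config an \code{\linkS4class{InferenceConfig}}.
#' @return a \code{\linkS4class{PredictionResult}}.
#' @export
predictStudy <- function(record, model, config = inferenceConfig()) {
  validObject(config)
  bad <- validatePair(record)
  if (length(bad)) stop("invalid study: ", paste(bad, collapse = "; "))
  x <- prepareInput(record, config@targetXY, config@channels)
  if (dim(x)[4] != model@spec@inChannels)
    stop("channel selection does not match the model's input channels")
  prob <- networkForward(model, x, training = FALSE)$prob
  if (any(!is.finite(prob))) stop("non-finite network output")
  native <- dim(record@dwi)
  probNative <- resizeInplane(prob, native[1:2])
  # bilinear resampling cannot create values outside [0, 1]
  s <- classifyProbMap(probNative, config@operatingPoint)
  vol <- quantifyVolume(probNative, record@spacing, config@operatingPoint)
  new("PredictionResult", studyId = record@studyId, probMap = prob,
      probMapNative = probNative, studyProbability = s$studyProbability,
      label = s$label, predictedVolumeML = vol,
      operatingPoint = config@operatingPoint)
}

#' Predict every study of a cohort
#'
#' @param records list of \code{\linkS4class{StudyRecord}}.
#' @param model a \code{\linkS4class{UNetModel}}.
#' @param config an \code{\linkS4class{InferenceConfig}}.
#' @return named list of \code{\linkS4class{PredictionResult}}.
#' @export
predictCohort <- function(records, model, config = inferenceConfig()) {
  out <- lapply(records, predictStudy, model = model, config = config)
  names(out) <- vapply(records, function(r) r@studyId, "")
  out
}
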