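#' @import methods
#' @importFrom stats quantile rnorm runif rbinom median cor cor.test sd
#'   setNames
#' @useDynLib infarctSeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Study annotation: binary label plus optional voxel mask
#'
#' An annotation carries the study-level classification label
#' (\code{"positive"} or \code{"negative"}) and, optionally, a binary
#' voxel-level ground-truth mask. Three supervision classes follow:
#' \emph{segmented-positive} (positive with mask), \emph{classification-only
#' positive} (positive without mask) and \emph{negative}. Negative studies
#' are known to have empty masks, so a mask attached to a negative study must
#' be all zero.
#'
#' @slot label character, \code{"positive"} or \code{"negative"}.
#' @slot mask optional binary 3D array (1 = infarct voxel) or \code{NULL}.
#' @export
setClass("Annotation",
  representation(label = "character", mask = "arrayOrNULL"),
  prototype(label = "negative", mask = NULL))

setValidity("Annotation", function(object) {
  msg <- character()
  if (length(object@label) != 1L ||
      !object@label %in% c("positive", "negative"))
    msg <- c(msg, "label must be 'positive' or 'negative'")
  if (!is.null(object@mask)) {
    if (length(dim(object@mask)) != 3L)
      msg <- c(msg, "mask must be a 3D array")
    if (!all(object@mask %in% c(0, 1)))
      msg <- c(msg, "mask must be binary")
    if (identical(object@label, "negative") && any(object@mask != 0))
      msg <- c(msg, "negative study must have an all-zero mask")
  }
  if (length(msg)) msg else TRUE
})

#' One study's paired DWI/ADC volumes
#'
#' A \code{StudyRecord} holds the axial DWI (B-1000) and ADC volumes of a
#' single MRI study on a shared voxel grid, the voxel spacing in mm, and the
#' study's annotation. Arrays are ordered (x, y, z) with z indexing axial
#' slices.
#'
#' @slot studyId character scalar.
#' @slot dwi 3D array, DWI B-1000 intensities (arbitrary units).
#' @slot adc 3D array, ADC intensities; same grid as \code{dwi}.
#' @slot spacing numeric(3), voxel dimensions (dx, dy, dz) in mm.
#' @slot annotation an \code{\linkS4class{Annotation}}.
#' @export
setClass("StudyRecord",
  representation(studyId = "character", dwi = "array", adc = "array",
                 spacing = "numeric", annotation = "Annotation"))

setValidity("StudyRecord", function(object) {
  msg <- character()
  if (length(dim(object@dwi)) != 3L || length(dim(object@adc)) != 3L)
    msg <- c(msg, "dwi and adc must be 3D arrays")
  if (length(object@spacing) != 3L)
    msg <- c(msg, "spacing must have 3 components")
  if (length(msg)) msg else TRUE
})

#' Architecture description of the z-preserving encoder-decoder network
#'
#' The network is a U-Net whose pooling acts only within the axial (x, y)
#' plane so that the z resolution is preserved and the model runs on an
#' arbitrary number of axial slices. All convolutions use 3x3(x3) kernels
#' followed by batch normalization and a leaky ReLU; the output layer is a
#' 1x1(x1) convolution followed by a sigmoid. The same description is shared
#' by the 2D (slice-wise) and 3D variants.
#'
#' @slot inChannels integer, input channels (2 = DWI + ADC).
#' @slot depth integer, number of xy pooling levels.
#' @slot baseChannels integer, channels at the first level (doubling per
#'   level).
#' @slot leakySlope numeric, negative-side slope of the leaky ReLU.
#' @export
setClass("NetworkSpec",
  representation(inChannels = "integer", depth = "integer",
                 baseChannels = "integer", leakySlope = "numeric"),
  prototype(inChannels = 2L, depth = 3L, baseChannels = 16L,
            leakySlope = 0.3))

setValidity("NetworkSpec", function(object) {
  msg <- character()
  if (object@inChannels < 1L) msg <- c(msg, "inChannels must be >= 1")
  if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
  if (object@baseChannels < 1L) msg <- c(msg, "baseChannels must be >= 1")
  if (object@leakySlope < 0 || object@leakySlope >= 1)
    msg <- c(msg, "leakySlope must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' A built network: spec, variant and named weights
#'
#' @slot spec a \code{\linkS4class{NetworkSpec}}.
#' @slot dims integer, 2 (slice-wise kernels, z extent 1) or 3.
#' @slot weights named list of parameter arrays (convolution kernels and
#'   biases, batch-norm scale/shift and running statistics).
#' @export
setClass("UNetModel",
  representation(spec = "NetworkSpec", dims = "integer", weights = "list"))

setValidity("UNetModel", function(object) {
  if (!object@dims %in% c(2L, 3L)) return("dims must be 2 or 3")
  TRUE
})

#' Phantom cohort generator settings
#'
#' Describes the synthetic stroke phantom: an ellipsoidal "brain" of constant
#' base intensity per series, infarct lesions built from 1-3 overlapping
#' spheres that are hyperintense on DWI and hypointense on ADC, optional T2
#' shine-through confounders that are bright on \emph{both} series (and never
#' part of the ground-truth mask), and additive Gaussian noise.
#'
#' @slot grid integer(3), voxel grid (nx, ny, nz).
#' @slot spacing numeric(3), voxel spacing in mm.
#' @slot brainSemiAxes numeric(3), ellipsoid semi-axes in voxels.
#' @slot dwiBrain,dwiBackground,adcBrain,adcBackground base intensities.
#' @slot lesionCountRange integer(2), spheres per lesion.
#' @slot lesionRadiusRange numeric(2), sphere radius range in mm.
#' @slot dwiLesionContrast multiplicative DWI lesion factor (> 1).
#' @slot adcLesionContrast multiplicative ADC lesion factor (in (0, 1)).
#' @slot shinethroughProb probability a study receives a confounder blob.
#' @slot dwiNoiseSd,adcNoiseSd additive Gaussian noise sd per series.
#' @slot biasField logical, apply a smooth multiplicative field.
#' @slot seed integer master seed; per-study seeds derive from it.
#' @export
setClass("PhantomSpec",
  representation(grid = "integer", spacing = "numeric",
                 brainSemiAxes = "numeric",
                 dwiBrain = "numeric", dwiBackground = "numeric",
                 adcBrain = "numeric", adcBackground = "numeric",
                 lesionCountRange = "integer", lesionRadiusRange = "numeric",
                 dwiLesionContrast = "numeric", adcLesionContrast = "numeric",
                 shinethroughProb = "numeric",
                 dwiNoiseSd = "numeric", adcNoiseSd = "numeric",
                 biasField = "logical", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be positive")
  if (object@dwiLesionContrast <= 1)
    msg <- c(msg, "dwiLesionContrast must be > 1")
  if (object@adcLesionContrast <= 0 || object@adcLesionContrast >= 1)
    msg <- c(msg, "adcLesionContrast must be in (0, 1)")
  if (object@shinethroughProb < 0 || object@shinethroughProb > 1)
    msg <- c(msg, "shinethroughProb must be in [0, 1]")
  rmax <- max(object@lesionRadiusRange) / min(object@spacing[1:2])
  if (rmax >= min(object@brainSemiAxes[1:2]))
    msg <- c(msg, "lesion radii must fit inside the brain ellipsoid")
  if (length(msg)) msg else TRUE
})

#' Ground truth for a phantom study
#'
#' @slot mask binary 3D array.
#' @slot trueVolumeML lesion volume in mL: positive-voxel count times the
#'   voxel volume (dx dy dz) / 1000.
#' @slot label \code{"positive"} iff the mask has at least one voxel.
#' @export
setClass("GroundTruth",
  representation(mask = "array", trueVolumeML = "numeric",
                 label = "character"))

setValidity("GroundTruth", function(object) {
  pos <- any(object@mask != 0)
  if (pos != identical(object@label, "positive"))
    return("label must be positive iff the mask is nonempty")
  TRUE
})

#' Training-time augmentation bounds
#'
#' Geometric draws act only within the axial plane and are applied
#' identically to DWI, ADC and (nearest-neighbour) mask; the intensity draw
#' shifts the normalization window \eqn{[I_{min}, I_{max}]} of each image
#' series by up to a fraction of \eqn{I_{97} - I_3} in either direction.
#'
#' @slot maxRotationDeg in-plane rotation bound (degrees).
#' @slot maxTranslationFrac translation bound as a fraction of x/y extent.
#' @slot scaleRange numeric(2), in-plane scale factor range.
#' @slot intensityOffsetFrac offset bound as a fraction of I97 - I3.
#' @export
setClass("AugmentationConfig",
  representation(maxRotationDeg = "numeric", maxTranslationFrac = "numeric",
                 scaleRange = "numeric", intensityOffsetFrac = "numeric"),
  prototype(maxRotationDeg = 10, maxTranslationFrac = 0.10,
            scaleRange = c(0.9, 1.1), intensityOffsetFrac = 0.2))

#' Training configuration
#'
#' Defaults follow the training regime of the mixed-supervision model: 3D
#' batches of 8 studies balanced as 2 segmented positives, 2
#' classification-only positives and 4 negatives; Adam with initial learning
#' rate 1e-4 for 200 epochs, divided by 10 after epoch 100 and again after
#' epoch 150; 2D pretraining batches of all axial slices from 16 studies at
#' learning rate 1e-3.
#'
#' @slot batchComposition integer(3): segmented positives,
#'   classification-only positives, negatives per 3D batch.
#' @slot lr3d,epochs3d 3D schedule.
#' @slot lr2d,epochs2d,pretrainStudiesPerBatch 2D pretraining schedule.
#' @slot augment logical, apply training-time augmentation.
#' @slot seed integer.
#' @export
setClass("TrainingConfig",
  representation(batchComposition = "integer", lr3d = "numeric",
                 epochs3d = "integer", lr2d = "numeric", epochs2d = "integer",
                 pretrainStudiesPerBatch = "integer", augment = "logical",
                 seed = "integer"),
  prototype(batchComposition = c(2L, 2L, 4L), lr3d = 1e-4, epochs3d = 200L,
            lr2d = 1e-3, epochs2d = 20L, pretrainStudiesPerBatch = 16L,
            augment = TRUE, seed = 1L))

#' Inference configuration
#'
#' @slot operatingPoint probability threshold in (0, 1); the comparison is
#'   inclusive (probability >= operating point is called positive).
#' @slot channels \code{"both"}, \code{"dwi_only"} or \code{"adc_only"}.
#' @slot targetXY integer(2), in-plane grid the series are resized to before
#'   the forward pass (z is never resampled).
#' @export
setClass("InferenceConfig",
  representation(operatingPoint = "numeric", channels = "character",
                 targetXY = "integer"),
  prototype(operatingPoint = 0.5, channels = "both",
            targetXY = c(256L, 256L)))

setValidity("InferenceConfig", function(object) {
  msg <- character()
  if (object@operatingPoint <= 0 || object@operatingPoint >= 1)
    msg <- c(msg, "operatingPoint must be in (0, 1)")
  if (!object@channels %in% c("both", "dwi_only", "adc_only"))
    msg <- c(msg, "channels must be both, dwi_only or adc_only")
  if (length(msg)) msg else TRUE
})

#' Per-study prediction
#'
#' @slot studyId character.
#' @slot probMap voxel probability map on the network grid.
#' @slot probMapNative probability map resampled to the study's native grid.
#' @slot studyProbability maximum voxel probability (native grid).
#' @slot label \code{"positive"} iff studyProbability >= operating point.
#' @slot predictedVolumeML supra-threshold native voxel count times native
#'   voxel volume / 1000.
#' @slot operatingPoint threshold used.
#' @export
setClass("PredictionResult",
  representation(studyId = "character", probMap = "array",
                 probMapNative = "array", studyProbability = "numeric",
                 label = "character", predictedVolumeML = "numeric",
                 operatingPoint = "numeric"))

#' Cohort evaluation report
#'
#' Classification metrics with bootstrap percentile confidence intervals,
#' segmentation overlap on true positives, and volume agreement.
#'
#' @slot nStudies,nPositive cohort size.
#' @slot auroc,sensitivity,specificity numeric(3): point, CI lower, CI upper.
#' @slot diceMedian,diceIQR median and interquartile range of the Dice
#'   coefficient over true-positive studies.
#' @slot pearsonVolume Pearson r between true and predicted volumes.
#' @slot blandAltman list with mean difference and limits of agreement,
#'   overall and restricted to ground-truth volumes < 70 mL.
#' @slot spearman data.frame of (covariate, rho, p).
#' @slot operatingPoint threshold used.
#' @export
setClass("EvaluationReport",
  representation(nStudies = "integer", nPositive = "integer",
                 auroc = "numeric", sensitivity = "numeric",
                 specificity = "numeric", diceMedian = "numeric",
                 diceIQR = "numeric", pearsonVolume = "numeric",
                 blandAltman = "list", spearman = "data.frame",
                 operatingPoint = "numeric"))

setValidity("EvaluationReport", function(object) {
  a <- object@auroc
  if (length(a) == 3L && !is.na(a[1]) && (a[1] < 0 || a[1] > 1))
    return("auroc must lie in [0, 1]")
  TRUE
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "StudyRecord", function(object) {
  d <- dim(object@dwi)
  cat("StudyRecord '", object@studyId, "': ", d[1], "x", d[2], "x", d[3],
      " @ (", paste(signif(object@spacing, 3), collapse = ", "), ") mm, ",
      object@annotation@label,
      if (!is.null(object@annotation@mask)) ", segmented" else "", "\n",
      sep = "")
})

setMethod("show", "UNetModel", function(object) {
  cat(sprintf("UNetModel: %dD, depth %d, base %d channels, %d input channel(s), %s parameters\n",
              object@dims, object@spec@depth, object@spec@baseChannels,
              object@spec@inChannels,
              format(sum(vapply(object@weights, length, 1L)),
                     big.mark = ",")))
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult '%s': p = %.4f, %s, %.2f mL (operating point %.2f)\n",
              object@studyId, object@studyProbability, object@label,
              object@predictedVolumeML, object@operatingPoint))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: n = %d (%d positive)\n", object@nStudies,
              object@nPositive))
  cat(sprintf("  AUROC       %.3f (95%% CI %.3f-%.3f)\n", object@auroc[1],
              object@auroc[2], object@auroc[3]))
  cat(sprintf("  sensitivity %.3f (95%% CI %.3f-%.3f)\n",
              object@sensitivity[1], object@sensitivity[2],
              object@sensitivity[3]))
  cat(sprintf("  specificity %.3f (95%% CI %.3f-%.3f)\n",
              object@specificity[1], object@specificity[2],
              object@specificity[3]))
  if (!is.na(object@diceMedian))
    cat(sprintf("  median Dice %.3f (IQR %.3f-%.3f)\n", object@diceMedian,
                object@diceIQR[1], object@diceIQR[2]))
  if (!is.na(object@pearsonVolume))
    cat(sprintf("  Pearson volume r %.3f\n", object@pearsonVolume))
})
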