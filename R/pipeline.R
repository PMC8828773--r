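# End-to-end phantom experiment: generate a cohort, pretrain the 2D
# network, inflate, train the 3D network under mixed supervision, and
# evaluate on the held-out split. This is the package's reference study
# design; the acceptance script and the scaled-down experiments in the test
# suite run through it.

#' Run a synthetic end-to-end training and evaluation experiment
#'
#' Generates a seeded phantom cohort, splits it into training and held-out
#' studies, pretrains the 2D slice-wise network, inflates its weights into
#' the 3D network, trains with the mixed-supervision loss and balanced
#' batches, and evaluates the result on the held-out split (AUROC,
#' sensitivity/specificity at the operating point, Dice on true positives,
#' volume agreement).
#'
#' @param seed master seed for the cohort, the weight initialization and
#'   the training draws.
#' @param nStudies cohort size (default 200).
#' @param prevalence fraction positive (default 0.5; counts are exact).
#' @param segmentedFraction fraction of training positives that keep their
#'   segmentation mask; the remainder are classification-only.
#' @param holdout number of held-out studies.
#' @param phantom a \code{\linkS4class{PhantomSpec}} template; its grid and
#'   contrasts define the study conditions (its seed is replaced by
#'   \code{seed}).
#' @param netSpec a \code{\linkS4class{NetworkSpec}} (default depth 3, base
#'   16, 2 channels).
#' @param targetXY network in-plane grid (default the phantom grid).
#' @param epochs2d,epochs3d scaled-down schedule lengths.
#' @param lr2d,lr3d initial learning rates (reference defaults; short
#'   schedules may need a larger \code{lr3d} for the 3D phase to matter).
#' @param pretrainStudiesPerBatch 2D batch size in studies.
#' @param augment training-time augmentation.
#' @param channels \code{"both"}, \code{"dwi_only"} or \code{"adc_only"}.
#' @param supervision \code{"mixed"} (classification + segmentation
#'   annotations) or \code{"segmented_only"} (the ablation that discards
#'   classification-only positives and fills their batch slots with
#'   additional segmented draws).
#' @param operatingPoint study-call threshold (default 0.5).
#' @param bootstrapIters bootstrap iterations for the report CIs.
#' @param outDir directory for the cohort files (default a temporary one).
#' @param verbose print training progress.
#' @return list: \code{report} (\code{\linkS4class{EvaluationReport}}),
#'   \code{model}, \code{predictions}, \code{truths}, \code{manifest},
#'   \code{log2d}, \code{log3d}.
#' @export
runPhantomExperiment <- function(seed = 1L, nStudies = 200L,
                                 prevalence = 0.5, segmentedFraction = 0.5,
                                 holdout = 60L,
                                 phantom = phantomSpec(),
                                 netSpec = networkSpec(2L, 3L, 16L),
                                 targetXY = NULL,
                                 epochs2d = 6L, epochs3d = 2L,
                                 lr2d = 1e-3, lr3d = 1e-4,
                                 pretrainStudiesPerBatch = 4L,
                                 augment = TRUE, channels = "both",
                                 supervision = c("mixed", "segmented_only"),
                                 operatingPoint = 0.5,
                                 bootstrapIters = 10000L,
                                 outDir = tempfile("phantom_cohort"),
                                 verbose = FALSE) {
  supervision <- match.arg(supervision)
  phantom@seed <- as.integer(seed)
  if (is.null(targetXY)) targetXY <- phantom@grid[1:2]
  if (channels != "both") netSpec@inChannels <- 1L

  manifest <- generateCohort(
    phantom, nStudies, prevalence = prevalence,
    segmentedFraction = segmentedFraction, outDir = outDir,
    splitFractions = c(train = 1 - holdout / nStudies,
                       test = holdout / nStudies),
    exact = TRUE)
  records <- loadCohort(manifest)
  trainRecs <- records[manifest$split == "train"]
  testIdx <- which(manifest$split == "test")
  testRecs <- records[testIdx]

  config <- trainingConfig(epochs2d = as.integer(epochs2d),
                           epochs3d = as.integer(epochs3d),
                           lr2d = lr2d, lr3d = lr3d,
                           pretrainStudiesPerBatch =
                             as.integer(pretrainStudiesPerBatch),
                           augment = augment,
                           seed = deriveSeed(seed, 500))
  if (supervision == "segmented_only") {
    # ablation: no classification-only studies; their batch slots go to
    # additional segmented draws
    keep <- vapply(trainRecs, supervisionClass, "") != "classonly"
    trainRecs <- trainRecs[keep]
    config@batchComposition <- c(4L, 0L, 4L)
  }

  pre <- pretrain2d(trainRecs, netSpec, config, targetXY = targetXY,
                    channels = channels, verbose = verbose)
  tr <- train3d(trainRecs, netSpec, config, init = inflate2dTo3d(pre$model),
                targetXY = targetXY, channels = channels,
                epochs = as.integer(epochs3d), verbose = verbose)

  infCfg <- inferenceConfig(operatingPoint = operatingPoint,
                            channels = channels,
                            targetXY = targetXY)
  predictions <- predictCohort(testRecs, tr$finalModel, infCfg)
  truths <- lapply(testIdx, function(i)
    generateStudy(phantom, manifest$label[i] == "positive",
                  seed = deriveSeed(phantom@seed, i + 2),
                  studyId = manifest$study_id[i])$truth)
  report <- evaluateCohort(predictions, truths,
                           bootstrapIters = bootstrapIters,
                           seed = deriveSeed(seed, 900))
  list(report = report, model = tr$finalModel, predictions = predictions,
       truths = truths, manifest = manifest, log2d = pre$log, log3d = tr$log)
}
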