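# Cohort-level validation statistics: AUROC with bootstrap confidence
# intervals, operating-point sensitivity/specificity, Dice on true
# positives, Pearson and Bland-Altman volume agreement, and Spearman
# correlations of the classification probability with covariates.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive outscores a random negative, with half credit for ties —
#' identical to the exhaustive pair count over all positive x negative
#' pairs, and invariant under strictly monotone transforms of the scores.
#'
#' @param scores per-study probabilities (or any monotone scores).
#' @param labels binary labels (0/1 or logical).
#' @return AUROC in [0, 1].
#' @export
aurocScore <- function(scores, labels) {
  labels <- as.numeric(labels)
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0) stop("single-class cohort")
  r <- rank(scores)
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Percentile bootstrap confidence interval for a cohort metric
#'
#' Resamples studies with replacement \code{nIter} times (default 10,000)
#' and reports the percentile interval of the resampled metric
#' distribution. Resamples on which the metric is undefined (for AUROC, a
#' single-class resample) are discarded and redrawn; if more than half of
#' the draws are undefined the metric is deemed un-bootstrappable and an
#' error is raised. Bit-reproducible for a fixed seed.
#'
#' @param metricFn function(idx) -> scalar, evaluating the metric on the
#'   resample given by integer indices \code{idx}.
#' @param n number of studies.
#' @param nIter bootstrap iterations.
#' @param level confidence level.
#' @param seed integer seed.
#' @return numeric(3): point estimate (full sample), lower, upper.
#' @export
bootstrapCI <- function(metricFn, n, nIter = 10000, level = 0.95,
                        seed = 1L) {
  point <- unname(metricFn(seq_len(n)))
  vals <- withSeed(seed, {
    out <- numeric(nIter)
    bad <- 0L
    i <- 1L
    while (i <= nIter) {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(metricFn(idx), error = function(e) NA_real_)
      if (is.na(v)) {
        bad <- bad + 1L
        if (bad > nIter / 2) stop(
          "metric undefined on more than half of the bootstrap resamples")
        next
      }
      out[i] <- v
      i <- i + 1L
    }
    out
  })
  a <- (1 - level) / 2
  ci <- quantile(vals, c(a, 1 - a), names = FALSE, type = 7)
  c(point, ci[1], ci[2])
}

#' Sensitivity and specificity of binary calls
#'
#' @param labelsTrue,labelsPred binary vectors (0/1 or logical) of equal
#'   length.
#' @return numeric(2): sensitivity TP/(TP+FN), specificity TN/(TN+FP).
#' @export
sensitivitySpecificity <- function(labelsTrue, labelsPred) {
  t <- as.numeric(labelsTrue)
  p <- as.numeric(labelsPred)
  if (length(t) != length(p)) stop("length mismatch")
  if (!any(t == 1)) stop("sensitivity undefined: no positive studies")
  if (!any(t == 0)) stop("specificity undefined: no negative studies")
  c(sensitivity = sum(t == 1 & p == 1) / sum(t == 1),
    specificity = sum(t == 0 & p == 0) / sum(t == 0))
}

#' Dice coefficient between two binary masks
#'
#' \eqn{2 |A \cap B| / (|A| + |B|)}.
#'
#' @param maskA,maskB binary volumes on the same grid, at least one
#'   nonempty.
#' @return Dice overlap in [0, 1].
#' @export
diceCoefficient <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB))) stop("mask grids differ")
  sa <- sum(maskA != 0)
  sb <- sum(maskB != 0)
  if (sa + sb == 0) stop("Dice undefined: both masks empty")
  2 * sum(maskA != 0 & maskB != 0) / (sa + sb)
}

#' Volume agreement: Pearson correlation and Bland-Altman statistics
#'
#' The Bland-Altman statistics are the mean difference (predicted minus
#' true) and the 95% limits of agreement, mean +/- 1.96 sd of the
#' differences.
#'
#' @param trueVolumes,predVolumes paired numeric vectors (length >= 3).
#' @return list: \code{pearson}, \code{meanDiff}, \code{loaLower},
#'   \code{loaUpper}, \code{n}.
#' @export
volumeAgreement <- function(trueVolumes, predVolumes) {
  if (length(trueVolumes) != length(predVolumes) || length(trueVolumes) < 3)
    stop("need paired vectors of length >= 3")
  if (sd(trueVolumes) == 0 || sd(predVolumes) == 0)
    stop("zero-variance input for Pearson correlation")
  d <- predVolumes - trueVolumes
  list(pearson = cor(trueVolumes, predVolumes),
       meanDiff = mean(d),
       loaLower = mean(d) - 1.96 * sd(d),
       loaUpper = mean(d) + 1.96 * sd(d),
       n = length(d))
}

#' Spearman correlation of classification probability with a covariate
#'
#' Rank correlation with midrank tie handling and a two-sided p-value,
#' used to relate the study probability to clinical covariates such as
#' lesion volume.
#'
#' @param probabilities study probabilities.
#' @param covariate paired numeric covariate (>= 5 pairs).
#' @return list: \code{rho}, \code{p}.
#' @export
probabilityCovariateSpearman <- function(probabilities, covariate) {
  if (length(probabilities) != length(covariate) || length(covariate) < 5)
    stop("need >= 5 paired values")
  if (sd(covariate) == 0) stop("constant covariate")
  ct <- suppressWarnings(cor.test(probabilities, covariate,
                                  method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Evaluate a cohort of predictions against ground truth
#'
#' Assembles the full validation report: AUROC, sensitivity and specificity
#' at the predictions' operating point (each with a study-level bootstrap
#' percentile CI), the Dice coefficient on true positives (positive by both
#' ground truth and model, computed on the native grid), Pearson and
#' Bland-Altman volume agreement on true positives — overall and restricted
#' to ground-truth volumes below 70 mL — and the Spearman correlation
#' between classification probability and true lesion volume over all
#' ground-truth-positive studies.
#'
#' @param predictions list of \code{\linkS4class{PredictionResult}}.
#' @param truths list of \code{\linkS4class{GroundTruth}} in the same order.
#' @param bootstrapIters bootstrap iterations (default 10,000).
#' @param seed bootstrap seed.
#' @param covariates optional data.frame of additional per-study covariates;
#'   Spearman entries are computed over ground-truth-positive studies.
#' @return an \code{\linkS4class{EvaluationReport}}.
#' @export
evaluateCohort <- function(predictions, truths, bootstrapIters = 10000,
                           seed = 1L, covariates = NULL) {
  stopifnot(length(predictions) == length(truths))
  n <- length(predictions)
  scores <- vapply(predictions, function(p) p@studyProbability, 0)
  predLab <- vapply(predictions, function(p)
    as.numeric(p@label == "positive"), 0)
  trueLab <- vapply(truths, function(t) as.numeric(t@label == "positive"), 0)
  if (!any(trueLab == 1) || !any(trueLab == 0)) stop("single-class cohort")
  op <- predictions[[1]]@operatingPoint

  auroc <- bootstrapCI(function(i) aurocScore(scores[i], trueLab[i]), n,
                       bootstrapIters, seed = deriveSeed(seed, 1))
  sens <- bootstrapCI(function(i) {
    if (!any(trueLab[i] == 1)) stop("no positives")
    sensitivitySpecificity(trueLab[i], predLab[i])[1]
  }, n, bootstrapIters, seed = deriveSeed(seed, 2))
  spec <- bootstrapCI(function(i) {
    if (!any(trueLab[i] == 0)) stop("no negatives")
    sensitivitySpecificity(trueLab[i], predLab[i])[2]
  }, n, bootstrapIters, seed = deriveSeed(seed, 3))

  tp <- which(trueLab == 1 & predLab == 1)
  diceVals <- vapply(tp, function(i) {
    predMask <- predictions[[i]]@probMapNative >= op
    diceCoefficient(truths[[i]]@mask, predMask)
  }, 0)
  diceMedian <- if (length(diceVals)) median(diceVals) else NA_real_
  diceIQR <- if (length(diceVals))
    unname(quantile(diceVals, c(0.25, 0.75))) else c(NA_real_, NA_real_)

  trueVol <- vapply(truths, function(t) t@trueVolumeML, 0)
  predVol <- vapply(predictions, function(p) p@predictedVolumeML, 0)
  ba <- list(overall = NULL, under70 = NULL)
  pearson <- NA_real_
  if (length(tp) >= 3) {
    va <- volumeAgreement(trueVol[tp], predVol[tp])
    pearson <- va$pearson
    ba$overall <- va[c("meanDiff", "loaLower", "loaUpper", "n")]
    small <- tp[trueVol[tp] < 70]
    if (length(small) >= 3)
      ba$under70 <- volumeAgreement(trueVol[small],
                                    predVol[small])[
        c("meanDiff", "loaLower", "loaUpper", "n")]
  }

  pos <- which(trueLab == 1)
  sp <- data.frame(covariate = character(), rho = numeric(),
                   p = numeric(), stringsAsFactors = FALSE)
  if (length(pos) >= 5 && sd(trueVol[pos]) > 0) {
    s <- probabilityCovariateSpearman(scores[pos], trueVol[pos])
    sp <- rbind(sp, data.frame(covariate = "true_volume_mL", rho = s$rho,
                               p = s$p))
  }
  if (!is.null(covariates)) {
    for (nm in names(covariates)) {
      cv <- covariates[[nm]][pos]
      if (length(cv) >= 5 && sd(cv) > 0) {
        s <- probabilityCovariateSpearman(scores[pos], cv)
        sp <- rbind(sp, data.frame(covariate = nm, rho = s$rho, p = s$p))
      }
    }
  }

  new("EvaluationReport", nStudies = as.integer(n),
      nPositive = as.integer(sum(trueLab)), auroc = auroc,
      sensitivity = sens, specificity = spec, diceMedian = diceMedian,
      diceIQR = diceIQR, pearsonVolume = pearson, blandAltman = ba,
      spearman = sp, operatingPoint = op)
}

#' Serialize an EvaluationReport to JSON
#'
#' @param report an \code{\linkS4class{EvaluationReport}}.
#' @param path destination file.
#' @return invisibly, \code{path}.
#' @export
writeReport <- function(report, path) {
  x <- list(n_studies = report@nStudies, n_positive = report@nPositive,
            operating_point = report@operatingPoint,
            auroc = list(point = report@auroc[1], lower = report@auroc[2],
                         upper = report@auroc[3]),
            sensitivity = list(point = report@sensitivity[1],
                               lower = report@sensitivity[2],
                               upper = report@sensitivity[3]),
            specificity = list(point = report@specificity[1],
                               lower = report@specificity[2],
                               upper = report@specificity[3]),
            dice = list(median = report@diceMedian,
                        iqr_lower = report@diceIQR[1],
                        iqr_upper = report@diceIQR[2]),
            pearson_volume = report@pearsonVolume,
            bland_altman = report@blandAltman,
            spearman = report@spearman)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
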