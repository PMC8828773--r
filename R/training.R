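# Mixed-supervision training: soft Dice + binary cross-entropy with the
# Dice term masked to studies whose ground-truth masks are known (segmented
# positives and negatives, whose masks are known to be empty);
# classification-only positives contribute only through the max-pooled
# classification head. Balanced batches of (2 segmented positive, 2
# classification-only positive, 4 negative) studies; Adam; 2D slice-wise
# pretraining whose kernels are inflated into the 3D network.

DICE_SMOOTH <- 1.0
BCE_CLAMP <- 1e-7

#' Construct a TrainingConfig
#'
#' @param batchComposition integer(3): segmented positives,
#'   classification-only positives and negatives per 3D batch (default
#'   2, 2, 4).
#' @param lr3d initial 3D learning rate (default 1e-4; divided by 10 at half
#'   and three-quarters of the schedule, i.e. epochs 100 and 150 of 200).
#' @param epochs3d 3D epochs (default 200).
#' @param lr2d initial 2D pretraining learning rate (default 1e-3).
#' @param epochs2d 2D pretraining epochs (default 20).
#' @param pretrainStudiesPerBatch studies per 2D batch; the batch contains
#'   all their axial slices (default 16).
#' @param augment apply training-time augmentation.
#' @param seed integer.
#' @return a \code{\linkS4class{TrainingConfig}}.
#' @export
trainingConfig <- function(batchComposition = c(2L, 2L, 4L), lr3d = 1e-4,
                           epochs3d = 200L, lr2d = 1e-3, epochs2d = 20L,
                           pretrainStudiesPerBatch = 16L, augment = TRUE,
                           seed = 1L) {
  new("TrainingConfig", batchComposition = as.integer(batchComposition),
      lr3d = lr3d, epochs3d = as.integer(epochs3d), lr2d = lr2d,
      epochs2d = as.integer(epochs2d),
      pretrainStudiesPerBatch = as.integer(pretrainStudiesPerBatch),
      augment = augment, seed = as.integer(seed))
}

#' Soft Dice loss
#'
#' \deqn{L = 1 - (2 \sum p t + \epsilon) / (\sum p + \sum t + \epsilon).}
#' With \code{smooth = 1} the empty-vs-empty case is lossless (ratio
#' \eqn{\epsilon/\epsilon = 1}), which is what makes the term applicable to
#' negative studies with empty masks.
#'
#' @param pred probability volume in [0, 1].
#' @param target binary volume on the same grid.
#' @param smooth smoothing constant \eqn{\epsilon}.
#' @return scalar loss.
#' @export
softDiceLoss <- function(pred, target, smooth = DICE_SMOOTH) {
  if (!identical(dim(pred), dim(target)))
    stop("pred and target grids differ")
  inter <- sum(pred * target)
  1 - (2 * inter + smooth) / (sum(pred) + sum(target) + smooth)
}

# analytic gradient of softDiceLoss w.r.t. pred
softDiceGrad <- function(pred, target, smooth = DICE_SMOOTH) {
  S <- sum(pred) + sum(target) + smooth
  I2 <- 2 * sum(pred * target) + smooth
  -(2 * target * S - I2) / S^2
}

#' Binary cross-entropy between a probability and a 0/1 label
#'
#' @param p predicted probability (clamped away from 0 and 1).
#' @param y label in \{0, 1\}.
#' @return scalar loss.
#' @export
bceLoss <- function(p, y) {
  p <- pmin(pmax(p, BCE_CLAMP), 1 - BCE_CLAMP)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Mixed-supervision batch loss
#'
#' The mean binary cross-entropy between the max-pooled classification
#' output and the study label is taken over \emph{all} studies in the batch;
#' the mean soft Dice loss is taken only over the Dice-eligible subset
#' (segmented positives, and negatives using their known empty masks).
#' Classification-only positives contribute no Dice term. The two terms are
#' summed with equal weight.
#'
#' @param probMaps list of probability volumes.
#' @param labels numeric 0/1 study labels.
#' @param masks list of binary volumes, \code{NULL} for classification-only
#'   positives (negatives may pass \code{NULL}; an empty mask is implied).
#' @param classes character vector of supervision classes
#'   (\code{"segmented"}, \code{"classonly"}, \code{"negative"}).
#' @return list: \code{total}, \code{bce}, \code{dice}, \code{nDice}.
#' @export
combinedLoss <- function(probMaps, labels, masks, classes) {
  n <- length(probMaps)
  stopifnot(length(labels) == n, length(classes) == n)
  bce <- mean(vapply(seq_len(n), function(i)
    bceLoss(classificationHead(probMaps[[i]]), labels[i]), 0))
  eligible <- which(classes != "classonly")
  if (!length(eligible))
    return(list(total = bce, bce = bce, dice = 0, nDice = 0L))
  dice <- mean(vapply(eligible, function(i) {
    tgt <- masks[[i]]
    if (is.null(tgt)) tgt <- array(0, dim = dim(probMaps[[i]]))
    softDiceLoss(probMaps[[i]], tgt)
  }, 0))
  list(total = bce + dice, bce = bce, dice = dice, nDice = length(eligible))
}

#' Balanced batch sampler
#'
#' Draws the exact batch composition every time, sampling with replacement
#' within each supervision class so that scarce classes (typically the
#' segmented positives) are oversampled across batches.
#'
#' @param manifest manifest data.frame.
#' @param composition integer(3): segmented, classification-only, negative.
#' @return integer vector of row indices into \code{manifest}, of length
#'   \code{sum(composition)}.
#' @export
sampleBatch <- function(manifest, composition = c(2L, 2L, 4L)) {
  cls <- supervisionClass(manifest)
  pools <- list(segmented = which(cls == "segmented"),
                classonly = which(cls == "classonly"),
                negative = which(cls == "negative"))
  for (k in seq_along(pools))
    if (composition[k] > 0L && !length(pools[[k]]))
      stop("no studies available in supervision class '",
           names(pools)[k], "'")
  unlist(lapply(1:3, function(k)
    if (composition[k] > 0L)
      pools[[k]][sample.int(length(pools[[k]]), composition[k],
                            replace = TRUE)]
    else integer()))
}

#' Stepped learning-rate schedule
#'
#' The learning rate is divided by 10 after half of the epochs and by
#' another 10 after a further quarter: for the default 200-epoch run, 1e-4
#' for epochs 1-100, 1e-5 for 101-150, 1e-6 for 151-200.
#'
#' @param epoch 1-based epoch index.
#' @param totalEpochs schedule length.
#' @param baseLr initial learning rate.
#' @return learning rate for \code{epoch}.
#' @export
lrSchedule <- function(epoch, totalEpochs, baseLr) {
  b1 <- floor(totalEpochs / 2)
  b2 <- b1 + floor(totalEpochs / 4)
  if (epoch <= b1) baseLr else if (epoch <= b2) baseLr / 10 else baseLr / 100
}

# ---- Adam ------------------------------------------------------------------

TRAINABLE_RE <- "_(W|b|gamma|beta)$"

adamInit <- function(weights) {
  nm <- grep(TRAINABLE_RE, names(weights), value = TRUE)
  nm <- c(nm, "out_W", "out_b")
  nm <- unique(nm)
  list(t = 0,
       m = setNames(lapply(nm, function(n) weights[[n]] * 0), nm),
       v = setNames(lapply(nm, function(n) weights[[n]] * 0), nm))
}

adamStep <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}

# accumulate grads (named lists of arrays)
addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

# ---- study preparation -----------------------------------------------------

# Normalize + resize every study once; returns a list of light-weight
# training items. Masks are transported to the network grid by nearest
# neighbour.
prepareCohort <- function(records, targetXY, channels = "both") {
  lapply(records, function(r) {
    nrmD <- resizeInplane(normalizeIntensities(r@dwi, 1), targetXY)
    nrmA <- resizeInplane(normalizeIntensities(r@adc, 0), targetXY)
    mk <- r@annotation@mask
    if (!is.null(mk)) mk <- resizeInplane(mk, targetXY, isMask = TRUE)
    list(id = r@studyId, dwi = nrmD, adc = nrmA, mask = mk,
         label = as.numeric(r@annotation@label == "positive"),
         class = supervisionClass(r), channels = channels)
  })
}

# assemble the network input array for one prepared item, with optional
# augmentation (one shared geometric draw + per-series intensity offsets)
itemInput <- function(item, augment = FALSE,
                      augCfg = augmentationConfig()) {
  dwi <- item$dwi
  adc <- item$adc
  mask <- item$mask
  if (augment) {
    a <- augmentStudy(dwi, adc, mask, augCfg)
    dwi <- a$dwi
    adc <- a$adc
    mask <- a$mask
  }
  d <- dim(dwi)
  x <- switch(item$channels,
    both = {
      arr <- array(0, dim = c(d, 2))
      arr[, , , 1] <- dwi
      arr[, , , 2] <- adc
      arr
    },
    dwi_only = array(dwi, dim = c(d, 1)),
    adc_only = array(adc, dim = c(d, 1)))
  list(x = x, mask = mask)
}

# gradient of the batch loss w.r.t. one study's probability map.
# BCE routes through the argmax voxel; the division by the sigmoid
# derivative cancels inside the backward pass (which multiplies by
# p(1-p)), so clamping only guards against float saturation.
studyLossGrad <- function(prob, label, mask, class, nBatch, nDice) {
  d <- numeric(length(prob))
  s <- max(prob)
  iMax <- which.max(prob)
  sC <- min(max(s, BCE_CLAMP), 1 - BCE_CLAMP)
  d[iMax] <- d[iMax] + (sC - label) / (sC * (1 - sC)) / nBatch
  if (class != "classonly") {
    tgt <- if (is.null(mask)) array(0, dim = dim(prob)) else mask
    d <- d + as.numeric(softDiceGrad(prob, tgt)) / nDice
  }
  array(d, dim = dim(prob))
}

# ---- 2D pretraining --------------------------------------------------------

#' Pretrain the 2D slice-wise network
#'
#' One epoch consists of all segmented positive studies plus an equal number
#' of negative studies redrawn from the full negative pool at the start of
#' the epoch; classification-only positives are excluded because slice-level
#' labels are not available for them. A batch holds all axial slices from
#' \code{pretrainStudiesPerBatch} studies. The loss is the same two-term
#' mixed loss applied at slice level: the label of a slice is whether its
#' mask contains any positive pixel, and every slice of these studies has a
#' known mask, so every slice is Dice-eligible.
#'
#' @param records list of \code{\linkS4class{StudyRecord}} (the training
#'   split).
#' @param spec a \code{\linkS4class{NetworkSpec}}.
#' @param config a \code{\linkS4class{TrainingConfig}}.
#' @param targetXY in-plane network grid.
#' @param channels input channel selection.
#' @param verbose print per-epoch losses.
#' @return list: \code{model} (2D \code{UNetModel}), \code{log} (data.frame
#'   of per-epoch mean losses).
#' @export
pretrain2d <- function(records, spec, config = trainingConfig(),
                       targetXY = c(64L, 64L), channels = "both",
                       verbose = FALSE) {
  items <- prepareCohort(records, targetXY, channels)
  cls <- vapply(items, `[[`, "", "class")
  segIdx <- which(cls == "segmented")
  negIdx <- which(cls == "negative")
  if (!length(segIdx)) stop("2D pretraining requires segmented positives")
  if (!length(negIdx)) stop("2D pretraining requires negative studies")
  model <- buildNetwork(spec, dims = 2L, seed = config@seed)
  adam <- adamInit(model@weights)
  logRows <- list()
  withSeed(deriveSeed(config@seed, 1000), {
    for (epoch in seq_len(config@epochs2d)) {
      lr <- lrSchedule(epoch, config@epochs2d, config@lr2d)
      negEpoch <- sample(negIdx, length(segIdx),
                         replace = length(negIdx) < length(segIdx))
      order <- sample(c(segIdx, negEpoch))
      losses <- c()
      for (b in split(order, ceiling(seq_along(order) /
                                     config@pretrainStudiesPerBatch))) {
        step <- pretrainBatchStep(model, items[b], config, adam, lr)
        model <- step$model
        adam <- step$adam
        losses <- c(losses, step$loss)
      }
      logRows[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                                     lr = lr)
      if (verbose)
        message(sprintf("2D epoch %d: loss %.4f", epoch, mean(losses)))
    }
  })
  list(model = model, log = do.call(rbind, logRows))
}

# one 2D batch: forward/backward each study (its slices are independent
# under kz = 1), slice-level loss averaged over all slices in the batch
pretrainBatchStep <- function(model, batchItems, config, adam, lr) {
  nSlices <- sum(vapply(batchItems, function(it) dim(it$dwi)[3], 0L))
  grads <- NULL
  lossAcc <- 0
  for (it in batchItems) {
    inp <- itemInput(it, augment = config@augment)
    fw <- networkForward(model, inp$x, training = TRUE, keepCache = TRUE)
    model <- applyBnUpdates(model, fw$bnUpdates)
    prob <- fw$prob
    mask <- if (is.null(inp$mask)) array(0, dim = dim(prob)) else inp$mask
    nz <- dim(prob)[3]
    dP <- array(0, dim = dim(prob))
    for (z in seq_len(nz)) {
      pz <- prob[, , z]
      tz <- mask[, , z]
      yz <- as.numeric(any(tz > 0))
      s <- max(pz)
      sC <- min(max(s, BCE_CLAMP), 1 - BCE_CLAMP)
      lossAcc <- lossAcc + (bceLoss(s, yz) + softDiceLoss(pz, tz)) / nSlices
      dz <- softDiceGrad(pz, tz) / nSlices
      iMax <- which.max(pz)
      dz[iMax] <- dz[iMax] + (sC - yz) / (sC * (1 - sC)) / nSlices
      dP[, , z] <- dz
    }
    g <- networkBackward(fw$cache, dP)
    grads <- addGrads(grads, g)
  }
  upd <- adamStep(model@weights, grads, adam, lr)
  model@weights <- upd$weights
  list(model = model, adam = upd$state, loss = lossAcc)
}

# ---- 3D training -----------------------------------------------------------

#' Train the 3D mixed-supervision network
#'
#' Runs balanced batches through the two-term loss with the Adam optimizer
#' and the stepped learning-rate schedule. One epoch is
#' \code{ceiling(nSegmented / s)} batches where \code{s} is the number of
#' segmented slots per batch, so each segmented positive is expected about
#' once per epoch under the balanced sampling. When validation records are
#' given, held-out AUROC is computed each epoch and the best checkpoint is
#' retained.
#'
#' @param records training-split \code{\linkS4class{StudyRecord}} list; all
#'   three supervision classes must be present (batch composition permitting).
#' @param spec a \code{\linkS4class{NetworkSpec}}.
#' @param config a \code{\linkS4class{TrainingConfig}}.
#' @param init optional initial 3D \code{\linkS4class{UNetModel}} (typically
#'   from [inflate2dTo3d()]); a seeded random initialization is used
#'   otherwise.
#' @param valRecords optional validation \code{StudyRecord} list.
#' @param targetXY in-plane network grid.
#' @param channels input channel selection.
#' @param epochs override \code{config@epochs3d} (scaled-down runs).
#' @param verbose print progress.
#' @return list: \code{model} (best-validation or final), \code{finalModel},
#'   \code{log} (per-epoch data.frame: loss, bce, dice, lr, valAuroc).
#' @export
train3d <- function(records, spec, config = trainingConfig(), init = NULL,
                    valRecords = NULL, targetXY = c(64L, 64L),
                    channels = "both", epochs = config@epochs3d,
                    verbose = FALSE) {
  items <- prepareCohort(records, targetXY, channels)
  manifest <- data.frame(
    label = vapply(items, function(i) if (i$label > 0) "positive" else
      "negative", ""),
    mask_path = vapply(items, function(i)
      if (i$class == "segmented") "x" else NA_character_, ""))
  nSeg <- sum(vapply(items, `[[`, "", "class") == "segmented")
  batchesPerEpoch <- max(1L, ceiling(nSeg / max(1L,
                                                config@batchComposition[1])))
  model <- if (is.null(init)) buildNetwork(spec, 3L, config@seed) else init
  if (model@dims != 3L) stop("init must be a 3D model")
  adam <- adamInit(model@weights)
  valItems <- if (!is.null(valRecords))
    prepareCohort(valRecords, targetXY, channels) else NULL
  best <- list(auroc = -Inf, model = model)
  logRows <- list()
  withSeed(deriveSeed(config@seed, 2000), {
    for (epoch in seq_len(epochs)) {
      lr <- lrSchedule(epoch, epochs, config@lr3d)
      eLoss <- eBce <- eDice <- c()
      for (bi in seq_len(batchesPerEpoch)) {
        idx <- sampleBatch(manifest, config@batchComposition)
        step <- batchStep3d(model, items[idx], config, adam, lr)
        model <- step$model
        adam <- step$adam
        if (!is.finite(step$loss))
          stop(sprintf(
            "training diverged (non-finite loss at epoch %d batch %d)",
            epoch, bi))
        eLoss <- c(eLoss, step$loss)
        eBce <- c(eBce, step$bce)
        eDice <- c(eDice, step$dice)
      }
      valAuroc <- NA_real_
      if (!is.null(valItems)) {
        sc <- vapply(valItems, function(it) {
          inp <- itemInput(it, augment = FALSE)
          classificationHead(networkForward(model, inp$x)$prob)
        }, 0)
        yv <- vapply(valItems, `[[`, 0, "label")
        valAuroc <- aurocScore(sc, yv)
        if (valAuroc >= best$auroc) best <- list(auroc = valAuroc,
                                                 model = model)
      }
      logRows[[epoch]] <- data.frame(epoch = epoch, loss = mean(eLoss),
                                     bce = mean(eBce), dice = mean(eDice),
                                     lr = lr, valAuroc = valAuroc)
      if (verbose)
        message(sprintf("3D epoch %d: loss %.4f (bce %.4f dice %.4f) val %.3f",
                        epoch, mean(eLoss), mean(eBce), mean(eDice),
                        valAuroc))
    }
  })
  list(model = if (is.finite(best$auroc)) best$model else model,
       finalModel = model, log = do.call(rbind, logRows))
}

# one balanced 3D batch: per-study forward/backward, summed gradients,
# single Adam step
batchStep3d <- function(model, batchItems, config, adam, lr) {
  n <- length(batchItems)
  classes <- vapply(batchItems, `[[`, "", "class")
  nDice <- sum(classes != "classonly")
  grads <- NULL
  bceAcc <- diceAcc <- 0
  for (it in batchItems) {
    inp <- itemInput(it, augment = config@augment)
    fw <- networkForward(model, inp$x, training = TRUE, keepCache = TRUE)
    model <- applyBnUpdates(model, fw$bnUpdates)
    prob <- fw$prob
    s <- classificationHead(prob)
    bceAcc <- bceAcc + bceLoss(s, it$label) / n
    if (it$class != "classonly") {
      tgt <- if (is.null(inp$mask)) array(0, dim = dim(prob)) else inp$mask
      diceAcc <- diceAcc + softDiceLoss(prob, tgt) / nDice
    }
    dP <- studyLossGrad(prob, it$label, inp$mask, it$class, n, nDice)
    grads <- addGrads(grads, networkBackward(fw$cache, dP))
  }
  upd <- adamStep(model@weights, grads, adam, lr)
  model@weights <- upd$weights
  list(model = model, adam = upd$state, loss = bceAcc + diceAcc,
       bce = bceAcc, dice = diceAcc)
}
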