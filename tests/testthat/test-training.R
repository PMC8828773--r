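test_that("soft Dice loss matches hand-evaluated cases", {
  z <- array(0, c(10, 10, 10))
  expect_equal(softDiceLoss(z, z, smooth = 1), 0)
  p <- array(0, c(10, 10, 10)); p[1:100] <- 1
  expect_equal(softDiceLoss(p, p, smooth = 1), 0)
  # uniform 0.5 on 8 voxels vs 4 ones, eps = 0: 1 - (2*2)/(4+4) = 0.5
  pr <- array(0.5, c(2, 2, 2))
  tg <- array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2))
  expect_equal(softDiceLoss(pr, tg, smooth = 0), 0.5)
  expect_error(softDiceLoss(pr, array(0, c(2, 2, 3))), "grids differ")
})

test_that("the Dice term is masked out for classification-only positives", {
  set.seed(1)
  maps <- lapply(1:4, function(i) array(runif(64), c(4, 4, 4)))
  masks <- list(array(rbinom(64, 1, .2), c(4, 4, 4)), NULL, NULL, NULL)
  classes <- c("segmented", "classonly", "classonly", "negative")
  labels <- c(1, 1, 1, 0)
  full <- combinedLoss(maps, labels, masks, classes)
  # ablating a classification-only study's Dice contribution changes
  # nothing: the total equals BCE plus Dice over the eligible subset only
  bceOnly <- mean(sapply(seq_along(maps), function(i)
    bceLoss(classificationHead(maps[[i]]), labels[i])))
  diceElig <- mean(c(softDiceLoss(maps[[1]], masks[[1]]),
                     softDiceLoss(maps[[4]], array(0, c(4, 4, 4)))))
  expect_equal(full$total, bceOnly + diceElig, tolerance = 1e-12)
  expect_equal(full$nDice, 2)

  # perturbing a classification-only study's non-argmax voxels leaves the
  # loss untouched (zero gradient from the Dice term)
  m2 <- maps
  iMax <- which.max(m2[[2]])
  pert <- m2[[2]]
  pert[-iMax] <- pert[-iMax] + runif(63, -0.01, 0.01)
  m2[[2]] <- pert
  full2 <- combinedLoss(m2, labels, masks, classes)
  expect_equal(full2$total - full$total, 0, tolerance = 1e-12)
})

test_that("an all-classification-only batch reduces to the BCE term", {
  maps <- list(array(0.999, c(2, 2, 2)), array(0.998, c(2, 2, 2)))
  out <- combinedLoss(maps, c(1, 1), list(NULL, NULL),
                      c("classonly", "classonly"))
  expect_equal(out$dice, 0)
  expect_lt(out$total, 0.01)
})

test_that("perfect predictions on a full 2/2/4 batch give near-zero loss", {
  mk <- function(v) array(v, c(4, 4, 2))
  posMask <- mk(0); posMask[1, 1, 1] <- 1
  maps <- c(replicate(2, mk(1e-7) + posMask * (1 - 2e-7), simplify = FALSE),
            replicate(2, mk(1e-7) + posMask * (1 - 2e-7), simplify = FALSE),
            replicate(4, mk(1e-7), simplify = FALSE))
  masks <- c(replicate(2, posMask, simplify = FALSE),
             list(NULL, NULL), replicate(4, mk(0), simplify = FALSE))
  out <- combinedLoss(maps, c(1, 1, 1, 1, 0, 0, 0, 0), masks,
                      c("segmented", "segmented", "classonly", "classonly",
                        rep("negative", 4)))
  expect_lt(out$total, 1e-4)
})

test_that("every sampled batch has the exact 2/2/4 composition, deterministically", {
  man <- data.frame(
    label = c("positive", rep("positive", 5), rep("negative", 6)),
    mask_path = c("m.nii", rep(NA, 11)))
  cls <- supervisionClass(man)
  set.seed(31)
  comps <- replicate(1000, {
    idx <- sampleBatch(man, c(2L, 2L, 4L))
    expect_length(idx, 8)
    table(factor(cls[idx], levels = c("segmented", "classonly",
                                      "negative")))
  })
  expect_true(all(comps["segmented", ] == 2))
  expect_true(all(comps["classonly", ] == 2))
  expect_true(all(comps["negative", ] == 4))
  # the lone segmented study is oversampled into both slots every batch
  expect_true(all(replicate(20, all(sampleBatch(man)[1:2] == 1))))
  # seeded determinism
  s1 <- withr::with_seed(7, replicate(50, sampleBatch(man)))
  s2 <- withr::with_seed(7, replicate(50, sampleBatch(man)))
  expect_identical(s1, s2)
})

test_that("an empty supervision class is reported by name", {
  man <- data.frame(label = rep("negative", 5),
                    mask_path = rep(NA_character_, 5))
  expect_error(sampleBatch(man), "segmented")
  man2 <- data.frame(label = c("positive", "negative"),
                     mask_path = c("m", NA))
  expect_error(sampleBatch(man2), "classonly")
})

test_that("the learning-rate schedule has the printed breakpoints", {
  lrs <- vapply(1:200, lrSchedule, 0, totalEpochs = 200, baseLr = 1e-4)
  expect_true(all(lrs[1:100] == 1e-4))
  expect_true(all(lrs[101:150] == 1e-5))
  expect_true(all(lrs[151:200] == 1e-6))
})

test_that("2D pretraining requires segmented positives and negatives", {
  co <- tinyCohort(nSeg = 0, nClass = 3, nNeg = 3)
  expect_error(pretrain2d(co$records, tinyNetworkSpec(),
                          trainingConfig(epochs2d = 1L),
                          targetXY = c(16L, 16L)),
               "segmented")
  co2 <- tinyCohort(nSeg = 2, nClass = 0, nNeg = 0)
  expect_error(pretrain2d(co2$records[1:2], tinyNetworkSpec(),
                          trainingConfig(epochs2d = 1L),
                          targetXY = c(16L, 16L)),
               "negative")
})

test_that("2D pretraining loss decreases over epochs on a phantom cohort", {
  co <- tinyCohort(nSeg = 5, nClass = 0, nNeg = 10, seed = 3)
  cfg <- trainingConfig(epochs2d = 10L, pretrainStudiesPerBatch = 2L,
                        augment = FALSE, seed = 2L)
  out <- pretrain2d(co$records, tinyNetworkSpec(), cfg,
                    targetXY = c(16L, 16L))
  expect_equal(nrow(out$log), 10)
  expect_lt(out$log$loss[10], out$log$loss[1])
  expect_equal(out$model@dims, 2L)
})

test_that("3D training runs the schedule, logs it, and reduces the loss", {
  co <- tinyCohort(nSeg = 3, nClass = 3, nNeg = 6, seed = 5)
  cfg <- trainingConfig(epochs2d = 2L, augment = FALSE, seed = 4L)
  spec <- tinyNetworkSpec()
  tr <- train3d(co$records, spec, cfg, epochs = 8L,
                targetXY = c(16L, 16L))
  expect_equal(tr$log$lr, vapply(1:8, lrSchedule, 0, 8, cfg@lr3d))
  expect_lt(tr$log$loss[8], tr$log$loss[1])
  expect_true(all(is.finite(tr$log$loss)))

  # inflated init follows the same code path and stays finite
  pre <- pretrain2d(co$records, spec, cfg, targetXY = c(16L, 16L))
  tr2 <- train3d(co$records, spec, cfg, init = inflate2dTo3d(pre$model),
                 epochs = 2L, targetXY = c(16L, 16L))
  expect_true(all(is.finite(tr2$log$loss)))
})

test_that("validation AUROC selects the retained checkpoint", {
  co <- tinyCohort(nSeg = 3, nClass = 2, nNeg = 5, seed = 11)
  val <- tinyCohort(nSeg = 2, nClass = 0, nNeg = 2, seed = 12)
  cfg <- trainingConfig(augment = FALSE, seed = 6L)
  tr <- train3d(co$records, tinyNetworkSpec(), cfg, epochs = 3L,
                valRecords = val$records, targetXY = c(16L, 16L))
  expect_true(all(is.finite(tr$log$valAuroc)))
  expect_s4_class(tr$model, "UNetModel")
})
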