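test_that("percentiles follow the linear-interpolation definition", {
  expect_equal(unname(computePercentiles(array(5, c(4, 4, 2)))), c(5, 5))
  v <- array(sample(0:100), c(101, 1, 1))
  expect_equal(unname(computePercentiles(v)), c(3.0, 97.0))
  # permutation invariance
  p1 <- computePercentiles(array(rnorm(64), c(4, 4, 4)))
  set.seed(2)
  v2 <- rnorm(64)
  expect_equal(computePercentiles(array(v2, c(4, 4, 4))),
               computePercentiles(array(sample(v2), c(4, 4, 4))))
  expect_error(computePercentiles(array(NaN, c(2, 2, 2))), "finite")
})

test_that("intensity mapping matches the alpha = 0 and alpha = 1 equations", {
  v <- array(500, c(2, 2, 1))
  # ADC: I_min = 100, I_max = 900
  expect_equal(as.numeric(normalizeIntensities(v, 0, I3 = 100, I97 = 900)),
               rep(0.5, 4))
  # DWI: I_max = 900 + (900 - 100) = 1700; 900 maps to (900-100)/1600 = 0.5
  v2 <- array(900, c(2, 2, 1))
  expect_equal(as.numeric(normalizeIntensities(v2, 1, I3 = 100, I97 = 900)),
               rep(0.5, 4))
  # clamping at the window edges
  ext <- array(c(90, 910), c(2, 1, 1))
  out <- normalizeIntensities(ext, 0, I3 = 100, I97 = 900)
  expect_equal(as.numeric(out), c(0, 1))
})

test_that("normalization is monotone with range in [0,1] and ~3% tails", {
  set.seed(5)
  v <- array(rnorm(8000, 100, 25), c(20, 20, 20))
  out <- normalizeIntensities(v, 0)
  expect_true(all(out >= 0 & out <= 1))
  o <- order(v)
  expect_true(all(diff(out[o]) >= 0))
  # for a continuous distribution, ~3% map to each end
  expect_equal(mean(out == 0), 0.03, tolerance = 0.01)
  expect_equal(mean(out == 1), 0.03, tolerance = 0.01)
  # constant volume maps to all-zero
  expect_true(all(normalizeIntensities(array(7, c(4, 4, 2)), 1) == 0))
})

test_that("in-plane resize preserves z, masks stay binary, areas scale", {
  v <- array(rnorm(16 * 16 * 5), c(16, 16, 5))
  expect_identical(resizeInplane(v, c(16, 16)), v)
  r <- resizeInplane(v, c(32, 32))
  expect_equal(dim(r), c(32, 32, 5))

  # centred disk mask: 4x upsampling quadruples the positive area (~5%)
  d <- 64
  xy <- expand.grid(x = 1:d, y = 1:d)
  disk <- array(as.numeric((xy$x - 32.5)^2 + (xy$y - 32.5)^2 <= 14^2),
                c(d, d, 1))
  up <- resizeInplane(disk, c(2L * d, 2L * d), isMask = TRUE)
  expect_true(all(up %in% c(0, 1)))
  expect_equal(sum(up), 4 * sum(disk), tolerance = 0.05)
  expect_error(resizeInplane(v, c(0, 16)), "positive")
})

test_that("augmentation draws respect the configured bounds", {
  cfg <- augmentationConfig()
  tiny <- array(runif(4 * 4 * 1), c(4, 4, 1))
  set.seed(77)
  draws <- replicate(1000, augmentStudy(tiny, tiny, config = cfg)$draw,
                     simplify = FALSE)
  th <- vapply(draws, `[[`, 0, "thetaDeg")
  sc <- vapply(draws, `[[`, 0, "scale")
  tx <- vapply(draws, `[[`, 0, "tx")
  ty <- vapply(draws, `[[`, 0, "ty")
  offs <- c(vapply(draws, `[[`, 0, "dwiOffsetFrac"),
            vapply(draws, `[[`, 0, "adcOffsetFrac"))
  expect_true(all(abs(th) <= 10))
  expect_true(all(sc >= 0.9 & sc <= 1.1))
  expect_true(all(abs(tx) <= 0.10 * 4 & abs(ty) <= 0.10 * 4))
  expect_true(all(abs(offs) <= 0.2))
  # the bounds are actually explored
  expect_gt(max(abs(th)), 8)
  expect_gt(max(sc), 1.08)
})

test_that("a collapsed augmentation config is the identity", {
  cfg <- augmentationConfig(maxRotationDeg = 0, maxTranslationFrac = 0,
                            scaleRange = c(1, 1), intensityOffsetFrac = 0)
  v <- array(runif(8 * 8 * 3), c(8, 8, 3))
  m <- array(rbinom(8 * 8 * 3, 1, 0.3), c(8, 8, 3))
  out <- augmentStudy(v, v, m, cfg)
  expect_equal(out$dwi, v)
  expect_equal(out$adc, v)
  expect_equal(out$mask, m)
})

test_that("a pure translation moves the mask centroid by the drawn amount", {
  cfg <- augmentationConfig(maxRotationDeg = 0, maxTranslationFrac = 0.15,
                            scaleRange = c(1, 1), intensityOffsetFrac = 0)
  d <- 32
  xy <- expand.grid(x = 1:d, y = 1:d)
  m <- array(as.numeric((xy$x - 16)^2 + (xy$y - 16)^2 <= 5^2), c(d, d, 1))
  set.seed(3)
  for (i in 1:5) {
    out <- augmentStudy(m, m, m, cfg)
    c0 <- colMeans(which(m[, , 1] == 1, arr.ind = TRUE))
    c1 <- colMeans(which(out$mask[, , 1] == 1, arr.ind = TRUE))
    expect_lt(abs((c1[1] - c0[1]) - out$draw$tx), 0.5)
    expect_lt(abs((c1[2] - c0[2]) - out$draw$ty), 0.5)
  }
})

test_that("geometric transport of image and mask agree (IoU >= 0.9)", {
  cfg <- augmentationConfig(intensityOffsetFrac = 0)
  d <- 48
  xy <- expand.grid(x = 1:d, y = 1:d)
  m <- array(as.numeric((xy$x - 22)^2 + (xy$y - 26)^2 <= 9^2), c(d, d, 1))
  set.seed(8)
  for (i in 1:5) {
    out <- augmentStudy(m, m, m, cfg)
    imgMask <- out$dwi[, , 1] > 0.5      # bilinear-transported "image"
    nnMask <- out$mask[, , 1] == 1       # nearest-transported mask
    iou <- sum(imgMask & nnMask) / sum(imgMask | nnMask)
    expect_gte(iou, 0.9)
  }
})

test_that("prepareInput stacks normalized channels on the network grid", {
  st <- generateStudy(tinyPhantomSpec(), TRUE, seed = 2)
  x <- prepareInput(st$record, targetXY = c(16L, 16L))
  expect_equal(dim(x), c(16, 16, 4, 2))
  expect_true(all(x >= 0 & x <= 1))
  x1 <- prepareInput(st$record, targetXY = c(16L, 16L),
                     channels = "adc_only")
  expect_equal(dim(x1)[4], 1)
  expect_equal(x1[, , , 1], x[, , , 2])
})
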