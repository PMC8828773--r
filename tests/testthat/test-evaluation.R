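test_that("AUROC handles separation, ties, and matches pROC", {
  expect_equal(aurocScore(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(aurocScore(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(aurocScore(runif(5), rep(1, 5)), "single-class")
  set.seed(40)
  sc <- round(runif(50), 1)  # plenty of ties
  y <- rbinom(50, 1, 0.5)
  expect_equal(aurocScore(sc, y), aurocPairOracle(sc, y), tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(aurocScore(sc, y),
                 as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(41)
  sc <- rnorm(60)
  y <- rbinom(60, 1, 0.4)
  a <- aurocScore(sc, y)
  expect_equal(aurocScore(exp(sc), y), a)
  expect_equal(aurocScore(qlogis(plogis(sc)), y), a, tolerance = 1e-12)
})

test_that("threshold-sweep ROC area equals the pair-count AUROC", {
  set.seed(42)
  sc <- runif(80)
  y <- rbinom(80, 1, 0.5)
  th <- c(Inf, sort(unique(sc), decreasing = TRUE), -Inf)
  sens <- sapply(th, function(t) mean(sc[y == 1] >= t))
  fpr <- sapply(th, function(t) mean(sc[y == 0] >= t))
  area <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  expect_equal(area, aurocScore(sc, y), tolerance = 1e-12)
})

test_that("bootstrap CIs are seeded, degenerate when the metric is constant, and shrink with n", {
  set.seed(43)
  sc <- c(runif(40, 0.6, 1), runif(40, 0, 0.4))
  y <- rep(c(1, 0), each = 40)
  f <- function(i) aurocScore(sc[i], y[i])
  ci1 <- bootstrapCI(f, 80, nIter = 500, seed = 7)
  ci2 <- bootstrapCI(f, 80, nIter = 500, seed = 7)
  expect_identical(ci1, ci2)
  # perfectly separated, ample data: every resample with both classes is 1
  expect_equal(ci1, c(1, 1, 1))

  # CI width shrinks from n = 100 to n = 400 (median over replicates)
  widths <- sapply(1:10, function(r) {
    sapply(c(100, 400), function(n) {
      set.seed(1000 + 17 * r + n)
      s <- rnorm(n, mean = 0.5 * rbinom(n, 1, 0.5))
      yy <- as.numeric(s > 0.25) * 0 + rbinom(n, 1, plogis(2 * s))
      g <- function(i) aurocScore(s[i], yy[i])
      ci <- bootstrapCI(g, n, nIter = 300, seed = r)
      ci[3] - ci[2]
    })
  })
  expect_lt(median(widths[2, ]), median(widths[1, ]))
})

test_that("an unbootstrappable metric raises an error", {
  # one positive among many: most resamples are single-class
  y <- c(1, rep(0, 9))
  sc <- runif(10)
  expect_error(bootstrapCI(function(i) aurocScore(sc[i], y[i]), 10,
                           nIter = 100, seed = 1),
               "more than half")
})

test_that("sensitivity and specificity follow the confusion-matrix arithmetic", {
  expect_equal(unname(sensitivitySpecificity(c(1, 1, 0, 0), c(1, 1, 0, 0))),
               c(1, 1))
  expect_equal(unname(sensitivitySpecificity(c(1, 0, 1, 0), c(1, 1, 1, 1))),
               c(1, 0))
  yt <- c(rep(1, 100), rep(0, 100))
  yp <- c(rep(1, 89), rep(0, 11), rep(0, 95), rep(1, 5))
  expect_equal(unname(sensitivitySpecificity(yt, yp)), c(0.89, 0.95))
  expect_error(sensitivitySpecificity(rep(0, 4), rep(0, 4)), "no positive")
})

test_that("Dice overlap matches the set formula", {
  a <- array(0, c(5, 5, 4)); a[1:40] <- 1
  expect_equal(diceCoefficient(a, a), 1)
  b <- array(0, c(5, 5, 4)); b[31:50] <- 1
  # |A|=40, |B|=20, overlap 10 -> 2*10/60
  expect_equal(diceCoefficient(a, b), 1 / 3)
  d <- array(0, c(5, 5, 4)); d[41:50] <- 1
  expect_equal(diceCoefficient(a, d), 0)
  # |A| = 100, |B| = 100, overlap 60 -> 2*60/200 = 0.6
  e <- array(0, c(10, 10, 2)); e[1:100] <- 1
  f <- array(0, c(10, 10, 2)); f[41:140] <- 1
  expect_equal(diceCoefficient(e, f), 0.6)
  expect_error(diceCoefficient(array(0, c(2, 2, 1)), array(0, c(2, 2, 1))),
               "both masks empty")
})

test_that("volume agreement recovers exact, shifted and noisy relations", {
  v <- c(1, 5, 10, 20, 40)
  ex <- volumeAgreement(v, v)
  expect_equal(ex$pearson, 1)
  expect_equal(ex$meanDiff, 0)
  expect_equal(c(ex$loaLower, ex$loaUpper), c(0, 0))
  sh <- volumeAgreement(v, v + 3)
  expect_equal(sh$pearson, 1)
  expect_equal(sh$meanDiff, 3)
  expect_equal(sh$loaUpper - sh$loaLower, 0)
  # agreement half-width ~ 1.96 sigma (median over replicates)
  halves <- sapply(1:20, function(r) {
    set.seed(600 + r)
    tv <- runif(50, 1, 60)
    pv <- tv + rnorm(50, sd = 4)
    va <- volumeAgreement(tv, pv)
    (va$loaUpper - va$loaLower) / 2
  })
  expect_equal(median(halves), 1.96 * 4, tolerance = 0.15)
  expect_error(volumeAgreement(rep(3, 5), runif(5)), "zero-variance")
})

test_that("Spearman correlation is antisymmetric with a permutation null", {
  p <- seq(0.1, 0.9, length.out = 20)
  up <- probabilityCovariateSpearman(p, seq_len(20))
  expect_equal(up$rho, 1)
  dn <- probabilityCovariateSpearman(p, rev(seq_len(20)))
  expect_equal(dn$rho, -1)
  expect_equal(up$rho, -dn$rho)
  set.seed(50)
  null <- replicate(200, {
    s <- probabilityCovariateSpearman(runif(30), runif(30))
    c(s$rho, s$p)
  })
  expect_lt(abs(mean(null[1, ])), 0.1)
  # p-values roughly uniform under the null
  expect_gt(suppressWarnings(ks.test(null[2, ], "punif"))$p.value, 0.01)
  expect_error(probabilityCovariateSpearman(runif(10), rep(2, 10)),
               "constant")
})

test_that("cohort evaluation rejects single-class cohorts", {
  maps <- lapply(1:4, function(i) array(0.9, c(2, 2, 1)))
  preds <- lapply(1:4, function(i) fakePrediction(paste0("s", i),
                                                  maps[[i]]))
  truths <- lapply(1:4, function(i)
    new("GroundTruth", mask = array(1, c(2, 2, 1)), trueVolumeML = 0.004,
        label = "positive"))
  expect_error(evaluateCohort(preds, truths, bootstrapIters = 10),
               "single-class")
})

test_that("shuffled labels drive AUROC to chance at n = 200", {
  set.seed(51)
  n <- 200
  scores <- runif(n)
  labels <- sample(rep(c(1, 0), each = n / 2))
  expect_lt(abs(aurocScore(scores, labels) - 0.5), 0.1)
})

test_that("reports serialize to JSON with the labelled agreement limits", {
  set.seed(52)
  preds <- truths <- vector("list", 12)
  for (i in 1:12) {
    pos <- i <= 6
    mask <- array(0, c(4, 4, 2))
    if (pos) mask[1:(2 + i)] <- 1
    pm <- mask * 0.9 + 0.02
    preds[[i]] <- fakePrediction(paste0("s", i), pm, spacing = c(10, 10, 10))
    truths[[i]] <- new("GroundTruth", mask = mask,
                       trueVolumeML = sum(mask),
                       label = if (pos) "positive" else "negative")
  }
  rep <- evaluateCohort(preds, truths, bootstrapIters = 50, seed = 2)
  f <- tempfile(fileext = ".json")
  writeReport(rep, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$n_studies, 12)
  expect_true(!is.null(j$bland_altman$overall$loaLower))
  expect_equal(j$auroc$point, 1)
})
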