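# shared miniature fixtures: everything is generated in code, at test time

# tiny phantom settings: 16x16x4 grid, lesions 3-5 mm on 2x2x4 mm voxels
tinyPhantomSpec <- function(seed = 1L) {
  phantomSpec(grid = c(16L, 16L, 4L), spacing = c(2, 2, 4),
              brainSemiAxes = c(6.5, 7, 1.8),
              lesionRadiusRange = c(3, 5), lesionCountRange = c(1L, 2L),
              seed = as.integer(seed))
}

# small network that keeps forward/backward in the millisecond range
tinyNetworkSpec <- function(inChannels = 2L) {
  networkSpec(inChannels = inChannels, depth = 2L, baseChannels = 4L)
}

# in-memory miniature cohort with explicit supervision-class counts
tinyCohort <- function(nSeg = 3, nClass = 3, nNeg = 6, seed = 1L,
                       spec = tinyPhantomSpec(seed)) {
  n <- nSeg + nClass + nNeg
  pos <- seq_len(n) <= nSeg + nClass
  recs <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    st <- generateStudy(spec, pos[i], seed = seed * 1000 + i,
                        studyId = sprintf("t%03d", i))
    r <- st$record
    if (i > nSeg && pos[i]) r@annotation@mask <- NULL  # classification-only
    recs[[i]] <- r
    truths[[i]] <- st$truth
  }
  list(records = recs, truths = truths)
}

# deterministic pseudo-prediction built directly from a probability map
fakePrediction <- function(id, probMap, spacing = c(1, 1, 1), op = 0.5) {
  s <- max(probMap)
  new("PredictionResult", studyId = id, probMap = probMap,
      probMapNative = probMap, studyProbability = s,
      label = if (s >= op) "positive" else "negative",
      predictedVolumeML = sum(probMap >= op) * prod(spacing) / 1000,
      operatingPoint = op)
}

# brute-force O(n^2) pair-counting AUROC oracle
aurocPairOracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
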