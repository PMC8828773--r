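# Construction of the z-preserving encoder-decoder network and the 2D->3D
# weight inflation. The numerical engine (im2col convolution, batch norm,
# pooling, backprop) lives in src/unet.cpp; this file owns the parameter
# layout, which is shared between the 2D (kernel z extent 1) and 3D (z
# extent 3) variants so that inflation is a pure reshape.

#' Construct a NetworkSpec
#'
#' @param inChannels input channels (2 for DWI + ADC, 1 for single-series
#'   ablation models).
#' @param depth number of xy pooling levels; the input x and y dimensions
#'   must be divisible by \code{2^depth}.
#' @param baseChannels channels at the first level, doubling per level.
#' @param leakySlope negative-side slope of the leaky ReLU (default 0.3).
#' @return a \code{\linkS4class{NetworkSpec}}.
#' @export
networkSpec <- function(inChannels = 2L, depth = 3L, baseChannels = 16L,
                        leakySlope = 0.3) {
  new("NetworkSpec", inChannels = as.integer(inChannels),
      depth = as.integer(depth), baseChannels = as.integer(baseChannels),
      leakySlope = leakySlope)
}

# block names in forward order; must match src/unet.cpp
unetBlockNames <- function(depth) {
  c(as.vector(t(outer(paste0("enc", seq_len(depth)), c("_c1", "_c2"),
                      paste0))),
    "bot_c1", "bot_c2",
    as.vector(t(outer(paste0("dec", rev(seq_len(depth))), c("_c1", "_c2"),
                      paste0))))
}

# (Cin, Cout) per block for a given spec
unetBlockChannels <- function(spec) {
  D <- spec@depth
  B <- spec@baseChannels
  ch <- list()
  for (l in seq_len(D)) {
    cin <- if (l == 1) spec@inChannels else B * 2^(l - 2)
    ch[[paste0("enc", l, "_c1")]] <- c(cin, B * 2^(l - 1))
    ch[[paste0("enc", l, "_c2")]] <- c(B * 2^(l - 1), B * 2^(l - 1))
  }
  ch[["bot_c1"]] <- c(B * 2^(D - 1), B * 2^D)
  ch[["bot_c2"]] <- c(B * 2^D, B * 2^D)
  for (l in rev(seq_len(D))) {
    ch[[paste0("dec", l, "_c1")]] <- c(3 * B * 2^(l - 1), B * 2^(l - 1))
    ch[[paste0("dec", l, "_c2")]] <- c(B * 2^(l - 1), B * 2^(l - 1))
  }
  ch
}

#' Build a 2D or 3D network with freshly initialized weights
#'
#' Convolution kernels are drawn from a fan-in-scaled normal distribution
#' (He initialization); biases and batch-norm shifts start at zero,
#' batch-norm scales at one, running statistics at (0, 1). The 2D variant is
#' identical except its kernels have z extent 1, so its weights can
#' initialize the central axial plane of the 3D kernels
#' ([inflate2dTo3d()]).
#'
#' @param spec a \code{\linkS4class{NetworkSpec}}.
#' @param dims 2 or 3.
#' @param seed integer seed for the weight draws.
#' @return a \code{\linkS4class{UNetModel}}.
#' @export
buildNetwork <- function(spec, dims = 3L, seed = 1L) {
  validObject(spec)
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  kz <- if (dims == 2L) 1L else 3L
  ch <- unetBlockChannels(spec)
  weights <- withSeed(seed, {
    w <- list()
    for (nm in unetBlockNames(spec@depth)) {
      cin <- ch[[nm]][1]
      cout <- ch[[nm]][2]
      fanIn <- 3 * 3 * kz * cin
      w[[paste0(nm, "_W")]] <- array(rnorm(fanIn * cout,
                                           sd = sqrt(2 / fanIn)),
                                     dim = c(3, 3, kz, cin, cout))
      w[[paste0(nm, "_b")]] <- numeric(cout)
      w[[paste0(nm, "_gamma")]] <- rep(1, cout)
      w[[paste0(nm, "_beta")]] <- numeric(cout)
      w[[paste0(nm, "_rmean")]] <- numeric(cout)
      w[[paste0(nm, "_rvar")]] <- rep(1, cout)
    }
    B <- spec@baseChannels
    w[["out_W"]] <- array(rnorm(B, sd = sqrt(1 / B)), dim = c(B, 1))
    w[["out_b"]] <- 0
    w
  })
  new("UNetModel", spec = spec, dims = dims, weights = weights)
}

#' Forward pass of a network on one study input
#'
#' Maps a 2-channel (or 1-channel) input grid to a same-grid voxel
#' probability map in (0, 1). In training mode batch-norm uses the
#' statistics of the given sample and returns updated running statistics;
#' in inference mode the stored running statistics are used and the pass is
#' deterministic.
#'
#' @param model a \code{\linkS4class{UNetModel}}.
#' @param x array of dim (nx, ny, nz, channels); nx and ny must be divisible
#'   by \code{2^depth}; nz is arbitrary.
#' @param training logical.
#' @param keepCache keep the activation cache for [networkBackward()].
#' @return list with \code{prob} (array nx x ny x nz), \code{cache}
#'   (external pointer or NULL) and \code{bnUpdates} (named list of updated
#'   running statistics when training).
#' @export
networkForward <- function(model, x, training = FALSE, keepCache = FALSE) {
  kz <- if (model@dims == 2L) 1L else 3L
  s <- model@spec
  res <- unet_forward_cpp(model@weights, x, s@depth, kz, s@inChannels,
                          s@baseChannels, s@leakySlope, training, keepCache)
  list(prob = res$prob,
       cache = if (keepCache) res$cache else NULL,
       bnUpdates = res$bn_updates)
}

#' Backward pass: gradients of a scalar loss through the network
#'
#' @param cache activation cache from [networkForward()] with
#'   \code{keepCache = TRUE}; consumed by this call.
#' @param dProb array, gradient of the loss with respect to the output
#'   probability map.
#' @return named list of gradients matching the weight layout (convolution
#'   kernels/biases and batch-norm scale/shift).
#' @export
networkBackward <- function(cache, dProb) {
  unet_backward_cpp(cache, as.numeric(dProb))
}

#' Global max-pooling classification head
#'
#' The study-level probability is the maximum voxel probability of the
#' segmentation output: if any voxel is positive the study is positive.
#' During training its subgradient routes through the argmax voxel.
#'
#' @param probMap probability volume with values in [0, 1].
#' @return scalar study probability.
#' @export
classificationHead <- function(probMap) {
  if (!length(probMap)) stop("empty probability map")
  max(probMap)
}

#' Inflate trained 2D weights into a 3D network
#'
#' Every 3x3 2D kernel becomes the central axial plane of a 3x3x3 kernel
#' whose other planes are zero; convolution biases and batch-norm
#' parameters (scale, shift and running statistics) are copied. In inference
#' mode the inflated 3D network is exactly slice-separable: its output on
#' any volume equals the 2D network applied slice by slice.
#'
#' @param model2d a trained 2D \code{\linkS4class{UNetModel}}.
#' @return a 3D \code{\linkS4class{UNetModel}} with the same spec.
#' @export
inflate2dTo3d <- function(model2d) {
  if (model2d@dims != 2L) stop("inflate2dTo3d expects a 2D model")
  w2 <- model2d@weights
  w3 <- list()
  for (nm in names(w2)) {
    v <- w2[[nm]]
    if (grepl("_W$", nm) && nm != "out_W") {
      d <- dim(v)
      stopifnot(d[3] == 1L)
      a <- array(0, dim = c(d[1], d[2], 3L, d[4], d[5]))
      a[, , 2L, , ] <- v
      w3[[nm]] <- a
    } else {
      w3[[nm]] <- v
    }
  }
  new("UNetModel", spec = model2d@spec, dims = 3L, weights = w3)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file; a JSON sidecar
#' (\code{<path>.json}) records the architecture so a checkpoint is
#' self-describing.
#'
#' @param model a \code{\linkS4class{UNetModel}}.
#' @param path checkpoint file path.
#' @return invisibly, \code{path}.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(inChannels = model@spec@inChannels, depth = model@spec@depth,
               baseChannels = model@spec@baseChannels,
               leakySlope = model@spec@leakySlope, dims = model@dims,
               weights = model@weights), path)
  jsonlite::write_json(list(inChannels = model@spec@inChannels,
                            depth = model@spec@depth,
                            baseChannels = model@spec@baseChannels,
                            leakySlope = model@spec@leakySlope,
                            dims = model@dims),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  new("UNetModel",
      spec = networkSpec(x$inChannels, x$depth, x$baseChannels,
                         x$leakySlope),
      dims = as.integer(x$dims), weights = x$weights)
}

# merge updated batch-norm running statistics into a model
applyBnUpdates <- function(model, bnUpdates) {
  for (nm in names(bnUpdates)) model@weights[[nm]] <- bnUpdates[[nm]]
  model
}
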