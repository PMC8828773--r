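# Synthetic paired DWI/ADC stroke phantoms.
#
# The phantom is deliberately simple: piecewise-constant ellipsoidal brain,
# lesions built from overlapping spheres that are DWI-bright and ADC-dark
# (restricted diffusion), optional T2 shine-through confounders bright on
# both series, additive Gaussian noise. It emulates the contrast logic the
# detector must learn, not MR physics.

# evaluate expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# deterministic per-study seed derivation from a master seed (counter based)
deriveSeed <- function(master, i) {
  as.integer((as.double(master) * 48271 + as.double(i) * 16807) %%
               2147483629)
}

# shine-through intensity factors: bright on BOTH series (no restricted
# diffusion), the classic false-positive pattern
SHINE_DWI_FACTOR <- 1.6
SHINE_ADC_FACTOR <- 1.5

#' Construct a PhantomSpec
#'
#' Defaults describe the study conditions used throughout the package's
#' synthetic experiments: a 64 x 64 x 16 grid at (3.4, 3.4, 5.0) mm (slice
#' thickness at the 5 mm admission bound), lesions of 1-3 overlapping
#' spheres with radii 5-12 mm, DWI lesion contrast x1.8 and ADC contrast
#' x0.45 against the brain base intensity, a 30% chance of a T2
#' shine-through confounder, and ~10% additive noise.
#'
#' @param grid integer(3) voxel grid.
#' @param spacing numeric(3) voxel spacing (mm).
#' @param brainSemiAxes ellipsoid semi-axes in voxels.
#' @param dwiBrain,dwiBackground,adcBrain,adcBackground base intensities.
#' @param lesionCountRange integer(2) spheres per lesion.
#' @param lesionRadiusRange numeric(2) sphere radii (mm).
#' @param dwiLesionContrast multiplicative DWI factor (> 1).
#' @param adcLesionContrast multiplicative ADC factor (in (0,1)).
#' @param shinethroughProb per-study confounder probability.
#' @param dwiNoiseSd,adcNoiseSd Gaussian noise sd.
#' @param biasField apply a smooth multiplicative field.
#' @param seed master seed; all per-study randomness derives from it.
#' @return a \code{\linkS4class{PhantomSpec}}.
#' @export
phantomSpec <- function(grid = c(64L, 64L, 16L), spacing = c(3.4, 3.4, 5.0),
                        brainSemiAxes = c(26, 29, 7),
                        dwiBrain = 400, dwiBackground = 40,
                        adcBrain = 800, adcBackground = 60,
                        lesionCountRange = c(1L, 3L),
                        lesionRadiusRange = c(5, 12),
                        dwiLesionContrast = 1.8, adcLesionContrast = 0.45,
                        shinethroughProb = 0.3,
                        dwiNoiseSd = 40, adcNoiseSd = 80,
                        biasField = FALSE, seed = 1L) {
  new("PhantomSpec", grid = as.integer(grid), spacing = as.numeric(spacing),
      brainSemiAxes = as.numeric(brainSemiAxes),
      dwiBrain = dwiBrain, dwiBackground = dwiBackground,
      adcBrain = adcBrain, adcBackground = adcBackground,
      lesionCountRange = as.integer(lesionCountRange),
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      dwiLesionContrast = dwiLesionContrast,
      adcLesionContrast = adcLesionContrast,
      shinethroughProb = shinethroughProb,
      dwiNoiseSd = dwiNoiseSd, adcNoiseSd = adcNoiseSd,
      biasField = biasField, seed = as.integer(seed))
}

# binary ellipsoid membership on the voxel grid (voxel units)
brainMask <- function(grid, semi) {
  cx <- (grid + 1) / 2
  x <- (seq_len(grid[1]) - cx[1]) / semi[1]
  y <- (seq_len(grid[2]) - cx[2]) / semi[2]
  z <- (seq_len(grid[3]) - cx[3]) / semi[3]
  o <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(o <= 1, dim = grid)
}

# sphere membership in physical mm around a (voxel-coordinate) centre
sphereMask <- function(grid, spacing, centre, radiusMM) {
  x <- (seq_len(grid[1]) - centre[1]) * spacing[1]
  y <- (seq_len(grid[2]) - centre[2]) * spacing[2]
  z <- (seq_len(grid[3]) - centre[3]) * spacing[3]
  o <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(o <= radiusMM^2, dim = grid)
}

# random point inside the brain ellipsoid shrunk by `margin`
randomBrainPoint <- function(grid, semi, margin = 0.7) {
  cx <- (grid + 1) / 2
  repeat {
    u <- runif(3, -1, 1)
    if (sum(u^2) <= 1) return(cx + u * semi * margin)
  }
}

#' Generate one synthetic DWI/ADC study with known ground truth
#'
#' Lesion voxels share one geometry across both series: DWI intensity is
#' raised by \code{dwiLesionContrast} and ADC lowered by
#' \code{adcLesionContrast} relative to the local brain intensity, before
#' noise. Shine-through confounders (drawn with probability
#' \code{shinethroughProb} for positive and negative studies alike) raise
#' both series and are never part of the ground-truth mask. Negative studies
#' have empty masks.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @param positive logical: simulate an infarct.
#' @param seed integer seed for this study (all randomness local).
#' @param studyId character id.
#' @return list with elements \code{record}
#'   (\code{\linkS4class{StudyRecord}}; annotation carries the true mask for
#'   positives) and \code{truth} (\code{\linkS4class{GroundTruth}}).
#' @export
generateStudy <- function(spec, positive, seed = spec@seed,
                          studyId = "phantom") {
  validObject(spec)
  g <- spec@grid
  withSeed(seed, {
    brain <- brainMask(g, spec@brainSemiAxes)
    dwi <- ifelse(brain, spec@dwiBrain, spec@dwiBackground)
    adc <- ifelse(brain, spec@adcBrain, spec@adcBackground)
    mask <- array(0, dim = g)
    if (positive) {
      for (try in 1:20) {
        n <- sample(spec@lesionCountRange[1]:spec@lesionCountRange[2], 1)
        c0 <- randomBrainPoint(g, spec@brainSemiAxes)
        les <- array(FALSE, dim = g)
        for (j in seq_len(n)) {
          r <- runif(1, spec@lesionRadiusRange[1], spec@lesionRadiusRange[2])
          jit <- if (j == 1) c(0, 0, 0) else
            rnorm(3, sd = r / (2 * spec@spacing))
          les <- les | sphereMask(g, spec@spacing, c0 + jit, r)
        }
        les <- les & brain
        if (any(les)) break
      }
      if (!any(les)) stop("could not place a lesion inside the brain")
      mask[les] <- 1
      dwi[les] <- dwi[les] * spec@dwiLesionContrast
      adc[les] <- adc[les] * spec@adcLesionContrast
    }
    if (runif(1) < spec@shinethroughProb) {
      cs <- randomBrainPoint(g, spec@brainSemiAxes)
      rs <- runif(1, spec@lesionRadiusRange[1], spec@lesionRadiusRange[2])
      shine <- sphereMask(g, spec@spacing, cs, rs) & brain & (mask == 0)
      dwi[shine] <- dwi[shine] * SHINE_DWI_FACTOR
      adc[shine] <- adc[shine] * SHINE_ADC_FACTOR
    }
    if (spec@biasField) {
      cx <- (g + 1) / 2
      fx <- 1 + 0.15 * sin(pi * seq_len(g[1]) / g[1])
      fy <- 1 + 0.15 * cos(pi * seq_len(g[2]) / g[2])
      fld <- outer(outer(fx, fy), rep(1, g[3]))
      dwi <- dwi * fld
      adc <- adc * fld
    }
    dwi <- dwi + rnorm(length(dwi), sd = spec@dwiNoiseSd)
    adc <- adc + rnorm(length(adc), sd = spec@adcNoiseSd)
    dim(dwi) <- g
    dim(adc) <- g
    label <- if (any(mask != 0)) "positive" else "negative"
    rec <- studyRecord(studyId, dwi, adc, spec@spacing, label = label,
                       mask = if (label == "positive") mask else NULL)
    truth <- new("GroundTruth", mask = mask,
                 trueVolumeML = sum(mask) * prod(spec@spacing) / 1000,
                 label = label)
    list(record = rec, truth = truth)
  })
}

#' Generate and write a synthetic cohort
#'
#' Writes per-study DWI, ADC and (where annotated) mask NIfTI volumes plus a
#' CSV manifest. Labels are Bernoulli(\code{prevalence}) draws unless
#' \code{exact = TRUE}, in which case exactly
#' \code{round(n * prevalence)} studies are positive (and the segmented count
#' exact as well). Within the \code{train} split only a fraction
#' \code{segmentedFraction} of positives carry a mask path
#' (classification-only positives); positives in \code{val}/\code{test}
#' splits always carry their mask so held-out segmentation metrics can be
#' computed, mirroring fully annotated validation and test sets.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}; \code{spec@seed} drives
#'   a deterministic counter-based per-study seed derivation, so the same
#'   spec reproduces the cohort file-for-file.
#' @param nStudies number of studies.
#' @param prevalence expected fraction positive.
#' @param segmentedFraction fraction of train-split positives that keep
#'   their segmentation mask in the manifest.
#' @param outDir output directory (created if needed).
#' @param splitFractions named fractions over \code{train}/\code{val}/
#'   \code{test}; default everything train.
#' @param exact force exact positive/segmented counts.
#' @return the manifest data.frame (also written to
#'   \code{file.path(outDir, "manifest.csv")}).
#' @export
generateCohort <- function(spec, nStudies, prevalence = 0.5,
                           segmentedFraction = 1.0, outDir,
                           splitFractions = c(train = 1), exact = FALSE) {
  stopifnot(nStudies >= 1)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  labels <- withSeed(deriveSeed(spec@seed, 0), {
    if (exact) {
      npos <- round(nStudies * prevalence)
      sample(rep(c(TRUE, FALSE), c(npos, nStudies - npos)))
    } else {
      runif(nStudies) < prevalence
    }
  })
  splits <- withSeed(deriveSeed(spec@seed, 1), {
    nm <- names(splitFractions)
    cnt <- round(nStudies * splitFractions / sum(splitFractions))
    cnt[1] <- nStudies - sum(cnt[-1])
    sample(rep(nm, cnt))
  })
  segFlag <- withSeed(deriveSeed(spec@seed, 2), {
    idx <- which(labels & splits == "train")
    f <- rep(FALSE, nStudies)
    if (length(idx)) {
      nseg <- if (exact) round(length(idx) * segmentedFraction) else
        rbinom(1, length(idx), segmentedFraction)
      f[sample(idx, nseg)] <- TRUE
    }
    f
  })
  rows <- vector("list", nStudies)
  for (i in seq_len(nStudies)) {
    id <- sprintf("phantom%04d", i)
    st <- generateStudy(spec, labels[i], seed = deriveSeed(spec@seed, i + 2),
                        studyId = id)
    dwiP <- file.path(outDir, paste0(id, "_dwi.nii.gz"))
    adcP <- file.path(outDir, paste0(id, "_adc.nii.gz"))
    writeVolume(st$record@dwi, spec@spacing, dwiP)
    writeVolume(st$record@adc, spec@spacing, adcP)
    maskP <- NA_character_
    keepMask <- labels[i] && (segFlag[i] || splits[i] != "train")
    if (keepMask) {
      maskP <- file.path(outDir, paste0(id, "_mask.nii.gz"))
      writeVolume(st$truth@mask, spec@spacing, maskP, mask = TRUE)
    }
    rows[[i]] <- data.frame(study_id = id, dwi_path = dwiP, adc_path = adcP,
                            label = ifelse(labels[i], "positive", "negative"),
                            mask_path = maskP, split = splits[i],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  # the CSV next to the volumes carries bare file names (loadManifest
  # resolves them against its own directory); the returned data.frame
  # carries absolute paths usable from any working directory
  onDisk <- manifest
  for (col in c("dwi_path", "adc_path", "mask_path"))
    onDisk[[col]] <- ifelse(is.na(onDisk[[col]]), NA, basename(onDisk[[col]]))
  writeManifest(onDisk, file.path(outDir, "manifest.csv"))
  for (col in c("dwi_path", "adc_path", "mask_path")) {
    ok <- !is.na(manifest[[col]])
    manifest[[col]][ok] <- normalizePath(manifest[[col]][ok])
  }
  manifest
}

#' Load every study of a manifest into memory
#'
#' @param manifest data.frame from [loadManifest()] or [generateCohort()].
#' @return named list of \code{\linkS4class{StudyRecord}} objects.
#' @export
loadCohort <- function(manifest) {
  out <- lapply(seq_len(nrow(manifest)), function(i) loadStudy(manifest[i, ]))
  names(out) <- manifest$study_id
  out
}
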