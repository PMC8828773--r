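test_that("volumes round-trip through NIfTI with identical values and spacing", {
  f <- tempfile(fileext = ".nii.gz")
  v <- array(7.0, c(8, 8, 4))
  writeVolume(v, c(1, 1, 5), f)
  r <- readVolume(f)
  expect_identical(r$volume, v)
  expect_equal(r$spacing, c(1, 1, 5))

  set.seed(11)
  v2 <- array(rnorm(10 * 12 * 3), c(10, 12, 3))
  writeVolume(v2, c(0.9, 0.9, 5.0), f)
  r2 <- readVolume(f)
  expect_equal(max(abs(r2$volume - v2)), 0)
  expect_equal(r2$spacing, c(0.9, 0.9, 5.0), tolerance = 1e-6)
})

test_that("masks are stored as unsigned integers and stay binary", {
  f <- tempfile(fileext = ".nii.gz")
  m <- array(rbinom(8 * 8 * 2, 1, 0.4), c(8, 8, 2))
  writeVolume(m, c(2, 2, 4), f, mask = TRUE)
  r <- readVolume(f)
  expect_true(all(r$volume %in% c(0, 1)))
  expect_identical(r$volume, array(as.numeric(m), dim(m)))
})

test_that("readVolume and writeVolume reject contract violations", {
  f <- tempfile(fileext = ".nii.gz")
  img4d <- RNifti::asNifti(array(0, c(4, 4, 2, 3)), internal = FALSE)
  RNifti::writeNifti(img4d, f)
  expect_error(readVolume(f), "non-3D")
  expect_error(readVolume(tempfile(fileext = ".nii")), "cannot read")
  v <- array(1, c(4, 4, 2)); v[1] <- NaN
  expect_error(writeVolume(v, c(1, 1, 1), f), "non-finite")
  expect_error(writeVolume(array(1, c(4, 4, 2)), c(1, 0, 1), f), "positive")
})

test_that("manifests load, normalize labels and flag structural errors", {
  d <- tempfile(); dir.create(d)
  for (s in c("a", "b", "c")) {
    writeVolume(array(0, c(4, 4, 2)), c(1, 1, 4),
                file.path(d, paste0(s, "_dwi.nii.gz")))
    writeVolume(array(0, c(4, 4, 2)), c(1, 1, 4),
                file.path(d, paste0(s, "_adc.nii.gz")))
  }
  mf <- file.path(d, "manifest.csv")
  writeLines(c("study_id,dwi_path,adc_path,label",
               "a,a_dwi.nii.gz,a_adc.nii.gz,Positive",
               "b,b_dwi.nii.gz,b_adc.nii.gz,NEGATIVE",
               "c,c_dwi.nii.gz,c_adc.nii.gz,negative"), mf)
  m <- loadManifest(mf)
  expect_equal(nrow(m), 3)
  expect_equal(m$label, c("positive", "negative", "negative"))
  expect_true(all(is.na(m$mask_path)))

  writeLines(c("study_id,dwi_path,adc_path,label",
               "a,a_dwi.nii.gz,a_adc.nii.gz,positive",
               "a,b_dwi.nii.gz,b_adc.nii.gz,negative"), mf)
  expect_error(loadManifest(mf), "duplicate study_id.*a")
  writeLines(c("study_id,dwi_path,adc_path,label",
               "a,a_dwi.nii.gz,a_adc.nii.gz,maybe"), mf)
  expect_error(loadManifest(mf), "unknown label")
  writeLines(c("study_id,dwi_path",
               "a,a_dwi.nii.gz"), mf)
  expect_error(loadManifest(mf), "missing required column")
})

test_that("validatePair accepts the 5 mm boundary and reports one violation per fault", {
  ok <- studyRecord("s", array(0, c(16, 16, 20)), array(0, c(16, 16, 20)),
                    c(1, 1, 5.0))
  expect_length(validatePair(ok), 0)

  thick <- ok; thick@spacing[3] <- 6.0
  expect_match(validatePair(thick), "slice thickness exceeds 5 mm")

  mism <- studyRecord("s", array(0, c(16, 16, 20)),
                      array(0, c(16, 16, 19)), c(1, 1, 5))
  expect_match(validatePair(mism), "does not match ADC grid")

  negsp <- ok; negsp@spacing[1] <- -1
  expect_match(validatePair(negsp), "positive", all = FALSE)

  badMask <- studyRecord("s", array(0, c(8, 8, 4)), array(0, c(8, 8, 4)),
                         c(1, 1, 4), label = "positive",
                         mask = array(1, c(8, 8, 3)))
  expect_match(validatePair(badMask), "mask grid", all = FALSE)

  # one violation string per fault, empty exactly when all invariants hold
  expect_length(validatePair(thick), 1)
  expect_length(validatePair(mism), 1)
})

test_that("supervision classes are derived from label and mask presence", {
  seg <- studyRecord("a", array(0, c(4, 4, 2)), array(0, c(4, 4, 2)),
                     c(1, 1, 4), label = "positive",
                     mask = array(1, c(4, 4, 2)))
  cls <- studyRecord("b", array(0, c(4, 4, 2)), array(0, c(4, 4, 2)),
                     c(1, 1, 4), label = "positive")
  neg <- studyRecord("c", array(0, c(4, 4, 2)), array(0, c(4, 4, 2)),
                     c(1, 1, 4))
  expect_equal(supervisionClass(seg), "segmented")
  expect_equal(supervisionClass(cls), "classonly")
  expect_equal(supervisionClass(neg), "negative")
})
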