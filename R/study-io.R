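#' Read a 3D volume from a NIfTI-1 file
#'
#' Reads a single 3D scalar volume and its voxel spacing from the NIfTI
#' header. Arrays are returned in (x, y, z) order with z indexing axial
#' slices; orientation metadata beyond voxel spacing is not interpreted.
#'
#' @param path path to a readable \code{.nii} or \code{.nii.gz} file.
#' @return list with elements \code{volume} (3D array) and \code{spacing}
#'   (numeric(3), mm).
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(array(7, c(8, 8, 4)), c(1, 1, 5), f)
#' v <- readVolume(f)
#' stopifnot(all(v$volume == 7), identical(v$spacing, c(1, 1, 5)))
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("non-3D image: ", path, " has ", length(d),
                            " dimensions")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(sp <= 0)) stop("non-positive voxel spacing in header of ", path)
  vol <- array(as.numeric(img), dim = d)
  list(volume = vol, spacing = as.numeric(sp))
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' Values round-trip bit-identically through [readVolume()] (volumes are
#' stored as 64-bit float, masks as unsigned 8-bit integer).
#'
#' @param volume 3D array of finite values.
#' @param spacing numeric(3), voxel dimensions in mm, all positive.
#' @param path destination file path.
#' @param mask logical; if \code{TRUE} the volume must be binary and is
#'   stored as an unsigned integer type.
#' @return invisibly, \code{path}.
#' @export
writeVolume <- function(volume, spacing, path, mask = FALSE) {
  if (length(dim(volume)) != 3L) stop("volume must be a 3D array")
  if (any(!is.finite(volume))) stop("volume contains non-finite values")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values")
  if (mask) {
    if (!all(volume %in% c(0, 1))) stop("mask volume must be binary")
    storage.mode(volume) <- "integer"
  }
  img <- RNifti::asNifti(volume, internal = FALSE)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = if (mask) "uint8" else "double")
  invisible(path)
}

#' Load a cohort manifest
#'
#' The manifest is a comma-separated table with header columns
#' \code{study_id,dwi_path,adc_path,label} and optional \code{mask_path} and
#' \code{split}. Labels are case-insensitive and normalized to
#' \code{"positive"}/\code{"negative"}. Relative paths are resolved against
#' the manifest's directory.
#'
#' @param path path to the CSV manifest.
#' @param checkPaths verify that every referenced file exists.
#' @return data.frame with columns \code{study_id}, \code{dwi_path},
#'   \code{adc_path}, \code{label}, \code{mask_path} (\code{NA} when absent)
#'   and \code{split}.
#' @export
loadManifest <- function(path, checkPaths = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("study_id", "dwi_path", "adc_path", "label")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop("manifest missing required column(s): ",
                         paste(miss, collapse = ", "))
  dup <- m$study_id[duplicated(m$study_id)]
  if (length(dup)) stop("duplicate study_id in manifest: ",
                        paste(unique(dup), collapse = ", "))
  lab <- tolower(trimws(m$label))
  bad <- setdiff(unique(lab), c("positive", "negative"))
  if (length(bad)) stop("unknown label value(s): ",
                        paste(bad, collapse = ", "))
  m$label <- lab
  if (is.null(m$mask_path)) m$mask_path <- NA_character_
  m$mask_path[!is.na(m$mask_path) & m$mask_path == ""] <- NA_character_
  if (is.null(m$split)) m$split <- NA_character_
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(is.na(p) | grepl("^/", p), p,
                                file.path(base, p))
  m$dwi_path <- resolve(m$dwi_path)
  m$adc_path <- resolve(m$adc_path)
  m$mask_path <- resolve(m$mask_path)
  if (checkPaths) {
    paths <- c(m$dwi_path, m$adc_path, m$mask_path[!is.na(m$mask_path)])
    gone <- paths[!file.exists(paths)]
    if (length(gone)) stop("manifest references missing file(s): ",
                           paste(utils::head(gone, 5), collapse = ", "))
  }
  m
}

#' Write a cohort manifest
#'
#' @param manifest data.frame as returned by [loadManifest()].
#' @param path destination CSV path.
#' @return invisibly, \code{path}.
#' @export
writeManifest <- function(manifest, path) {
  cols <- c("study_id", "dwi_path", "adc_path", "label", "mask_path",
            "split")
  utils::write.csv(manifest[, intersect(cols, names(manifest))], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct a StudyRecord
#'
#' @param studyId character scalar.
#' @param dwi,adc 3D arrays on the same voxel grid.
#' @param spacing numeric(3) voxel dimensions in mm.
#' @param label \code{"positive"} or \code{"negative"}.
#' @param mask optional binary 3D array.
#' @return a \code{\linkS4class{StudyRecord}}.
#' @export
studyRecord <- function(studyId, dwi, adc, spacing,
                        label = "negative", mask = NULL) {
  new("StudyRecord", studyId = as.character(studyId), dwi = dwi, adc = adc,
      spacing = as.numeric(spacing),
      annotation = new("Annotation", label = label, mask = mask))
}

#' Load one study (volumes, spacing and annotation) from a manifest row
#'
#' @param row single-row data.frame (one manifest record).
#' @return a \code{\linkS4class{StudyRecord}}.
#' @export
loadStudy <- function(row) {
  dwi <- readVolume(row$dwi_path)
  adc <- readVolume(row$adc_path)
  mask <- NULL
  if (!is.na(row$mask_path)) {
    mk <- readVolume(row$mask_path)
    mask <- array(as.numeric(mk$volume != 0), dim = dim(mk$volume))
  }
  studyRecord(row$study_id, dwi$volume, adc$volume, dwi$spacing,
              label = row$label, mask = mask)
}

#' Validate a DWI/ADC study pair
#'
#' Checks the cohort-admission invariants: DWI and ADC share one voxel grid,
#' all spacing components are positive, the slice thickness does not exceed
#' 5 mm (the boundary value 5 mm is accepted), there is at least one axial
#' slice, a mask (if present) matches the grid, and a negative study's mask
#' is empty. Mere invalidity never raises an error.
#'
#' @param record a \code{\linkS4class{StudyRecord}}.
#' @return character vector of violations; empty iff the record is valid.
#' @examples
#' r <- studyRecord("s1", array(0, c(8, 8, 4)), array(0, c(8, 8, 4)),
#'                  c(1, 1, 5))
#' stopifnot(length(validatePair(r)) == 0)
#' @export
validatePair <- function(record) {
  v <- character()
  ddw <- dim(record@dwi)
  dad <- dim(record@adc)
  if (!identical(ddw, dad))
    v <- c(v, sprintf("DWI grid (%s) does not match ADC grid (%s)",
                      paste(ddw, collapse = "x"),
                      paste(dad, collapse = "x")))
  if (any(record@spacing <= 0))
    v <- c(v, "voxel spacing components must all be positive")
  if (length(record@spacing) == 3L && record@spacing[3] > 5)
    v <- c(v, "slice thickness exceeds 5 mm")
  if (length(ddw) == 3L && ddw[3] < 1L)
    v <- c(v, "study must contain at least one axial slice")
  mk <- record@annotation@mask
  if (!is.null(mk)) {
    if (!identical(dim(mk), ddw))
      v <- c(v, sprintf("mask grid (%s) does not match study grid (%s)",
                        paste(dim(mk), collapse = "x"),
                        paste(ddw, collapse = "x")))
    if (identical(record@annotation@label, "negative") && any(mk != 0))
      v <- c(v, "negative study has a nonempty mask")
  }
  v
}

#' Supervision class of a manifest row or StudyRecord
#'
#' @param x manifest data.frame or a \code{StudyRecord}.
#' @return factor/character in \code{segmented}, \code{classonly},
#'   \code{negative}.
#' @export
supervisionClass <- function(x) {
  if (is(x, "StudyRecord")) {
    lab <- x@annotation@label
    seg <- !is.null(x@annotation@mask)
    return(if (lab == "negative") "negative"
           else if (seg) "segmented" else "classonly")
  }
  ifelse(x$label == "negative", "negative",
         ifelse(!is.na(x$mask_path), "segmented", "classonly"))
}
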