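# NIfTI / JSON / CSV interfaces.

#' Read a 3-D NIfTI volume
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @return an \linkS4class{ImageVolume}; spacing from the header pixdim,
#'   origin from the affine translation.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3-D volume, got ", length(d), "-D")
  px <- RNifti::pixdim(img)[1:3]
  aff <- RNifti::xform(img)
  imageVolume(array(as.numeric(img), d), spacing = px, origin = aff[1:3, 4])
}

#' Write a 3-D volume (or mask) as NIfTI
#'
#' @param volume \linkS4class{ImageVolume} or logical/numeric array.
#' @param path output path (.nii or .nii.gz).
#' @param spacing spacing when \code{volume} is a bare array.
#' @return the path, invisibly.
#' @export
writeVolume <- function(volume, path, spacing = c(1, 1, 1)) {
  if (is(volume, "ImageVolume")) {
    dat <- imgData(volume)
    spacing <- spacing(volume)
  } else dat <- volume + 0
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a displacement field as 4-D NIfTI
#'
#' The last axis holds the (x, y, z) vector components in mm, matching the
#' package's field convention.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param path file path.
#' @return \code{writeField}: the path, invisibly. \code{readField}: a
#'   \linkS4class{DisplacementField}.
#' @export
writeField <- function(field, path) {
  stopifnot(is(field, "DisplacementField"))
  img <- RNifti::asNifti(fieldVectors(field))
  RNifti::pixdim(img) <- c(spacing(field), 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeField
#' @export
readField <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4-D NIfTI with 3 components on the last axis")
  displacementField(array(as.numeric(img), d),
                    spacing = RNifti::pixdim(img)[1:3])
}

#' Serialize / read a histogram template as JSON
#'
#' @param template a \linkS4class{HistogramTemplate}.
#' @param path JSON file path.
#' @return \code{writeTemplate}: the path, invisibly; \code{readTemplate}:
#'   a \linkS4class{HistogramTemplate}.
#' @export
writeTemplate <- function(template, path) {
  stopifnot(is(template, "HistogramTemplate"))
  jsonlite::write_json(list(percentiles = template@percentiles,
                            intensities = template@intensities,
                            n_contributing = template@nContributing),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeTemplate
#' @export
readTemplate <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("HistogramTemplate", percentiles = as.numeric(x$percentiles),
      intensities = as.numeric(x$intensities),
      nContributing = as.integer(x$n_contributing))
}

#' Read / write the clinical table
#'
#' CSV with header subject_id, age_years, subgroup, chang, eor, metastasis,
#' os_days, event.
#'
#' @param clinical the clinical data.frame.
#' @param path CSV path.
#' @return \code{writeClinical}: the path, invisibly; \code{readClinical}:
#'   a data.frame.
#' @export
writeClinical <- function(clinical, path) {
  write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClinical
#' @export
readClinical <- function(path) {
  req <- c("subject_id", "age_years", "subgroup", "chang", "eor",
           "metastasis", "os_days", "event")
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("clinical table missing column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Write a cohort feature table as CSV
#'
#' One row per subject: subject_id followed by the 60 canonical band
#' feature columns.
#'
#' @param features the feature data.frame.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeFeatures <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
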