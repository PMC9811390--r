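#' ImageVolume: a 3-D scalar grid with physical voxel spacing
#'
#' The container shared by every spatial operation in the package: a 3-D
#' numeric array together with its voxel spacing (mm) and physical origin
#' (mm). The axis convention is (x, y, z) with x the fastest-varying array
#' dimension, matching NIfTI storage order.
#'
#' @slot data 3-D numeric array of voxel values.
#' @slot spacing numeric(3), voxel spacing in mm, all > 0.
#' @slot origin numeric(3), physical coordinate (mm) of voxel (1,1,1).
#'
#' @seealso [imageVolume()], [readVolume()], [writeVolume()]
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0))
)

setValidity("ImageVolume", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite reals (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite reals (mm)")
  if (any(!is.finite(object@data)))
    return("voxel values must be finite")
  TRUE
})

#' DisplacementField: per-voxel 3-vector displacements in mm
#'
#' Displacements live on the grid of the space they map from (for the
#' subject-to-atlas field produced by registration, the subject grid). The
#' mapped position of the voxel at physical location x is x + u(x). A zero
#' field maps every point to itself.
#'
#' @slot vectors 4-D numeric array (nx, ny, nz, 3); last axis is the (x,y,z)
#'   displacement component in mm.
#' @slot spacing numeric(3), voxel spacing (mm) of the grid.
#' @slot origin numeric(3), physical origin (mm).
#'
#' @seealso [registerVolumes()], [invertField()], [deformationMagnitude()]
#' @export
setClass("DisplacementField",
  representation(vectors = "array", spacing = "numeric", origin = "numeric"),
  prototype(vectors = array(0, c(1, 1, 1, 3)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0))
)

setValidity("DisplacementField", function(object) {
  d <- dim(object@vectors)
  if (length(d) != 4L || d[4] != 3L)
    return("vectors must be a 4-D array with 3 components on the last axis")
  if (any(!is.finite(object@vectors)))
    return("displacement components must be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive reals (mm)")
  TRUE
})

#' HistogramTemplate: intensity landmarks for histogram standardization
#'
#' Stores the landmark percentiles and the cohort-averaged intensities at
#' those percentiles, used for piecewise-linear (Nyul-style) intensity
#' standardization.
#'
#' @slot percentiles ascending numeric vector in (0, 100).
#' @slot intensities strictly ascending numeric vector, same length.
#' @slot nContributing number of volumes averaged into the template.
#'
#' @seealso [buildHistogramTemplate()], [standardizeIntensity()]
#' @export
setClass("HistogramTemplate",
  representation(percentiles = "numeric", intensities = "numeric",
                 nContributing = "integer")
)

setValidity("HistogramTemplate", function(object) {
  p <- object@percentiles
  v <- object@intensities
  if (length(p) < 2L || length(p) != length(v))
    return("need >= 2 landmarks with matching intensities")
  if (any(p <= 0) || any(p >= 100) || any(diff(p) <= 0))
    return("percentiles must be strictly ascending within (0, 100)")
  if (any(diff(v) <= 0))
    return("landmark intensities must be strictly increasing")
  TRUE
})

#' BandSet: nested annular band masks around the tumor edge
#'
#' Cumulative bands: band k contains all brain voxels outside the tumor with
#' distance-to-tumor-edge 0 < d <= k * width, so band k is a subset of band
#' k+1 and the outermost band reaches n_bands * width mm (60 mm for the
#' default 12 bands of 5 mm). A disjoint-shell mode (width*(k-1) < d <=
#' width*k) is available via \code{cumulative = FALSE} in [makeBands()].
#'
#' @slot bands list of logical 3-D arrays, one per band, innermost first.
#' @slot outerDistance numeric vector of band outer boundaries (mm).
#' @slot cumulative logical flag.
#'
#' @seealso [makeBands()], [distanceMap()]
#' @export
setClass("BandSet",
  representation(bands = "list", outerDistance = "numeric",
                 cumulative = "logical")
)

setValidity("BandSet", function(object) {
  if (length(object@bands) != length(object@outerDistance))
    return("one outer distance per band")
  if (length(object@bands) >= 1L && any(diff(object@outerDistance) <= 0))
    return("outer distances must be increasing")
  TRUE
})

#' RiskModel: LASSO-selected features, weights and the trained cutpoint
#'
#' The radiomic risk score (RRS) of a subject is the weighted sum of its
#' selected, z-scored band features; the cutpoint dichotomizes RRS into
#' low-/high-risk groups and is learned on the training cohort only.
#'
#' @slot features character vector of selected feature names.
#' @slot coefficients numeric vector of LASSO-Cox weights (one per feature).
#' @slot center,scale numeric vectors: the z-scoring parameters (training
#'   cohort mean / SD) for the selected features.
#' @slot cutpoint numeric(1); NA until [findCutpoint()] has been run.
#' @slot lambda numeric(1), the cross-validated penalty.
#' @slot trainingIds character vector of subject ids the model was fit on.
#'
#' @seealso [fitLassoCox()], [computeRRS()], [findCutpoint()]
#' @export
setClass("RiskModel",
  representation(features = "character", coefficients = "numeric",
                 center = "numeric", scale = "numeric", cutpoint = "numeric",
                 lambda = "numeric", trainingIds = "character"),
  prototype(cutpoint = NA_real_, lambda = NA_real_)
)

setValidity("RiskModel", function(object) {
  n <- length(object@features)
  if (length(object@coefficients) != n)
    return("one coefficient per selected feature")
  if (n > 0 && (length(object@center) != n || length(object@scale) != n))
    return("center/scale must match selected features")
  TRUE
})
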