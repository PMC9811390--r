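#' @name accessors
#' @title Accessors for deformBAT spatial classes
#'
#' @description \code{imgData} returns the raw array of an
#' \linkS4class{ImageVolume}; \code{spacing} and \code{origin} return the
#' voxel spacing and physical origin (mm); \code{fieldVectors} returns the
#' (nx, ny, nz, 3) displacement array of a \linkS4class{DisplacementField};
#' \code{bandMasks} returns the list of logical band masks of a
#' \linkS4class{BandSet}.
#'
#' @param x the object.
#' @return the slot value, never the object itself.
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname accessors
#' @export
setGeneric("fieldVectors", function(x) standardGeneric("fieldVectors"))

#' @rdname accessors
#' @export
setGeneric("bandMasks", function(x) standardGeneric("bandMasks"))

#' @rdname accessors
#' @export
setMethod("imgData", "ImageVolume", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("spacing", "DisplacementField", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("origin", "ImageVolume", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("origin", "DisplacementField", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("fieldVectors", "DisplacementField", function(x) x@vectors)

#' @rdname accessors
#' @export
setMethod("bandMasks", "BandSet", function(x) x@bands)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@vectors)
  mag <- sqrt(rowSums(matrix(object@vectors, ncol = 3)^2))
  cat(sprintf("DisplacementField %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  |u|: max %.3f mm, mean %.3f mm\n", max(mag), mean(mag)))
})

setMethod("show", "HistogramTemplate", function(object) {
  cat(sprintf("HistogramTemplate: %d landmarks from %d volumes\n",
              length(object@percentiles), object@nContributing))
  cat("  percentiles:", paste(object@percentiles, collapse = ", "), "\n")
})

setMethod("show", "BandSet", function(object) {
  cat(sprintf("BandSet: %d %s bands, outer boundaries %s mm\n",
              length(object@bands),
              if (object@cumulative) "cumulative" else "disjoint",
              paste(object@outerDistance, collapse = ", ")))
})

setMethod("show", "RiskModel", function(object) {
  cat(sprintf("RiskModel: %d selected feature(s)\n", length(object@features)))
  if (length(object@features))
    cat(paste(sprintf("  %s: %+.4f", object@features, object@coefficients),
              collapse = "\n"), "\n")
  cat(sprintf("  cutpoint: %s, lambda: %s\n",
              format(object@cutpoint), format(object@lambda)))
})

#' Construct an ImageVolume
#'
#' @param data 3-D numeric array.
#' @param spacing voxel spacing in mm (numeric(3) or scalar).
#' @param origin physical origin in mm.
#' @return an \linkS4class{ImageVolume}.
#' @examples
#' vol <- imageVolume(array(rnorm(8), c(2, 2, 2)), spacing = 1)
#' spacing(vol)
#' @export
imageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a DisplacementField
#'
#' @param vectors 4-D array (nx, ny, nz, 3), displacements in mm.
#' @param spacing voxel spacing in mm.
#' @param origin physical origin in mm.
#' @return a \linkS4class{DisplacementField}.
#' @export
displacementField <- function(vectors, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("DisplacementField", vectors = vectors, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}
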