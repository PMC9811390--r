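# Cumulative annular band construction around the infiltrating tumor edge
# and the five deformation-magnitude statistics per band (the 60-feature
# descriptor).

.BAND_STATS <- c("M", "MD", "STD", "SK", "K")

#' Canonical names of the 60 band features
#'
#' Stat-major order: M_5 ... M_60, MD_5 ... MD_60, STD_*, SK_*, K_5 ... K_60.
#' M = mean, MD = median, STD = standard deviation, SK = skewness, K =
#' (excess) kurtosis of the deformation magnitudes in the cumulative band
#' whose outer boundary (mm) is the suffix.
#'
#' @param width_mm band width in mm.
#' @param n_bands number of bands.
#' @return character vector of length 5 * n_bands.
#' @examples
#' head(bandFeatureNames())
#' @export
bandFeatureNames <- function(width_mm = 5, n_bands = 12) {
  dists <- width_mm * seq_len(n_bands)
  as.vector(t(outer(.BAND_STATS, dists, paste, sep = "_")))
}

#' Euclidean distance map from the tumor edge
#'
#' Exact anisotropic-spacing Euclidean distance from every voxel to the
#' nearest tumor voxel, retained only in brain-and-not-tumor; elsewhere NA.
#'
#' @param tumorMask logical array (nonempty, inside the brain).
#' @param brainMask logical array, same dimensions.
#' @param spacing voxel spacing in mm (numeric(3) or scalar).
#' @return numeric array: d > 0 in brain minus tumor, NA elsewhere.
#' @examples
#' tm <- array(FALSE, c(5, 5, 5)); tm[3, 3, 3] <- TRUE
#' bm <- array(TRUE, c(5, 5, 5))
#' d <- distanceMap(tm, bm, 1)
#' d[4, 3, 3]  # face neighbour at unit spacing -> 1
#' @export
distanceMap <- function(tumorMask, brainMask, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  dm <- dim(tumorMask)
  if (!identical(dm, dim(brainMask)))
    stop("tumor and brain masks must share dimensions")
  if (!any(tumorMask)) stop("empty tumor mask")
  if (!any(brainMask & !tumorMask))
    stop("tumor fills the brain mask: no brain-around-tumor region")
  d <- array(cpp_edt(as.logical(tumorMask), dm, as.numeric(spacing)), dm)
  d[!(brainMask & !tumorMask)] <- NA_real_
  d
}

#' Build cumulative (or disjoint) annular bands from a distance map
#'
#' Cumulative band k holds voxels with 0 < d <= k * width (each band
#' inclusive of the previous margins); with \code{cumulative = FALSE},
#' disjoint shells (k-1) * width < d <= k * width. The distance map already
#' restricts membership to brain-minus-tumor voxels. Empty bands are allowed
#' and flagged with a message.
#'
#' @param dmap distance map from [distanceMap()] (NA outside the region).
#' @param width_mm band width (mm), default 5.
#' @param n_bands number of bands, default 12 (outer boundary 60 mm).
#' @param cumulative logical, default TRUE.
#' @return a \linkS4class{BandSet}.
#' @export
makeBands <- function(dmap, width_mm = 5, n_bands = 12, cumulative = TRUE) {
  stopifnot(width_mm > 0, n_bands >= 1)
  outer <- width_mm * seq_len(n_bands)
  bands <- vector("list", n_bands)
  for (k in seq_len(n_bands)) {
    lo <- if (cumulative) 0 else outer[k] - width_mm
    b <- !is.na(dmap) & dmap > lo & dmap <= outer[k]
    bands[[k]] <- b
  }
  empty <- which(!vapply(bands, any, logical(1)))
  if (length(empty))
    message("empty band(s) at outer distance ",
            paste(outer[empty], collapse = ", "), " mm")
  new("BandSet", bands = bands, outerDistance = outer,
      cumulative = cumulative)
}

# population central-moment statistics with the degenerate convention
# SK = K = 0 when the variance vanishes; empty input -> all NA
.momStats <- function(v) {
  n <- length(v)
  if (n == 0L)
    return(c(M = NA_real_, MD = NA_real_, STD = NA_real_, SK = NA_real_,
             K = NA_real_))
  m <- mean(v)
  ctr <- v - m
  m2 <- mean(ctr^2)
  if (m2 <= 0) {
    sk <- 0
    ku <- 0
  } else {
    sk <- mean(ctr^3) / m2^1.5
    ku <- mean(ctr^4) / m2^2 - 3
  }
  c(M = m, MD = median(v), STD = sqrt(m2), SK = sk, K = ku)
}

#' Five statistics of deformation magnitudes within one band
#'
#' Mean, median, standard deviation (population, ddof = 0), skewness
#' (m3 / m2^1.5) and excess kurtosis (m4 / m2^2 - 3) over the in-band
#' magnitudes. Degenerate convention: a constant band has SK = K = 0; an
#' empty band yields all-NA.
#'
#' @param mag \linkS4class{ImageVolume} or numeric array of magnitudes.
#' @param band logical array, same dimensions.
#' @return named numeric(5): M, MD, STD, SK, K.
#' @examples
#' v <- array(c(0, 0, 0, 1, rep(0, 4)), c(2, 2, 2))
#' b <- array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2))
#' bandStatistics(v, b)  # M 0.25, SK 2/sqrt(3), K -2/3
#' @export
bandStatistics <- function(mag, band) {
  a <- if (is(mag, "ImageVolume")) imgData(mag) else mag
  if (!identical(dim(a), dim(band)))
    stop("magnitude map and band mask must share dimensions")
  .momStats(as.numeric(a[band]))
}

# shared worker: magnitudes + a distance array (any provenance) -> 60 stats
.bandFeaturesFromMaps <- function(mag, dmap, region, width_mm = 5,
                                  n_bands = 12) {
  outer <- width_mm * seq_len(n_bands)
  vals <- matrix(NA_real_, nrow = 5, ncol = n_bands,
                 dimnames = list(.BAND_STATS, NULL))
  d <- dmap[region]
  m <- mag[region]
  for (k in seq_len(n_bands))
    vals[, k] <- .momStats(m[d > 0 & d <= outer[k]])
  out <- as.vector(t(vals))
  names(out) <- as.vector(t(outer(.BAND_STATS, outer, paste, sep = "_")))
  out
}

#' Extract the 60-feature band descriptor for one subject
#'
#' Distance map, cumulative 5-mm bands to 60 mm, and the five statistics per
#' band, in the canonical stat-major order of [bandFeatureNames()]. Bands
#' clipped by the brain or image boundary are used as-is; empty bands yield
#' NA statistics.
#'
#' @param mag \linkS4class{ImageVolume} of deformation magnitudes (mm), or a
#'   numeric array.
#' @param tumorMask,brainMask logical arrays aligned to \code{mag}.
#' @param spacing voxel spacing (mm); taken from \code{mag} when it is an
#'   ImageVolume.
#' @param width_mm,n_bands band geometry (defaults 5 mm x 12).
#' @return named numeric of length 5 * n_bands (60 by default).
#' @export
extractFeatures <- function(mag, tumorMask, brainMask, spacing = NULL,
                            width_mm = 5, n_bands = 12) {
  if (is(mag, "ImageVolume")) {
    if (is.null(spacing)) spacing <- spacing(mag)
    a <- imgData(mag)
  } else {
    if (is.null(spacing)) stop("spacing required for a bare array")
    a <- mag
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  dmap <- distanceMap(tumorMask, brainMask, spacing)
  region <- !is.na(dmap)
  dmap[!region] <- 0
  .bandFeaturesFromMaps(a, dmap, region, width_mm, n_bands)
}

#' Assemble a feature table for a cohort
#'
#' Binds per-subject 60-feature vectors into a data.frame with a
#' \code{subject_id} column, in the canonical column order.
#'
#' @param featureList named list (or matrix) of per-subject feature vectors.
#' @param ids subject ids; defaults to the list names.
#' @return data.frame: subject_id + 60 feature columns.
#' @export
featureTable <- function(featureList, ids = names(featureList)) {
  m <- if (is.matrix(featureList)) featureList else do.call(rbind, featureList)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(m)))
  data.frame(subject_id = ids, as.data.frame(m), stringsAsFactors = FALSE,
             row.names = NULL)
}
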