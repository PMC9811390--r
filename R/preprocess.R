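# Bias-field correction and cohort-wide histogram-landmark intensity
# standardization, applied before registration.

#' Correct a smooth multiplicative bias field
#'
#' Estimates a smooth multiplicative inhomogeneity field as a low-order
#' polynomial fit to the in-mask log-intensities (two robust reweighting
#' iterations) and divides it out; the in-mask mean intensity is preserved.
#' The fit captures only slowly varying trends, leaving tissue contrast
#' intact. An external bias-correction backend can be substituted upstream;
#' this function defines the contract (smooth multiplicative field removal).
#'
#' @param volume \linkS4class{ImageVolume}.
#' @param mask logical array of brain voxels (nonempty; must exceed the
#'   number of polynomial coefficients).
#' @param order polynomial order (total degree), default 3.
#' @param maxVoxels fit at most this many in-mask voxels (deterministic
#'   stride subsample), default 20000.
#' @return bias-corrected \linkS4class{ImageVolume} (same grid).
#' @export
correctBias <- function(volume, mask, order = 3, maxVoxels = 20000) {
  stopifnot(is(volume, "ImageVolume"))
  v <- imgData(volume)
  if (!identical(dim(v), dim(mask))) stop("mask must match the volume")
  if (!any(mask)) stop("empty mask")
  if (all(v == 0)) stop("all-zero volume")
  dm <- dim(v)
  idx <- which(mask)
  # polynomial basis (total degree <= order) on [-1, 1]^3 coordinates
  basisCols <- function(ii) {
    ij <- arrayInd(ii, dm)
    nx <- 2 * (ij[, 1] - 1) / max(dm[1] - 1, 1) - 1
    ny <- 2 * (ij[, 2] - 1) / max(dm[2] - 1, 1) - 1
    nz <- 2 * (ij[, 3] - 1) / max(dm[3] - 1, 1) - 1
    cols <- list()
    for (k in 0:order) for (j in 0:order) for (i in 0:order)
      if (i + j + k <= order)
        cols[[length(cols) + 1L]] <- nx^i * ny^j * nz^k
    do.call(cbind, cols)
  }
  ncoef <- sum(outer(outer(0:order, 0:order, "+"), 0:order, "+") <= order)
  if (length(idx) <= ncoef)
    stop("mask too small for an order-", order, " bias fit")
  fitIdx <- idx[seq(1L, length(idx),
                    by = max(1L, length(idx) %/% maxVoxels))]
  eps <- 1e-6 * max(abs(v))
  y <- log(pmax(v[fitIdx], eps))
  X <- basisCols(fitIdx)
  w <- rep(1, length(y))
  for (it in 1:2) {
    fit <- lm.fit(X * sqrt(w), y * sqrt(w))
    co0 <- fit$coefficients
    co0[is.na(co0)] <- 0
    res <- as.numeric(y - X %*% co0)
    s <- stats::mad(res)
    w <- if (s > 0) 1 / (1 + (res / (3 * s))^2) else rep(1, length(y))
  }
  co <- fit$coefficients
  co[is.na(co)] <- 0
  logb <- as.numeric(basisCols(seq_along(v)) %*% co)
  logb <- logb - mean(logb[idx])          # unit-mean log-bias in mask
  out <- v / array(exp(logb), dm)
  out <- out * (mean(v[idx]) / mean(out[idx]))  # preserve in-mask mean
  imageVolume(array(out, dm), spacing(volume), origin(volume))
}

#' Build a cohort intensity histogram template
#'
#' Randomly selects \code{ceiling(fraction * n)} volumes (at least 2; the
#' selection is auto-raised to 2 with a warning if the fraction selects
#' fewer), computes each volume's in-mask intensities at the landmark
#' percentiles, and averages the landmarks across the selected volumes.
#'
#' @param volumes list of \linkS4class{ImageVolume}.
#' @param masks list of logical arrays, aligned with \code{volumes}.
#' @param fraction fraction of the cohort to select, in (0, 1].
#' @param percentiles landmark percentiles; default deciles plus 1 and 99.
#' @param seed integer seed for the random selection.
#' @return a \linkS4class{HistogramTemplate}.
#' @export
buildHistogramTemplate <- function(volumes, masks, fraction = 0.1,
                                   percentiles = c(1, seq(10, 90, by = 10),
                                                   99),
                                   seed = 1L) {
  n <- length(volumes)
  if (n < 2L) stop("need at least 2 volumes to build a template")
  stopifnot(length(masks) == n, fraction > 0, fraction <= 1)
  nsel <- ceiling(fraction * n)
  if (nsel < 2L) {
    warning("fraction selects fewer than 2 volumes; raised to 2")
    nsel <- 2L
  }
  sel <- withSeed(seed, sample.int(n, nsel))
  message("histogram template built from volumes: ",
          paste(sort(sel), collapse = ", "))
  lm <- vapply(sel, function(i) {
    vals <- imgData(volumes[[i]])[masks[[i]]]
    as.numeric(quantile(vals, percentiles / 100, names = FALSE))
  }, numeric(length(percentiles)))
  landmarks <- rowMeans(lm)
  if (any(diff(landmarks) <= 0))
    stop("degenerate template: landmark intensities are not increasing")
  new("HistogramTemplate", percentiles = as.numeric(percentiles),
      intensities = landmarks, nContributing = as.integer(nsel))
}

#' Standardize intensities to a histogram template
#'
#' Piecewise-linear landmark mapping: the volume's in-mask intensities at
#' the template percentiles are mapped onto the template landmark
#' intensities, interpolating linearly between landmarks and extrapolating
#' linearly beyond the first/last landmark. The map is monotone, so
#' intensity order is preserved; applying it twice is idempotent up to
#' interpolation error.
#'
#' @param volume \linkS4class{ImageVolume}.
#' @param mask logical array of brain voxels.
#' @param template a \linkS4class{HistogramTemplate}.
#' @return standardized \linkS4class{ImageVolume}.
#' @export
standardizeIntensity <- function(volume, mask, template) {
  stopifnot(is(volume, "ImageVolume"), is(template, "HistogramTemplate"))
  v <- imgData(volume)
  src <- as.numeric(quantile(v[mask], template@percentiles / 100,
                             names = FALSE))
  if (any(diff(src) <= 0))
    stop("degenerate in-mask intensity distribution: landmarks not distinct")
  tgt <- template@intensities
  k <- length(src)
  out <- array(NA_real_, dim(v))
  inside <- v >= src[1] & v <= src[k]
  out[inside] <- approx(src, tgt, xout = v[inside], ties = "ordered")$y
  sl1 <- (tgt[2] - tgt[1]) / (src[2] - src[1])
  slk <- (tgt[k] - tgt[k - 1]) / (src[k] - src[k - 1])
  lo <- v < src[1]
  hi <- v > src[k]
  out[lo] <- tgt[1] + sl1 * (v[lo] - src[1])
  out[hi] <- tgt[k] + slk * (v[hi] - src[k])
  imageVolume(out, spacing(volume), origin(volume))
}
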