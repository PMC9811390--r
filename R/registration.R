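# Age-bracket atlas selection, tumor-mask-excluded deformable registration
# (mutual information + cubic B-spline free-form deformation, affine
# initialization, multi-resolution), field inversion, and the per-voxel
# deformation-magnitude map.

#' Build an age-bracketed atlas set
#'
#' @param entries list of entries, each a list with \code{age_low},
#'   \code{age_high} (years), \code{volume} (\linkS4class{ImageVolume}) and
#'   \code{brainMask} (logical array). Brackets must be disjoint and
#'   ascending. The default pediatric brackets are 0-1, 1-5, 5-10 and 10-18
#'   years.
#' @return the validated list, classed \code{AtlasSet}.
#' @seealso [selectAtlas()], [defaultAgeBrackets()]
#' @export
atlasSet <- function(entries) {
  if (!length(entries)) stop("empty atlas set")
  lows <- vapply(entries, function(e) e$age_low, numeric(1))
  highs <- vapply(entries, function(e) e$age_high, numeric(1))
  if (any(highs <= lows)) stop("age_high must exceed age_low")
  o <- order(lows)
  entries <- entries[o]
  lows <- lows[o]
  highs <- highs[o]
  if (length(entries) > 1 && any(lows[-1] < highs[-length(highs)]))
    stop("age brackets overlap")
  structure(entries, class = "AtlasSet")
}

#' Default pediatric atlas age brackets (years)
#'
#' @return 4 x 2 matrix of (low, high) bracket bounds: 0-1, 1-5, 5-10, 10-18.
#' @export
defaultAgeBrackets <- function() {
  cbind(low = c(0, 1, 5, 10), high = c(1, 5, 10, 18))
}

#' Select the age-appropriate atlas
#'
#' Brackets are half-open [low, high): an age exactly at a boundary goes to
#' the older bracket; ages at or above the top bracket's upper bound map to
#' the oldest atlas.
#'
#' @param age_years nonnegative age in years.
#' @param atlases an [atlasSet()].
#' @return the selected atlas entry.
#' @export
selectAtlas <- function(age_years, atlases) {
  stopifnot(inherits(atlases, "AtlasSet"), age_years >= 0)
  for (e in atlases)
    if (age_years >= e$age_low && age_years < e$age_high) return(e)
  atlases[[length(atlases)]]
}

# dilate a mask to distance r_mm (Euclidean, anisotropic)
.dilateMask <- function(mask, spacing, r_mm) {
  if (is.null(mask) || r_mm <= 0) return(mask)
  d <- array(cpp_edt(as.logical(mask), dim(mask), as.numeric(spacing)),
             dim(mask))
  d <= r_mm
}

# lattice geometry for a cubic B-spline FFD covering the grid
.ffdLattice <- function(dim, spacing, cspacing) {
  ext <- (dim - 1) * spacing
  list(cdim = as.integer(ceiling(ext / cspacing) + 4L),
       corigin = rep(-cspacing, 3), cspacing = cspacing)
}

#' Mutual information between a fixed and a (warped) moving volume
#'
#' The registration metric, exposed directly: Mattes-style mutual
#' information over the sample voxels (32 bins by default), with the moving
#' volume optionally displaced by a field. Voxels inside
#' \code{exclusionMask} never contribute, so intensities there cannot
#' influence the metric.
#'
#' @param fixed,moving \linkS4class{ImageVolume}s on the same grid.
#' @param field optional \linkS4class{DisplacementField} applied to the
#'   sampling positions.
#' @param exclusionMask optional logical array (e.g. tumor) excluded from
#'   the metric.
#' @param sampleMask optional logical array restricting the samples (default
#'   all voxels).
#' @param nbins histogram bins, default 32.
#' @return list with \code{mi} (mutual information, nats) and \code{n}
#'   (samples used).
#' @export
miMetric <- function(fixed, moving, field = NULL, exclusionMask = NULL,
                     sampleMask = NULL, nbins = 32L) {
  dm <- dim(imgData(fixed))
  if (!identical(dm, dim(imgData(moving))))
    stop("fixed and moving must share the grid")
  sel <- if (is.null(sampleMask)) array(TRUE, dm) else sampleMask
  if (!is.null(exclusionMask)) sel <- sel & !exclusionMask
  samples <- which(sel) - 1L
  fvals <- imgData(fixed)[sel]
  fr <- range(fvals)
  mr <- range(imgData(moving))
  lat <- .ffdLattice(dm, spacing(fixed), 40)
  base <- if (is.null(field)) numeric(0) else as.numeric(fieldVectors(field))
  res <- cpp_mi_ffd(as.numeric(imgData(fixed)), as.numeric(imgData(moving)),
                    dm, spacing(fixed), samples,
                    c(diag(3)[1, ], diag(3)[2, ], diag(3)[3, ], 0, 0, 0),
                    base, numeric(prod(lat$cdim) * 3), lat$cdim,
                    lat$corigin, lat$cspacing, fr, mr, as.integer(nbins), 0L)
  list(mi = -res$value, n = res$n)
}

#' Registration configuration
#'
#' @param nbins MI histogram bins (32).
#' @param controlSpacing B-spline control-point spacing per level, mm
#'   (coarse to fine).
#' @param smoothingSigma Gaussian smoothing per level, mm.
#' @param stride sample stride (voxels) per level.
#' @param maxit L-BFGS-B iterations per level.
#' @param affine run the affine initialization stage (Nelder-Mead on the
#'   same MI metric) before the deformable stages.
#' @param affineMaxit Nelder-Mead iterations for the affine stage.
#' @return a list of class \code{RegistrationConfig}.
#' @export
registrationConfig <- function(nbins = 32L, controlSpacing = c(40, 20, 10),
                               smoothingSigma = c(4, 2, 0),
                               stride = c(4L, 2L, 1L),
                               maxit = c(60L, 60L, 40L), affine = TRUE,
                               affineMaxit = 200L) {
  stopifnot(length(controlSpacing) == length(smoothingSigma),
            length(controlSpacing) == length(stride),
            length(controlSpacing) == length(maxit))
  structure(list(nbins = as.integer(nbins), controlSpacing = controlSpacing,
                 smoothingSigma = smoothingSigma, stride = as.integer(stride),
                 maxit = as.integer(maxit), affine = affine,
                 affineMaxit = as.integer(affineMaxit)),
            class = "RegistrationConfig")
}

.identityAffine <- function() c(1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0)

.smoothVol <- function(v, dm, sp, sigma_mm) {
  if (sigma_mm <= 0) return(v)
  array(cpp_smooth3(as.numeric(v), dm, sigma_mm / sp), dm)
}

# strided sample indices (0-based) from a logical selection
.strideSamples <- function(sel, dm, stride) {
  if (stride > 1L) {
    keep <- array(FALSE, dm)
    keep[seq(1L, dm[1], by = stride), seq(1L, dm[2], by = stride),
         seq(1L, dm[3], by = stride)] <- TRUE
    sel <- sel & keep
  }
  which(sel) - 1L
}

#' Deformable registration of two volumes (MI + B-spline FFD)
#'
#' Multi-resolution deformable registration: an affine initialization
#' (Nelder-Mead on the mutual-information metric), then cubic B-spline
#' free-form deformation levels with decreasing control-point spacing,
#' optimized by L-BFGS-B with analytic MI gradients. The metric is computed
#' only over voxels outside \code{exclusionMask} (metric masking, not
#' zero-filling); at smoothed levels the exclusion is dilated by twice the
#' smoothing sigma so smeared excluded intensity stays out of the metric.
#' The returned field u satisfies \code{moving(x + u(x)) ~ fixed(x)}: it is
#' the mapping from fixed space into moving space, on the fixed grid, in mm,
#' including the affine component. Jacobian determinants of the final map
#' are checked; if folding is detected the field is smoothed (up to 3 x 1
#' voxel Gaussian) and the check logged.
#'
#' @param fixed,moving \linkS4class{ImageVolume}s on the same grid.
#' @param exclusionMask optional logical array in fixed space (e.g. the
#'   tumor mask when the fixed volume is the subject).
#' @param sampleMask optional logical array restricting metric samples.
#' @param config a [registrationConfig()].
#' @return a \linkS4class{DisplacementField} with attributes
#'   \code{finalMI}, \code{minJacobian}, \code{affine}.
#' @export
registerVolumes <- function(fixed, moving, exclusionMask = NULL,
                            sampleMask = NULL,
                            config = registrationConfig()) {
  stopifnot(is(fixed, "ImageVolume"), is(moving, "ImageVolume"))
  dm <- dim(imgData(fixed))
  sp <- spacing(fixed)
  if (!identical(dm, dim(imgData(moving))) ||
      max(abs(sp - spacing(moving))) > 1e-9)
    stop("fixed and moving must share grid shape and spacing")
  fv <- as.numeric(imgData(fixed))
  mv <- as.numeric(imgData(moving))
  thrF <- min(fv) + 0.01 * diff(range(fv))
  thrM <- min(mv) + 0.01 * diff(range(mv))
  if (!any(fv > thrF & mv > thrM))
    stop("non-overlapping fields of view: no voxel informative in both")
  nvox <- prod(dm)
  baseSel <- if (is.null(sampleMask)) array(TRUE, dm) else sampleMask
  mr <- range(mv)
  aff <- .identityAffine()

  levelSetup <- function(lvl) {
    sig <- config$smoothingSigma[lvl]
    fS <- .smoothVol(imgData(fixed), dm, sp, sig)
    mS <- .smoothVol(imgData(moving), dm, sp, sig)
    excl <- .dilateMask(exclusionMask, sp, 2 * sig)
    sel <- baseSel
    if (!is.null(excl)) sel <- sel & !excl
    samples <- .strideSamples(sel, dm, config$stride[lvl])
    list(f = as.numeric(fS), m = as.numeric(mS), samples = samples,
         fr = range(fS[samples + 1L]))
  }

  # --- affine initialization on the coarsest level ---
  if (config$affine) {
    ls <- levelSetup(1L)
    lat <- .ffdLattice(dm, sp, config$controlSpacing[1])
    zero <- numeric(prod(lat$cdim) * 3)
    affObj <- function(p) {
      A <- .identityAffine()
      A[1:9] <- A[1:9] + p[4:12]
      A[10:12] <- p[1:3]
      r <- cpp_mi_ffd(ls$f, ls$m, dm, sp, ls$samples, A, numeric(0), zero,
                      lat$cdim, lat$corigin, lat$cspacing, ls$fr, mr,
                      config$nbins, 0L)
      if (is.na(r$value)) 10 else r$value
    }
    op <- optim(rep(0, 12), affObj, method = "Nelder-Mead",
                control = list(maxit = config$affineMaxit,
                               parscale = c(rep(max(sp), 3), rep(0.05, 9))))
    aff <- .identityAffine()
    aff[1:9] <- aff[1:9] + op$par[4:12]
    aff[10:12] <- op$par[1:3]
  }

  # --- multi-resolution FFD levels ---
  uCur <- numeric(3 * nvox)
  finalMI <- NA_real_
  for (lvl in seq_along(config$controlSpacing)) {
    ls <- levelSetup(lvl)
    lat <- .ffdLattice(dm, sp, config$controlSpacing[lvl])
    npar <- prod(lat$cdim) * 3
    cache <- new.env()
    evalBoth <- function(p) {
      key <- !is.null(cache$par) && identical(cache$par, p)
      if (!key) {
        r <- cpp_mi_ffd(ls$f, ls$m, dm, sp, ls$samples, aff, uCur, p,
                        lat$cdim, lat$corigin, lat$cspacing, ls$fr, mr,
                        config$nbins, 1L)
        cache$par <- p
        cache$val <- if (is.na(r$value)) 10 else r$value
        cache$grad <- if (is.null(r$grad)) rep(0, npar) else r$grad
      }
      NULL
    }
    op <- optim(numeric(npar),
                fn = function(p) { evalBoth(p); cache$val },
                gr = function(p) { evalBoth(p); cache$grad },
                method = "L-BFGS-B",
                control = list(maxit = config$maxit[lvl]))
    uCur <- uCur + as.numeric(cpp_ffd_eval(op$par, lat$cdim, lat$corigin,
                                           lat$cspacing, dm, sp))
    finalMI <- -op$value
  }

  # --- compose with the affine: u_tot(p) = A (p + u(p)) - p ---
  g <- .gridCoords(dm, sp)
  px <- array(rep(g$x, times = dm[2] * dm[3]), dm) + array(uCur[1:nvox], dm)
  py <- array(rep(rep(g$y, each = dm[1]), times = dm[3]), dm) +
    array(uCur[nvox + 1:nvox], dm)
  pz <- array(rep(g$z, each = dm[1] * dm[2]), dm) +
    array(uCur[2 * nvox + 1:nvox], dm)
  vec <- array(0, c(dm, 3))
  vec[, , , 1] <- aff[1] * px + aff[2] * py + aff[3] * pz + aff[10] -
    array(rep(g$x, times = dm[2] * dm[3]), dm)
  vec[, , , 2] <- aff[4] * px + aff[5] * py + aff[6] * pz + aff[11] -
    array(rep(rep(g$y, each = dm[1]), times = dm[3]), dm)
  vec[, , , 3] <- aff[7] * px + aff[8] * py + aff[9] * pz + aff[12] -
    array(rep(g$z, each = dm[1] * dm[2]), dm)

  # --- approximate-diffeomorphism guard: Jacobian check + smoothing ---
  minJac <- .minJacobian(vec, sp)
  tries <- 0
  while (minJac <= 0 && tries < 3) {
    message("field folding detected (min Jacobian ", signif(minJac, 3),
            "); smoothing displacement field")
    for (c in 1:3)
      vec[, , , c] <- array(cpp_smooth3(as.numeric(vec[, , , c]), dm,
                                        rep(1, 3)), dm)
    minJac <- .minJacobian(vec, sp)
    tries <- tries + 1
  }

  out <- displacementField(vec, sp, origin(fixed))
  attr(out, "finalMI") <- finalMI
  attr(out, "minJacobian") <- minJac
  attr(out, "affine") <- aff
  out
}

# minimum Jacobian determinant of x + u(x) by central differences
.minJacobian <- function(vec, sp) {
  dm <- dim(vec)[1:3]
  J <- array(1, dm)
  d <- function(a, ax) {
    n <- dm[ax]
    idx1 <- pmin(seq_len(n) + 1L, n)
    idx0 <- pmax(seq_len(n) - 1L, 1L)
    den <- (idx1 - idx0) * sp[ax]
    if (ax == 1) (a[idx1, , , drop = FALSE] - a[idx0, , , drop = FALSE]) /
      array(den, dm)
    else if (ax == 2) (a[, idx1, , drop = FALSE] - a[, idx0, , drop = FALSE]) /
      array(rep(den, each = dm[1]), dm)
    else (a[, , idx1, drop = FALSE] - a[, , idx0, drop = FALSE]) /
      array(rep(den, each = dm[1] * dm[2]), dm)
  }
  g <- list()
  for (c in 1:3) for (ax in 1:3)
    g[[paste0(c, ax)]] <- d(vec[, , , c], ax) + as.numeric(c == ax)
  det <- g[["11"]] * (g[["22"]] * g[["33"]] - g[["23"]] * g[["32"]]) -
    g[["12"]] * (g[["21"]] * g[["33"]] - g[["23"]] * g[["31"]]) +
    g[["13"]] * (g[["21"]] * g[["32"]] - g[["22"]] * g[["31"]])
  min(det)
}

#' Invert a displacement field
#'
#' Fixed-point inversion: finds v with u(y + v(y)) + v(y) = 0, so composing
#' the field with its inverse displaces points by (near) zero. Errors if the
#' composition residual still exceeds \code{maxResidual} voxels after
#' \code{maxit} iterations.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param maxit maximum fixed-point iterations (default 50).
#' @param maxResidual admissible RMS composition residual, in voxels
#'   (default 0.1).
#' @return the inverse \linkS4class{DisplacementField}, with attribute
#'   \code{rmsResidual} (mm).
#' @export
invertField <- function(field, maxit = 50L, maxResidual = 0.1) {
  stopifnot(is(field, "DisplacementField"))
  dm <- dim(fieldVectors(field))[1:3]
  sp <- spacing(field)
  res <- cpp_invert_field(as.numeric(fieldVectors(field)), dm, sp,
                          as.integer(maxit), 0.005 * min(sp))
  if (res$rms_mm > maxResidual * min(sp))
    stop(sprintf(
      "field inversion did not converge: composition residual %.4f mm (%.3f voxels)",
      res$rms_mm, res$rms_mm / min(sp)))
  out <- displacementField(array(res$field, c(dm, 3)), sp, origin(field))
  attr(out, "rmsResidual") <- res$rms_mm
  out
}

#' Per-voxel deformation magnitude map
#'
#' Euclidean norm sqrt(ux^2 + uy^2 + uz^2) of the displacement vectors, in
#' mm, set to zero outside the brain mask.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param brainMask optional logical array; \code{NULL} keeps all voxels.
#' @return an \linkS4class{ImageVolume} of magnitudes (mm).
#' @export
deformationMagnitude <- function(field, brainMask = NULL) {
  stopifnot(is(field, "DisplacementField"))
  v <- fieldVectors(field)
  dm <- dim(v)[1:3]
  if (!is.null(brainMask) && !identical(dm, dim(brainMask)))
    stop("brain mask does not match the field grid")
  mag <- sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
  if (!is.null(brainMask)) mag[!brainMask] <- 0
  imageVolume(mag, spacing(field), origin(field))
}

#' Full deformation pipeline for one subject
#'
#' Selects the age-appropriate atlas, registers it to the subject with the
#' tumor excluded from the metric (forward field), inverts the field to
#' obtain the subject-to-atlas tissue deformation, and returns the
#' deformation-magnitude map on the subject grid. Supplying \code{field}
#' bypasses registration and inversion entirely (the injected ground-truth
#' field's magnitudes are returned): a first-class testing interface.
#'
#' @param subject preprocessed \linkS4class{ImageVolume}.
#' @param tumorMask,brainMask logical arrays aligned to the subject.
#' @param atlases an [atlasSet()].
#' @param age subject age in years.
#' @param field optional injected ground-truth
#'   \linkS4class{DisplacementField} (bypass mode).
#' @param config a [registrationConfig()].
#' @return \linkS4class{ImageVolume} of deformation magnitudes (mm), zero
#'   outside the brain.
#' @export
deformationPipeline <- function(subject, tumorMask, brainMask, atlases, age,
                                field = NULL,
                                config = registrationConfig()) {
  if (!is.null(field))
    return(deformationMagnitude(field, brainMask))
  entry <- selectAtlas(age, atlases)
  fwd <- registerVolumes(subject, entry$volume, exclusionMask = tumorMask,
                         config = config)
  inv <- invertField(fwd, maxResidual = 0.5)
  deformationMagnitude(inv, brainMask)
}
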