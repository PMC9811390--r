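# Synthetic phantom cohort generator: ellipsoidal brain atlases, tumors with
# analytically known radial displacement fields, and survival outcomes drawn
# from a proportional-hazards model on the ground-truth band features. Every
# downstream stage of the pipeline can therefore be checked against an exact
# or statistical oracle.

#' Run an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so the caller's RNG stream is
#' untouched. All randomness in the package flows through explicit seeds via
#' this helper.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @examples
#' identical(withSeed(1, rnorm(3)), withSeed(1, rnorm(3)))
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a named sub-seed from a master seed
#'
#' A named-stream splitter: each pipeline stage draws its seed from the
#' master seed plus a stage name, so stages are independently reproducible.
#' The result is always in [0, 2^31 - 2].
#' @param seed master integer seed.
#' @param name stream name (character).
#' @return an integer seed.
#' @examples
#' streamSeed(1, "cohort") != streamSeed(1, "split")
#' @export
streamSeed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807) %% 2147483647)
}

#' Phantom atlas configuration
#'
#' @param grid_shape integer(3), grid size in voxels.
#' @param spacing_mm numeric(3) or scalar, voxel spacing in mm.
#' @param brain_semi_axes_mm numeric(3), ellipsoid semi-axes in mm; the
#'   ellipsoid (centered in the grid) must fit inside it.
#' @param tissue_intensity_levels intensities of the concentric tissue
#'   shells, innermost first.
#' @param noise_sd additive Gaussian noise SD (>= 0).
#' @param bias_field_order polynomial order of a multiplicative bias field
#'   applied to simulated subjects (0 = none).
#' @param seed integer seed.
#' @return a validated list of class \code{PhantomConfig}.
#' @export
phantomConfig <- function(grid_shape = c(64L, 64L, 64L),
                          spacing_mm = c(2.5, 2.5, 2.5),
                          brain_semi_axes_mm = c(70, 75, 65),
                          tissue_intensity_levels = c(110, 60, 100, 40),
                          noise_sd = 2, bias_field_order = 0L, seed = 1L) {
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4),
            all(spacing_mm > 0), length(brain_semi_axes_mm) == 3L,
            all(brain_semi_axes_mm > 0), noise_sd >= 0,
            bias_field_order >= 0)
  ext <- (grid_shape - 1) * spacing_mm
  if (any(2 * brain_semi_axes_mm > ext))
    stop("brain ellipsoid does not fit inside the grid")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 brain_semi_axes_mm = as.numeric(brain_semi_axes_mm),
                 tissue_intensity_levels = as.numeric(tissue_intensity_levels),
                 noise_sd = noise_sd,
                 bias_field_order = as.integer(bias_field_order),
                 seed = as.integer(seed)),
            class = "PhantomConfig")
}

#' Tumor deformation simulation configuration
#'
#' The displacement magnitude model is
#' \deqn{m(d, \theta) = A_0 (1 + h \cos(k\theta)) e^{-d/\tau}}
#' with \eqn{d} the distance (mm) from the tumor surface, \eqn{\theta} the
#' azimuthal angle about the z-axis through the tumor center, amplitude
#' \eqn{A_0} (mm), decay length \eqn{\tau} (mm), heterogeneity \eqn{h \in
#' [0,1]} and angular harmonic \eqn{k}. Displacements point radially away
#' from the tumor center and vanish inside the tumor and as d grows.
#'
#' @param tumor_center_mm numeric(3), tumor center (mm); \code{NULL} centers
#'   it in the grid.
#' @param tumor_radius_mm tumor sphere radius (mm).
#' @param amplitude_A0_mm peak displacement amplitude at the surface (mm).
#' @param decay_tau_mm exponential decay length (mm).
#' @param heterogeneity_h angular modulation depth in [0, 1].
#' @param angular_harmonic positive integer harmonic k.
#' @param seed integer seed.
#' @return a validated list of class \code{DeformationSimConfig}.
#' @export
deformationConfig <- function(tumor_center_mm = NULL, tumor_radius_mm = 10,
                              amplitude_A0_mm = 4, decay_tau_mm = 10,
                              heterogeneity_h = 0.3, angular_harmonic = 2L,
                              seed = 1L) {
  stopifnot(tumor_radius_mm > 0, amplitude_A0_mm >= 0, decay_tau_mm > 0,
            heterogeneity_h >= 0, heterogeneity_h <= 1,
            angular_harmonic >= 1)
  structure(list(tumor_center_mm = tumor_center_mm,
                 tumor_radius_mm = tumor_radius_mm,
                 amplitude_A0_mm = amplitude_A0_mm,
                 decay_tau_mm = decay_tau_mm,
                 heterogeneity_h = heterogeneity_h,
                 angular_harmonic = as.integer(angular_harmonic),
                 seed = as.integer(seed)),
            class = "DeformationSimConfig")
}

#' Synthetic cohort configuration
#'
#' Subgroup labels are drawn from \code{subgroup_proportions} over (WNT,
#' SHH, G3, G4); each subgroup has mean deformation effects (A0, h) in
#' \code{subgroup_effects}, jittered per subject. Event times follow a
#' proportional-hazards model \eqn{T = -\log(U) / (\lambda_0
#' e^{\beta^\top x})} on the cohort-z-scored ground-truth band features x,
#' censored uniformly on (0, censor_max_days).
#'
#' Default effect sizes follow the aggressiveness ordering of the molecular
#' subgroups (G3 > G4 > SHH > WNT in both amplitude and heterogeneity);
#' default proportions mirror a typical medulloblastoma cohort mix.
#'
#' @param n_subjects cohort size.
#' @param subgroup_proportions named numeric(4) summing to 1 over WNT, SHH,
#'   G3, G4.
#' @param subgroup_effects named list of c(A0, h) per subgroup.
#' @param survival_beta named numeric: true Cox log-hazard coefficients per
#'   SD of the named band features (e.g. \code{c(K_10 = 1)}).
#' @param baseline_rate baseline hazard (events/day).
#' @param censor_max_days upper bound of the uniform censoring time.
#' @param covariate_probs Bernoulli probabilities for the pass-through
#'   clinical covariates chang ("high"), eor ("gross_total"), metastasis.
#' @param seed integer seed.
#' @return a validated list of class \code{CohortSimConfig}.
#' @export
cohortConfig <- function(n_subjects = 88L,
                         subgroup_proportions = c(WNT = 0.10, SHH = 0.30,
                                                  G3 = 0.15, G4 = 0.45),
                         subgroup_effects = list(
                           WNT = c(A0 = 2.0, h = 0.10),
                           SHH = c(A0 = 3.0, h = 0.25),
                           G3  = c(A0 = 5.0, h = 0.60),
                           G4  = c(A0 = 4.0, h = 0.40)),
                         survival_beta = c(K_10 = 1),
                         baseline_rate = log(2) / 1500,
                         censor_max_days = 3000,
                         covariate_probs = c(chang = 0.5, eor = 0.5,
                                             metastasis = 0.5),
                         seed = 1L) {
  stopifnot(n_subjects >= 1,
            length(subgroup_proportions) == 4L,
            abs(sum(subgroup_proportions) - 1) < 1e-9,
            all(subgroup_proportions >= 0),
            baseline_rate > 0, censor_max_days > 0)
  if (!all(names(subgroup_effects) %in% names(subgroup_proportions)))
    stop("subgroup_effects must be named by subgroup")
  if (length(survival_beta) &&
      !all(names(survival_beta) %in% bandFeatureNames()))
    stop("survival_beta names must be valid band feature names (e.g. K_10)")
  structure(list(n_subjects = as.integer(n_subjects),
                 subgroup_proportions = subgroup_proportions,
                 subgroup_effects = subgroup_effects,
                 survival_beta = survival_beta,
                 baseline_rate = baseline_rate,
                 censor_max_days = censor_max_days,
                 covariate_probs = covariate_probs,
                 seed = as.integer(seed)),
            class = "CohortSimConfig")
}

# physical coordinates (mm) of every voxel; columns x, y, z
.gridCoords <- function(dim, spacing) {
  list(x = (seq_len(dim[1]) - 1) * spacing[1],
       y = (seq_len(dim[2]) - 1) * spacing[2],
       z = (seq_len(dim[3]) - 1) * spacing[3])
}

#' Generate a phantom atlas volume and brain mask
#'
#' The brain is an ellipsoid centered in the grid, filled with concentric
#' tissue shells at the configured intensity levels (equal-width shells in
#' the normalized ellipsoidal radius) plus Gaussian noise. Deterministic for
#' a fixed seed.
#'
#' @param config a [phantomConfig()].
#' @return list with \code{volume} (\linkS4class{ImageVolume}) and
#'   \code{brainMask} (logical array).
#' @examples
#' atl <- phantomAtlas(phantomConfig(grid_shape = c(24, 24, 24),
#'                                   spacing_mm = 6,
#'                                   brain_semi_axes_mm = c(60, 62, 58)))
#' sum(atl$brainMask)
#' @export
phantomAtlas <- function(config) {
  stopifnot(inherits(config, "PhantomConfig"))
  dm <- config$grid_shape
  sp <- config$spacing_mm
  ctr <- (dm - 1) * sp / 2
  g <- .gridCoords(dm, sp)
  rx <- (g$x - ctr[1]) / config$brain_semi_axes_mm[1]
  ry <- (g$y - ctr[2]) / config$brain_semi_axes_mm[2]
  rz <- (g$z - ctr[3]) / config$brain_semi_axes_mm[3]
  rho <- sqrt(outer(outer(rx^2, ry^2, "+"), rz^2, "+"))
  mask <- rho <= 1
  lev <- config$tissue_intensity_levels
  nl <- length(lev)
  shell <- pmin(floor(rho * nl) + 1L, nl)  # 1..nl by normalized radius
  data <- array(0, dm)
  data[mask] <- lev[shell[mask]]
  if (config$noise_sd > 0)
    data <- data + withSeed(config$seed,
                            array(rnorm(prod(dm), 0, config$noise_sd), dm))
  list(volume = imageVolume(data, sp), brainMask = mask)
}

#' Rasterize the analytic tumor-centered radial displacement field
#'
#' Returns the field u(x) = m(d, theta) r-hat for voxels outside the tumor
#' sphere (zero inside), with d the distance to the tumor surface, theta the
#' azimuth about the z-axis through the tumor center, and m the model of
#' [deformationConfig()].
#'
#' @param dcfg a [deformationConfig()] (center must be set).
#' @param dim,spacing grid geometry.
#' @return a \linkS4class{DisplacementField}.
#' @export
radialField <- function(dcfg, dim, spacing) {
  stopifnot(inherits(dcfg, "DeformationSimConfig"),
            !is.null(dcfg$tumor_center_mm))
  g <- .gridCoords(dim, spacing)
  ctr <- dcfg$tumor_center_mm
  dx <- array(rep(g$x - ctr[1], times = dim[2] * dim[3]), dim)
  dy <- array(rep(rep(g$y - ctr[2], each = dim[1]), times = dim[3]), dim)
  dz <- array(rep(g$z - ctr[3], each = dim[1] * dim[2]), dim)
  r <- sqrt(dx^2 + dy^2 + dz^2)
  d <- r - dcfg$tumor_radius_mm
  theta <- atan2(dy, dx)
  m <- dcfg$amplitude_A0_mm *
    (1 + dcfg$heterogeneity_h * cos(dcfg$angular_harmonic * theta)) *
    exp(-pmax(d, 0) / dcfg$decay_tau_mm)
  out <- d > 0 & r > 0
  scale <- array(0, dim)
  scale[out] <- m[out] / r[out]
  vec <- array(0, c(dim, 3))
  vec[, , , 1] <- dx * scale
  vec[, , , 2] <- dy * scale
  vec[, , , 3] <- dz * scale
  displacementField(vec, spacing)
}

#' Analytic displacement magnitude of the radial model
#'
#' @param dcfg a [deformationConfig()].
#' @param d distance(s) from the tumor surface (mm, >= 0).
#' @param theta azimuthal angle(s) (radians).
#' @return magnitudes in mm.
#' @export
radialMagnitude <- function(dcfg, d, theta) {
  dcfg$amplitude_A0_mm *
    (1 + dcfg$heterogeneity_h * cos(dcfg$angular_harmonic * theta)) *
    exp(-d / dcfg$decay_tau_mm)
}

#' Simulate one tumor-bearing subject from an atlas
#'
#' The ground-truth field u is the subject-to-atlas mapping on the subject
#' grid: the subject volume is the atlas resampled through it,
#' \code{subject(x) = atlas(x + u(x))} (trilinear interpolation), with a
#' bright tumor sphere painted in afterwards. If the phantom config requests
#' a bias field (order > 0), a random smooth multiplicative polynomial bias
#' is applied last, so preprocessing has inhomogeneity to correct.
#'
#' @param atlas \linkS4class{ImageVolume} (the undeformed phantom).
#' @param brainMask logical array aligned to the atlas.
#' @param dcfg a [deformationConfig()]; a \code{NULL} center defaults to the
#'   grid center.
#' @param pcfg the [phantomConfig()] used to build the atlas.
#' @return list with \code{volume}, \code{tumorMask} (logical array),
#'   \code{field} (ground-truth \linkS4class{DisplacementField}) and
#'   \code{dcfg} (with the resolved center).
#' @export
simulateSubject <- function(atlas, brainMask, dcfg, pcfg) {
  stopifnot(is(atlas, "ImageVolume"), inherits(dcfg, "DeformationSimConfig"))
  dm <- dim(imgData(atlas))
  sp <- spacing(atlas)
  if (is.null(dcfg$tumor_center_mm))
    dcfg$tumor_center_mm <- (dm - 1) * sp / 2
  g <- .gridCoords(dm, sp)
  ctr <- dcfg$tumor_center_mm
  dx <- array(rep(g$x - ctr[1], times = dm[2] * dm[3]), dm)
  dy <- array(rep(rep(g$y - ctr[2], each = dm[1]), times = dm[3]), dm)
  dz <- array(rep(g$z - ctr[3], each = dm[1] * dm[2]), dm)
  r <- sqrt(dx^2 + dy^2 + dz^2)
  tumorMask <- r <= dcfg$tumor_radius_mm
  if (!any(tumorMask)) stop("tumor sphere contains no voxels on this grid")
  if (any(tumorMask & !brainMask)) stop("tumor outside brain mask")
  field <- radialField(dcfg, dm, sp)
  if (dcfg$amplitude_A0_mm == 0) {
    data <- imgData(atlas)
  } else {
    data <- array(cpp_warp(as.numeric(imgData(atlas)), dm, sp,
                           as.numeric(fieldVectors(field)), 0L), dm)
  }
  data[tumorMask] <- 1.4 * max(pcfg$tissue_intensity_levels)
  if (pcfg$bias_field_order > 0) {
    b <- .randomBiasField(dm, sp, pcfg$bias_field_order, amplitude = 0.2,
                          seed = streamSeed(dcfg$seed, "bias"))
    data <- data * b
  }
  list(volume = imageVolume(data, sp), tumorMask = tumorMask, field = field,
       dcfg = dcfg)
}

# smooth multiplicative polynomial bias field with mean ~1
.randomBiasField <- function(dim, spacing, order, amplitude, seed) {
  g <- .gridCoords(dim, spacing)
  nx <- 2 * (g$x - mean(g$x)) / diff(range(g$x))
  ny <- 2 * (g$y - mean(g$y)) / diff(range(g$y))
  nz <- 2 * (g$z - mean(g$z)) / diff(range(g$z))
  co <- withSeed(seed, rnorm((order + 1)^3))
  b <- array(0, dim)
  idx <- 1
  for (k in 0:order) for (j in 0:order) for (i in 0:order) {
    if (i + j + k <= order && i + j + k > 0) {
      b <- b + co[idx] * outer(outer(nx^i, ny^j, "*"), nz^k, "*")
    }
    idx <- idx + 1
  }
  if (max(abs(b)) > 0) b <- b / max(abs(b))
  1 + amplitude * b
}

#' Ground-truth band features from the analytic field
#'
#' Computes the 60 band statistics of the analytic displacement magnitude
#' using the surface distance d = |x - c| - R_eff, bands clipped to the
#' brain mask; no registration or distance transform involved. R_eff is the
#' effective radius of the tumor sphere as rasterized on this grid (the
#' largest voxel-center radius inside the nominal R), so the truth
#' describes the phantom the pipeline actually sees rather than the ideal
#' continuous sphere. This is the oracle the pipeline is validated against
#' and the feature set driving the simulated survival model.
#'
#' @param dcfg a [deformationConfig()] with resolved center.
#' @param brainMask logical array.
#' @param dim,spacing grid geometry.
#' @return named numeric(60) in canonical order (see [bandFeatureNames()]).
#' @export
trueBandFeatures <- function(dcfg, brainMask, dim, spacing) {
  g <- .gridCoords(dim, spacing)
  ctr <- dcfg$tumor_center_mm
  dx <- array(rep(g$x - ctr[1], times = dim[2] * dim[3]), dim)
  dy <- array(rep(rep(g$y - ctr[2], each = dim[1]), times = dim[3]), dim)
  dz <- array(rep(g$z - ctr[3], each = dim[1] * dim[2]), dim)
  r <- sqrt(dx^2 + dy^2 + dz^2)
  inside <- r <= dcfg$tumor_radius_mm
  rEff <- if (any(inside)) max(r[inside]) else dcfg$tumor_radius_mm
  d <- r - rEff
  theta <- atan2(dy, dx)
  mag <- radialMagnitude(dcfg, pmax(d, 0), theta)
  .bandFeaturesFromMaps(mag, d, brainMask & d > 0)
}

#' Generate a synthetic cohort with clinical table and survival outcomes
#'
#' Draws subgroup labels, per-subject deformation parameters (subgroup mean
#' effects with per-subject jitter on amplitude, heterogeneity, tumor radius
#' and center), ground-truth band features, and survival from the
#' proportional-hazards model of [cohortConfig()]. Clinical covariates not
#' tied to the deformation model (Chang class, EOR, metastasis) are
#' Bernoulli draws. With \code{materialize = "volumes"} the deformed subject
#' volumes and masks are also returned (slower); the default returns the
#' per-subject configs and ground-truth features, which is what the
#' statistics and survival stages consume.
#'
#' @param ccfg a [cohortConfig()].
#' @param pcfg a [phantomConfig()].
#' @param materialize \code{"features"} (default), \code{"volumes"}, or
#'   \code{"clinical"} (skip feature extraction when the survival model has
#'   no feature effects; only valid with an empty \code{survival_beta}).
#' @return list with \code{clinical} (data.frame: subject_id, age_years,
#'   subgroup, chang, eor, metastasis, os_days, event), \code{features}
#'   (data.frame of ground-truth band features, one row per subject),
#'   \code{subjects} (per-subject deformation configs, plus volumes if
#'   materialized), \code{atlas} and \code{brainMask}.
#' @export
simulateCohort <- function(ccfg, pcfg,
                           materialize = c("features", "volumes",
                                           "clinical")) {
  stopifnot(inherits(ccfg, "CohortSimConfig"), inherits(pcfg, "PhantomConfig"))
  materialize <- match.arg(materialize)
  n <- ccfg$n_subjects
  atl <- phantomAtlas(pcfg)
  dm <- pcfg$grid_shape
  sp <- pcfg$spacing_mm
  ctr <- (dm - 1) * sp / 2

  groups <- names(ccfg$subgroup_proportions)
  subgroup <- withSeed(streamSeed(ccfg$seed, "subgroup"),
                       sample(groups, n, replace = TRUE,
                              prob = ccfg$subgroup_proportions))
  missingGroups <- setdiff(groups, unique(subgroup))
  if (length(missingGroups))
    warning("no subjects sampled for subgroup(s): ",
            paste(missingGroups, collapse = ", "))

  pars <- withSeed(streamSeed(ccfg$seed, "effects"), {
    lapply(seq_len(n), function(i) {
      eff <- ccfg$subgroup_effects[[subgroup[i]]]
      A0 <- max(0.3, rnorm(1, eff[["A0"]], 0.15 * eff[["A0"]]))
      h <- min(1, max(0, rnorm(1, eff[["h"]], 0.08)))
      rad <- runif(1, 0.8, 1.2) * 10
      jit <- runif(3, -3, 3)
      deformationConfig(tumor_center_mm = ctr + jit, tumor_radius_mm = rad,
                        amplitude_A0_mm = A0, decay_tau_mm = 10,
                        heterogeneity_h = h, angular_harmonic = 2L,
                        seed = streamSeed(ccfg$seed, paste0("subj", i)))
    })
  })

  if (materialize == "clinical" && length(ccfg$survival_beta))
    stop("materialize = \"clinical\" requires an empty survival_beta")
  needFeatures <- length(ccfg$survival_beta) > 0 || materialize == "features"
  features <- NULL
  if (needFeatures) {
    fm <- t(vapply(pars, trueBandFeatures, numeric(60),
                   brainMask = atl$brainMask, dim = dm, spacing = sp))
    features <- as.data.frame(fm)
    features <- cbind(subject_id = sprintf("S%03d", seq_len(n)), features,
                      stringsAsFactors = FALSE)
  }

  lp <- rep(0, n)
  if (length(ccfg$survival_beta)) {
    for (nm in names(ccfg$survival_beta)) {
      v <- features[[nm]]
      s <- sd(v)
      z <- if (is.finite(s) && s > 0) (v - mean(v)) / s else rep(0, n)
      lp <- lp + ccfg$survival_beta[[nm]] * z
    }
  }
  surv <- withSeed(streamSeed(ccfg$seed, "survival"), {
    u <- runif(n)
    tEvent <- -log(u) / (ccfg$baseline_rate * exp(lp))
    cens <- if (is.finite(ccfg$censor_max_days))
      runif(n, 0, ccfg$censor_max_days) else rep(Inf, n)
    list(os = pmin(tEvent, cens), event = as.integer(tEvent <= cens))
  })

  covs <- withSeed(streamSeed(ccfg$seed, "covariates"), {
    p <- ccfg$covariate_probs
    list(chang = ifelse(rbinom(n, 1, p[["chang"]]) == 1,
                        "high_risk", "standard_risk"),
         eor = ifelse(rbinom(n, 1, p[["eor"]]) == 1,
                      "gross_total", "subtotal"),
         metastasis = rbinom(n, 1, p[["metastasis"]]))
  })
  age <- withSeed(streamSeed(ccfg$seed, "age"), runif(n, 0.3, 16))

  clinical <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                         age_years = age, subgroup = subgroup,
                         chang = covs$chang, eor = covs$eor,
                         metastasis = covs$metastasis,
                         os_days = surv$os, event = surv$event,
                         stringsAsFactors = FALSE)

  subjects <- pars
  if (materialize == "volumes") {
    subjects <- lapply(pars, function(d)
      simulateSubject(atl$volume, atl$brainMask, d, pcfg))
  }
  list(clinical = clinical, features = features, subjects = subjects,
       atlas = atl$volume, brainMask = atl$brainMask)
}
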