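# Synthetic-data generator: phantom atlases, deformation fields with known
# closed forms, and survival with known hazard structure.

test_that("noise-free atlas is piecewise-constant and deterministic", {
  cfg <- phantomConfig(grid_shape = c(20, 20, 20), spacing_mm = 5,
                       brain_semi_axes_mm = c(40, 40, 40),
                       tissue_intensity_levels = 7, noise_sd = 0, seed = 4)
  a1 <- phantomAtlas(cfg)
  expect_true(all(imgData(a1$volume)[a1$brainMask] == 7))
  expect_true(all(imgData(a1$volume)[!a1$brainMask] == 0))
  a2 <- phantomAtlas(cfg)
  expect_identical(imgData(a1$volume), imgData(a2$volume))
  cfgN <- phantomConfig(grid_shape = c(20, 20, 20), spacing_mm = 5,
                        brain_semi_axes_mm = c(40, 40, 40), noise_sd = 3,
                        seed = 9)
  expect_identical(imgData(phantomAtlas(cfgN)$volume),
                   imgData(phantomAtlas(cfgN)$volume))
})

test_that("ellipsoid mask voxel count matches the analytic volume", {
  cfg <- phantomConfig(grid_shape = c(48, 48, 48), spacing_mm = 1,
                       brain_semi_axes_mm = c(20, 20, 20), noise_sd = 0)
  a <- phantomAtlas(cfg)
  analytic <- 4 / 3 * pi * 20^3
  expect_lt(abs(sum(a$brainMask) - analytic) / analytic, 0.02)
})

test_that("ellipsoid that does not fit the grid is rejected", {
  expect_error(phantomConfig(grid_shape = c(16, 16, 16), spacing_mm = 1,
                             brain_semi_axes_mm = c(20, 20, 20)),
               "fit")
})

test_that("zero-amplitude deformation leaves the atlas untouched", {
  atl <- smallAtlas()
  s <- simulateSubject(atl$volume, atl$brainMask,
                       deformationConfig(amplitude_A0_mm = 0, seed = 1),
                       smallPhantomConfig())
  expect_true(all(fieldVectors(s$field) == 0))
  outside <- !s$tumorMask
  expect_identical(imgData(s$volume)[outside], imgData(atl$volume)[outside])
})

test_that("field magnitude matches the closed form on the +x axis", {
  # h = 0, voxel at distance tau from the surface: |u| = A0 * exp(-1)
  cfg <- phantomConfig(grid_shape = c(41, 41, 41), spacing_mm = 2,
                       brain_semi_axes_mm = c(39, 39, 39), noise_sd = 0)
  ctr <- (c(41, 41, 41) - 1) * 2 / 2
  dcfg <- deformationConfig(tumor_center_mm = ctr, tumor_radius_mm = 10,
                            amplitude_A0_mm = 4, decay_tau_mm = 10,
                            heterogeneity_h = 0)
  fld <- radialField(dcfg, c(41L, 41L, 41L), c(2, 2, 2))
  # voxel on +x axis at 20 mm from center = 10 mm (= tau) from surface
  vox <- c(ctr[1] + 20, ctr[2], ctr[3]) / 2 + 1
  u <- fieldVectors(fld)[vox[1], vox[2], vox[3], ]
  expect_equal(sqrt(sum(u^2)), 4 * exp(-1), tolerance = 1e-10)
  expect_equal(u[2], 0)
  expect_equal(u[3], 0)
})

test_that("magnitude decays monotonically along rays when h = 0", {
  dcfg <- deformationConfig(tumor_center_mm = c(0, 0, 0),
                            heterogeneity_h = 0)
  d <- seq(0, 50, by = 0.5)
  for (th in c(0, 1, 2.5)) {
    m <- radialMagnitude(dcfg, d, th)
    expect_true(all(diff(m) <= 0))
  }
})

test_that("band skewness of the heterogeneous field matches quadrature", {
  # h = 0.5, harmonic 2; shell 0-15 mm fully inside the brain
  cfg <- phantomConfig(grid_shape = c(64, 64, 64), spacing_mm = 2.5,
                       brain_semi_axes_mm = c(70, 75, 65), noise_sd = 0)
  ctr <- (c(64, 64, 64) - 1) * 2.5 / 2
  dcfg <- deformationConfig(tumor_center_mm = ctr, tumor_radius_mm = 10,
                            amplitude_A0_mm = 4, decay_tau_mm = 10,
                            heterogeneity_h = 0.5, angular_harmonic = 2)
  atl <- phantomAtlas(cfg)
  # rasterized field magnitudes over the analytic 0 < d <= 15 shell
  fld <- radialField(dcfg, cfg$grid_shape, cfg$spacing_mm)
  mag <- imgData(deformationMagnitude(fld))
  g <- list(x = (0:63) * 2.5, y = (0:63) * 2.5, z = (0:63) * 2.5)
  dx <- array(rep(g$x - ctr[1], times = 64 * 64), c(64, 64, 64))
  dy <- array(rep(rep(g$y - ctr[2], each = 64), times = 64), c(64, 64, 64))
  dz <- array(rep(g$z - ctr[3], each = 64 * 64), c(64, 64, 64))
  d <- sqrt(dx^2 + dy^2 + dz^2) - 10
  shell <- d > 0 & d <= 15
  skRaster <- bandStatistics(mag * shell, shell)[["SK"]]

  # dense numerical quadrature of m(d, theta) over the spherical shell,
  # volume element r^2 sin(phi) dr dphi dtheta (m independent of phi)
  R <- 10; tau <- 10; A0 <- 4; h <- 0.5; k <- 2
  rr <- seq(R + 0.005, R + 15 - 0.005, length.out = 600)
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  w <- rr^2                      # sin(phi) integrates out
  moment <- function(p) {
    mth <- outer(rr, th, function(r, t)
      (A0 * (1 + h * cos(k * t)) * exp(-(r - R) / tau))^p)
    sum(mth * w) / (length(th) * sum(w))
  }
  m1 <- moment(1)
  m2 <- moment(2) - m1^2
  m3 <- moment(3) - 3 * m1 * moment(2) + 2 * m1^3
  skQuad <- m3 / m2^1.5
  expect_lt(abs(skRaster - skQuad) / abs(skQuad), 0.05)
})

test_that("analytic ground-truth features match the extraction pipeline", {
  # rasterized-field features vs analytic-distance features at the
  # reference feature-extraction resolution (2.5 mm): 5% for the
  # magnitude-scale statistics, wider for near-zero higher moments
  cfg <- phantomConfig(grid_shape = c(48L, 48L, 48L), spacing_mm = 2.5,
                       brain_semi_axes_mm = c(55, 58, 52), seed = 2)
  atl <- phantomAtlas(cfg)
  s <- simulateSubject(atl$volume, atl$brainMask,
                       deformationConfig(tumor_radius_mm = 8,
                                         amplitude_A0_mm = 4,
                                         heterogeneity_h = 0.3, seed = 11),
                       cfg)
  mag <- deformationMagnitude(s$field, atl$brainMask)
  f <- extractFeatures(mag, s$tumorMask, atl$brainMask)
  tf <- trueBandFeatures(s$dcfg, atl$brainMask, cfg$grid_shape,
                         cfg$spacing_mm)
  dmap <- distanceMap(s$tumorMask, atl$brainMask, cfg$spacing_mm)
  counts <- vapply(bandMasks(makeBands(dmap)), sum, numeric(1))
  big <- counts >= 500
  # error model: the mask-based distance to voxel centers exceeds the
  # surface distance by up to one voxel, so magnitudes (~ e^{-d/tau}) can
  # differ by the factor e^{spacing/(2 tau)} on average; higher moments
  # amplify membership swaps, bounded by max(10%, 0.3 absolute)
  tolScale <- exp(mean(cfg$spacing_mm) / (2 * s$dcfg$decay_tau_mm)) - 1
  for (stat in c("M", "MD", "STD")) {
    nm <- paste0(stat, "_", 5 * which(big))
    expect_lt(max(abs(f[nm] - tf[nm]) / pmax(abs(tf[nm]), 1e-9)), tolScale)
  }
  for (stat in c("SK", "K")) {
    nm <- paste0(stat, "_", 5 * which(big))
    err <- abs(f[nm] - tf[nm])
    expect_true(all(err <= pmax(0.10 * abs(tf[nm]), 0.3)))
  }
})

test_that("null survival model yields exponential event times", {
  ccfg <- cohortConfig(n_subjects = 500, survival_beta = setNames(
    numeric(0), character(0)), baseline_rate = 0.001,
    censor_max_days = Inf, seed = 5)
  ch <- simulateCohort(ccfg, smallPhantomConfig(),
                       materialize = "clinical")$clinical
  expect_true(all(ch$event == 1))  # no censoring
  ks <- suppressWarnings(stats::ks.test(ch$os_days, "pexp", 0.001))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort generation is deterministic and well-formed", {
  ccfg <- cohortConfig(n_subjects = 30, seed = 42)
  pcfg <- smallPhantomConfig()
  c1 <- simulateCohort(ccfg, pcfg)
  c2 <- simulateCohort(ccfg, pcfg)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$features, c2$features)
  expect_true(all(c1$clinical$os_days > 0))
  expect_true(all(c1$clinical$event %in% 0:1))
  expect_equal(ncol(c1$features), 61)  # subject_id + 60
  expect_identical(names(c1$features)[-1], bandFeatureNames())
})

test_that("simulated hazard ratios are recovered empirically", {
  # two groups differing by log(2) in the linear predictor -> the pooled
  # empirical HR over the fixed seed set recovers 2 +/- 0.3
  hrs <- vapply(1:5, function(s) {
    lp <- rep(c(0, log(2)), each = 200)
    oc <- simSurvival(400, lp, seed = 100 + s)
    fit <- survival::coxph(survival::Surv(os_days, event) ~ grp,
                           data = cbind(oc, grp = rep(0:1, each = 200)))
    unname(coef(fit))
  }, numeric(1))
  expect_lt(abs(exp(mean(hrs)) - 2), 0.3)
})

test_that("tumor placed outside the brain is rejected", {
  atl <- smallAtlas()
  cfg <- smallPhantomConfig()
  dcfg <- deformationConfig(tumor_center_mm = c(0, 0, 0),
                            tumor_radius_mm = 8)
  expect_error(simulateSubject(atl$volume, atl$brainMask, dcfg, cfg),
               "outside brain")
})
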