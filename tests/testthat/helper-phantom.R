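# Shared phantom fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# small phantom: 40^3 at 3 mm (120 mm FOV), brain semi-axes fit bands to
# ~50 mm; fast enough for per-test reuse
smallPhantomConfig <- function(seed = 1L) {
  phantomConfig(grid_shape = c(40L, 40L, 40L), spacing_mm = 3,
                brain_semi_axes_mm = c(55, 58, 52), noise_sd = 2,
                seed = seed)
}

smallAtlas <- function() {
  if (is.null(.fixtures$smallAtlas))
    .fixtures$smallAtlas <- phantomAtlas(smallPhantomConfig())
  .fixtures$smallAtlas
}

smallSubject <- function() {
  if (is.null(.fixtures$smallSubject)) {
    atl <- smallAtlas()
    .fixtures$smallSubject <- simulateSubject(
      atl$volume, atl$brainMask,
      deformationConfig(tumor_radius_mm = 8, amplitude_A0_mm = 4,
                        decay_tau_mm = 10, heterogeneity_h = 0.3, seed = 11),
      smallPhantomConfig())
  }
  .fixtures$smallSubject
}

# brute-force anisotropic distance to the nearest TRUE voxel (O(n^2) oracle)
bruteDistance <- function(mask, spacing) {
  dm <- dim(mask)
  tum <- which(mask, arr.ind = TRUE)
  tp <- sweep(tum - 1, 2, spacing, "*")
  out <- array(NA_real_, dm)
  all <- arrayInd(seq_along(mask), dm)
  ap <- sweep(all - 1, 2, spacing, "*")
  for (i in seq_len(nrow(ap))) {
    d2 <- (tp[, 1] - ap[i, 1])^2 + (tp[, 2] - ap[i, 2])^2 +
      (tp[, 3] - ap[i, 3])^2
    out[i] <- sqrt(min(d2))
  }
  out
}

# synthetic survival data with a known linear predictor
simSurvival <- function(n, lp, rate = 0.001, cmax = 3000, seed = 1L) {
  withSeed(seed, {
    tEvent <- -log(runif(n)) / (rate * exp(lp))
    cens <- runif(n, 0, cmax)
    data.frame(os_days = pmin(tEvent, cens),
               event = as.integer(tEvent <= cens))
  })
}
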