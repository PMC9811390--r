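# Correlation pruning, scaling, subgroup ANOVA, post-hoc, semantic tests,
# hierarchical clustering.

test_that("pruning drops duplicated and anti-correlated columns", {
  df <- data.frame(subject_id = sprintf("S%02d", 1:20),
                   a = 1:20, b = 1:20, c = -(1:20) + 0.0,
                   d = withSeed(1, rnorm(20)))
  out <- pruneCorrelated(df, 0.95)
  kept <- names(out)[vapply(out, is.numeric, logical(1))]
  expect_identical(kept, c("a", "d"))   # b duplicates a; c = -a
  expect_setequal(attr(out, "dropped"), c("b", "c"))
  # constant columns are excluded with a warning
  df$e <- 5
  expect_warning(out2 <- pruneCorrelated(df, 0.95), "constant")
  expect_false("e" %in% names(out2))
})

test_that("independent columns survive pruning", {
  n <- 200
  X <- withSeed(7, as.data.frame(matrix(rnorm(n * 10), n)))
  names(X) <- paste0("f", 1:10)
  out <- pruneCorrelated(X, 0.95)
  expect_equal(sum(vapply(out, is.numeric, logical(1))), 10)
})

test_that("scaling z-scores with population SD and stores the transform", {
  df <- data.frame(x = c(1, 2, 3))
  sc <- scaleFeatures(df)
  expect_equal(sc$x, c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-9)
  expect_equal(sc$x, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  big <- data.frame(x = withSeed(3, rnorm(100, 50, 9)))
  s2 <- scaleFeatures(big)
  expect_lt(abs(mean(s2$x)), 1e-9)
  expect_lt(abs(sqrt(mean((s2$x - mean(s2$x))^2)) - 1), 1e-9)
  # stored transform is reused, not refit
  tr <- attr(s2, "transform")
  s3 <- scaleFeatures(data.frame(x = big$x + 10), transform = tr)
  expect_equal(mean(s3$x), 10 / tr$scale[["x"]], tolerance = 1e-9)
  expect_error(scaleFeatures(data.frame(x = rep(4, 5))), "zero-SD")
})

test_that("ANOVA reduces to the algebraic sum-of-squares formula", {
  f <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("WNT", "SHH"), each = 3)
  a <- anovaSubgroups(f, g)
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  # hand F on unbalanced groups
  f2 <- c(1, 2, 3, 4, 2, 4, 6)
  g2 <- c(rep("G3", 4), rep("G4", 3))
  gm <- mean(f2)
  ssb <- 4 * (mean(f2[1:4]) - gm)^2 + 3 * (mean(f2[5:7]) - gm)^2
  ssw <- sum((f2[1:4] - mean(f2[1:4]))^2) + sum((f2[5:7] - mean(f2[5:7]))^2)
  Fhand <- (ssb / 1) / (ssw / 5)
  a2 <- anovaSubgroups(f2, g2)
  expect_equal(a2$F, Fhand, tolerance = 1e-12)
  # perfect separation: p below any practical floor
  a3 <- anovaSubgroups(c(0, 0, 0, 1, 1, 1) + 1e-9 * c(1, -1, 0, 1, -1, 0),
                       rep(c("WNT", "G4"), each = 3))
  expect_lt(a3$p, 1e-12)
})

test_that("groups with fewer than two members are excluded with warning", {
  f <- c(rnorm(5), rnorm(5), 3)
  g <- c(rep("G3", 5), rep("G4", 5), "WNT")
  expect_warning(a <- anovaSubgroups(f, g), "WNT")
  expect_equal(sum(a$df) + 1, 10)  # WNT row dropped
})

test_that("ANOVA detects a 1-SD shift with at least 80% power", {
  reps <- 500
  hits <- 0
  for (r in seq_len(reps)) {
    dat <- withSeed(1000 + r, {
      y <- rnorm(80)
      y[61:80] <- y[61:80] + 1
      y
    })
    g <- rep(c("WNT", "SHH", "G4", "G3"), each = 20)
    if (anovaSubgroups(dat, g)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("Tukey post-hoc flags only the shifted group", {
  reps <- 200
  okRep <- 0
  for (r in seq_len(reps)) {
    dat <- withSeed(2000 + r, {
      y <- rnorm(80)
      y[61:80] <- y[61:80] + 2    # G4 shifted by 2 SD
      y
    })
    g <- rep(c("WNT", "SHH", "G3", "G4"), each = 20)
    ph <- posthocPairwise(dat, g)
    hit <- grepl("G4", ph$comparison)
    if (all(ph$p_adj[hit] < 0.05)) okRep <- okRep + 1
  }
  expect_gte(okRep / reps, 0.8)
  # identical groups: all adjusted p ~ 1
  ph0 <- posthocPairwise(rep(c(1, 2, 3), 4),
                         rep(c("WNT", "SHH", "G3", "G4"), each = 3))
  expect_true(all(ph0$p_adj > 0.999))
})

test_that("adjusted post-hoc p-values dominate unadjusted pairwise t", {
  dat <- withSeed(5, rnorm(40, rep(c(0, 0.7, 0.2, 1), each = 10)))
  g <- rep(c("WNT", "SHH", "G3", "G4"), each = 10)
  tk <- posthocPairwise(dat, g)
  for (i in seq_len(nrow(tk))) {
    pair <- strsplit(tk$comparison[i], "-")[[1]]
    sel <- g %in% pair
    praw <- t.test(dat[sel] ~ g[sel], var.equal = TRUE)$p.value
    expect_gte(tk$p_adj[i] + 1e-9, praw)
  }
})

test_that("semantic one-vs-all tests match the hypergeometric oracle", {
  # 2x2 table [[10, 0], [0, 10]]: Fisher p = 2 / choose(20, 10)
  f <- rep(c("Present", "Absent"), each = 10)
  g <- rep(c("G3", "G4"), each = 10)
  res <- semanticAssociation(f, g)
  pOracle <- 2 / choose(20, 10)
  expect_equal(res$p[res$group == "G3"], pOracle, tolerance = 1e-12)
  expect_equal(pOracle, 1.082509e-05, tolerance = 1e-6)
  expect_true(all(res$test == "fisher"))
  # three-level feature goes through chi-square
  f3 <- rep(c("Low", "Medium", "High"), length.out = 30)
  g3 <- rep(c("WNT", "SHH", "G3"), each = 10)
  res3 <- semanticAssociation(f3, g3)
  expect_true(all(res3$test == "chisq"))
  # degenerate single-level feature is skipped with status
  rs <- semanticAssociation(rep("Present", 20), g)
  expect_true(all(grepl("skipped", rs$status)))
})

test_that("semantic tests hold their type-I error under the null", {
  reps <- 500
  rej <- 0
  tot <- 0
  for (r in seq_len(reps)) {
    dat <- withSeed(3000 + r, {
      list(f = sample(c("Present", "Absent"), 100, replace = TRUE),
           g = sample(c("WNT", "SHH", "G3", "G4", "G3/G4"), 100,
                      replace = TRUE))
    })
    res <- semanticAssociation(dat$f, dat$g)
    rej <- rej + sum(res$p < 0.05, na.rm = TRUE)
    tot <- tot + sum(!is.na(res$p))
  }
  expect_lt(abs(rej / tot - 0.05), 0.02)
})

test_that("clustering separates well-separated blobs and is stable", {
  n <- 40
  X <- withSeed(11, rbind(matrix(rnorm(n * 3), n),
                          matrix(rnorm(n * 3, mean = 5), n)))
  cl <- hierarchicalCluster(as.data.frame(X))
  lab <- cl$clusters
  agree <- max(mean(lab == rep(1:2, each = n)),
               mean(lab == rep(2:1, each = n)))
  expect_gte(agree, 0.95)
  # duplicated subjects merge at height zero
  Y <- as.data.frame(rbind(X[1, ], X[1, ], X[5, ], X[9, ]))
  cl2 <- hierarchicalCluster(Y)
  expect_equal(min(cl2$tree$height), 0)
  # permutation changes leaf order only, not merge heights
  perm <- withSeed(12, sample(nrow(X)))
  cl3 <- hierarchicalCluster(as.data.frame(X[perm, ]))
  expect_equal(sort(cl3$tree$height), sort(cl$tree$height),
               tolerance = 1e-9)
})

test_that("G3/G4 and missing labels stay out of the four-group ANOVA", {
  f <- c(rnorm(20), 100, 200, NA)
  g <- c(rep(c("WNT", "SHH", "G3", "G4"), each = 5), "G3/G4", "G3/G4", "G4")
  a <- anovaSubgroups(f, g)
  expect_equal(sum(a$df) + 1, 20)  # transitional + NA rows excluded
})

test_that("the full subgroup analysis chain flags true group differences", {
  n <- 80
  g <- rep(c("WNT", "SHH", "G3", "G4"), each = 20)
  X <- withSeed(31, {
    X <- as.data.frame(matrix(rnorm(n * 8), n))
    names(X) <- paste0("f", 1:8)
    X$f2 <- X$f2 + 2 * (g == "G3")   # G3 shifted on f2
    X$f8 <- X$f1                     # duplicate, should be pruned
    X
  })
  res <- suppressWarnings(subgroupAnalysis(X, g, alpha = 0.05))
  expect_true("f8" %in% res$pruned)
  expect_true(res$results$significant[res$results$feature == "f2"])
  ph <- res$posthoc[["f2"]]
  expect_true(all(ph$p_adj[grepl("G3", ph$comparison)] < 0.05))
  # BH adjustment is available and monotone
  resBH <- suppressWarnings(subgroupAnalysis(X, g, adjust = TRUE))
  expect_true(all(resBH$results$p_adj >= resBH$results$p - 1e-12))
})
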