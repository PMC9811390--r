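# Cohort split, LASSO-Cox, RRS, cutpoint search, log-rank/KM, Cox fits,
# McNemar and chi-square agreement tests.

test_that("stratified split hits the 70/30 arithmetic", {
  cl <- data.frame(subject_id = sprintf("S%03d", 1:100),
                   subgroup = rep(c("WNT", "SHH", "G3", "G4"), each = 25))
  sp <- splitCohort(cl, 0.7, seed = 5)
  expect_length(sp$train, 70)
  expect_length(sp$test, 30)
  perStr <- table(cl$subgroup[cl$subject_id %in% sp$train])
  expect_true(all(perStr %in% 17:18))
  sp2 <- splitCohort(cl, 0.7, seed = 5)
  expect_identical(sp, sp2)
  expect_warning(sp3 <- splitCohort(cl, 1.0, seed = 1), "empty test")
  expect_length(sp3$train, 100)
})

test_that("singleton strata are forced into training", {
  cl <- data.frame(subject_id = sprintf("S%02d", 1:11),
                   subgroup = c(rep("G4", 10), "WNT"))
  expect_warning(sp <- splitCohort(cl, 0.7, seed = 2), "singleton")
  expect_true("S11" %in% sp$train)
})

test_that("an infinite LASSO penalty zeroes every coefficient", {
  n <- 60
  X <- withSeed(4, as.data.frame(matrix(rnorm(n * 10), n)))
  names(X) <- paste0("f", 1:10)
  oc <- simSurvival(n, rowSums(X[1:2]), seed = 8)
  m <- fitLassoCox(X, oc, lambda = 1e6)
  expect_length(m@features, 0)
  expect_true(attr(m, "empty"))
  expect_true(all(computeRRS(X, m) == 0))
})

test_that("LASSO-Cox recovers an informative feature and rejects noise", {
  reps <- 20
  hitSignal <- 0
  hitNull <- 0
  for (r in seq_len(reps)) {
    X <- withSeed(4000 + r,
                  as.data.frame(matrix(rnorm(200 * 15), 200)))
    names(X) <- paste0("f", 1:15)
    ocS <- simSurvival(200, X$f3, seed = 5000 + r)   # beta = 1 per SD
    mS <- fitLassoCox(X, ocS, folds = 3, seed = r)
    if ("f3" %in% mS@features) hitSignal <- hitSignal + 1
    ocN <- simSurvival(200, rep(0, 200), seed = 6000 + r)
    mN <- fitLassoCox(X, ocN, folds = 3, seed = r)
    if (length(mN@features) > 3) hitNull <- hitNull + 1
  }
  expect_gte(hitSignal / reps, 0.8)
  expect_lte(hitNull / reps, 0.5)   # near-empty selection under the null
})

test_that("the RRS is the stored-normalization weighted sum", {
  m <- new("RiskModel", features = c("K_10", "MD_25"),
           coefficients = c(0.5, -0.2), center = c(0, 0), scale = c(1, 1),
           cutpoint = NA_real_, lambda = NA_real_,
           trainingIds = character(0))
  df <- data.frame(K_10 = 2, MD_25 = 1, SK_15 = 99)
  expect_equal(computeRRS(df, m), 0.8)
  # unselected features never enter the score
  df2 <- df
  df2$SK_15 <- -99
  expect_identical(computeRRS(df, m), computeRRS(df2, m))
  expect_error(computeRRS(data.frame(K_10 = 1), m), "missing feature")
})

test_that("cutpoint search lands between separated risk clusters", {
  sc <- c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1))
  oc <- data.frame(os_days = c(runif(20, 2000, 3000), runif(20, 50, 300)),
                   event = c(rep(0, 20), rep(1, 20)))
  cut <- findCutpoint(sc, oc)
  expect_gt(cut, 1)
  expect_lt(cut, 9)
  # monotone-transform invariance of the induced groups
  cut2 <- findCutpoint(exp(sc / 5), oc)
  expect_identical(sc > cut, exp(sc / 5) > cut2)
  # identical outcomes: every cut ties, lowest admissible returned
  ocSame <- data.frame(os_days = rep(100, 10), event = rep(1, 10))
  scU <- 1:10
  cutT <- findCutpoint(scU, ocSame, min_group_frac = 0.2)
  expect_equal(as.numeric(cutT), 2.5)
  # no admissible cut
  expect_error(findCutpoint(1:9, ocSame[1:9, ], min_group_frac = 0.5),
               "admissible")
})

test_that("log-rank matches the hand-computed O/E/V oracle", {
  # group A events at t = 1, 2; group B at t = 3, 4; no censoring:
  # E_A = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36,
  # chi-square = (2 - 5/6)^2 / (17/36) = 49/17
  oc <- data.frame(os_days = 1:4, event = 1)
  lr <- kmLogrank(c("A", "A", "B", "B"), oc)
  expect_equal(lr$chisq, 49 / 17, tolerance = 1e-12)
  expect_equal(lr$p, pchisq(49 / 17, 1, lower.tail = FALSE))
  # symmetric groups: statistic 0, p = 1
  oc2 <- data.frame(os_days = rep(c(1, 2, 3), 2), event = 1)
  lr2 <- kmLogrank(rep(c("A", "B"), 3), oc2)
  expect_equal(lr2$chisq, 0, tolerance = 1e-12)
  expect_equal(lr2$p, 1)
  # KM equals the empirical survival function without censoring
  oc3 <- data.frame(os_days = c(1, 2, 3, 4, 10, 12, 15, 20), event = 1)
  lr3 <- suppressWarnings(kmLogrank(rep(c("A", "B"), each = 4), oc3))
  sA <- summary(lr3$km)$surv[1:4]
  expect_equal(sA, c(3, 2, 1, 0) / 4)
})

test_that("Cox fits report per-stratum hazard ratios and concordance", {
  n <- 300
  grp <- rep(c("low", "high"), each = n / 2)
  oc <- simSurvival(n, ifelse(grp == "high", log(2), 0), seed = 77)
  fit <- coxFit(data.frame(risk = grp), oc, baselines = list(risk = "low"))
  expect_equal(fit$hr$HR[fit$hr$stratum == "low"], 1)
  expect_gt(fit$hr$HR[fit$hr$stratum == "high"], 1.4)
  expect_lt(fit$hr$HR[fit$hr$stratum == "high"], 2.9)
  expect_true(fit$c_index > 0.5 && fit$c_index < 1)
  expect_gt(fit$c_index_se, 0)
  # null covariate: C-index ~ 0.5
  nullCov <- data.frame(x = withSeed(3, rnorm(n)))
  fit0 <- coxFit(nullCov, oc)
  expect_lt(abs(fit0$c_index - 0.5), 0.05)
  expect_lt(abs(fit0$hr$HR[1] - 1), 0.25)
  # perfect concordance: score = -os_days, no censoring
  ocAll <- data.frame(os_days = sort(withSeed(4, rexp(50, 0.001))) + 1,
                      event = 1)
  fitP <- coxFit(data.frame(score = -ocAll$os_days), ocAll)
  expect_equal(unname(fitP$c_index), 1)
})

test_that("simulated binary covariate recovers its true hazard ratio", {
  reps <- 25
  ok <- 0
  for (r in seq_len(reps)) {
    grp <- rep(0:1, each = 200)
    oc <- simSurvival(400, grp * log(2), seed = 7000 + r)
    fit <- coxFit(data.frame(g = factor(grp)), oc)
    hr <- fit$hr$HR[fit$hr$stratum == "1"]
    if (hr >= 1.6 && hr <= 2.5) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.9)
})

test_that("McNemar reduces to its closed form", {
  expect_equal(mcnemarTest(matrix(c(20, 5, 5, 30), 2))$statistic, 0)
  expect_equal(mcnemarTest(matrix(c(20, 5, 5, 30), 2))$p, 1)
  r <- mcnemarTest(matrix(c(20, 0, 10, 30), 2))  # b = 10, c = 0
  expect_equal(r$statistic, 10)
  expect_equal(r$p, pchisq(10, 1, lower.tail = FALSE))
  expect_equal(r$p, 0.001565402, tolerance = 1e-6)
  expect_equal(mcnemarTest(matrix(c(5, 0, 0, 5), 2))$p, 1)  # b = c = 0
  expect_error(mcnemarTest(matrix(c(-1, 0, 0, 1), 2)), "negative")
})

test_that("Pearson chi-square matches hand computation and scales", {
  prop <- matrix(c(10, 20, 5, 20, 40, 10), 3)  # proportional rows
  r0 <- chi2Independence(prop)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)
  tab <- matrix(c(10, 0, 10, 0, 0, 10, 0, 10), 4)  # hand Pearson: 40
  r1 <- chi2Independence(tab)
  expect_equal(r1$statistic, 40)
  expect_equal(r1$df, 3)
  expect_equal(r1$p, pchisq(40, 3, lower.tail = FALSE))
  r2 <- chi2Independence(2 * tab)
  expect_equal(r2$statistic, 80)   # doubling counts doubles the statistic
  expect_warning(r3 <- chi2Independence(rbind(tab, c(0, 0))), "zero")
  expect_equal(r3$statistic, 40)
})

test_that("the C-index of the true predictor beats a permuted one", {
  for (r in 1:5) {
    X <- withSeed(8000 + r, rnorm(150))
    oc <- simSurvival(150, X, seed = 8100 + r)
    cT <- coxFit(data.frame(x = X), oc)$c_index
    cP <- coxFit(data.frame(x = withSeed(8200 + r, sample(X))), oc)$c_index
    expect_gt(cT, cP)
  }
})
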