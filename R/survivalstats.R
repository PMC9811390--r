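# Experiments 2-3: LASSO-Cox feature selection, the radiomic risk score
# (RRS), log-rank-optimal cutpoint, Kaplan-Meier / log-rank, stratified Cox
# models with per-stratum hazard ratios and Harrell's C-index, and agreement
# tests between risk stratifications.

#' @importFrom survival Surv coxph survfit survdiff concordance
NULL

#' Stratified 70/30 cohort split
#'
#' Per-stratum proportional allocation by the largest-remainder rule, so
#' the overall training size is round(train_fraction * n) and every stratum
#' is represented proportionally. Singleton strata go to training with a
#' warning. Deterministic for a fixed seed.
#'
#' @param clinical data.frame with \code{subject_id} and the stratification
#'   column.
#' @param train_fraction fraction assigned to training, default 0.7.
#' @param stratify_by column name to stratify on, default "subgroup".
#' @param seed integer seed.
#' @return list with \code{train} and \code{test} subject-id vectors.
#' @export
splitCohort <- function(clinical, train_fraction = 0.7,
                        stratify_by = "subgroup", seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction <= 1)
  strata <- as.character(clinical[[stratify_by]])
  strata[is.na(strata)] <- "(missing)"
  ids <- as.character(clinical$subject_id)
  lev <- unique(strata)
  n <- length(ids)
  sizes <- vapply(lev, function(s) sum(strata == s), integer(1))
  if (any(sizes == 0)) stop("empty stratum")
  singles <- lev[sizes == 1L]
  if (length(singles))
    warning("singleton stratum(-a) assigned to training: ",
            paste(singles, collapse = ", "))
  quota <- train_fraction * sizes
  k <- floor(quota)
  k[sizes == 1L] <- 1L
  target <- round(train_fraction * n)
  rem <- target - sum(k)
  if (rem > 0) {
    fr <- quota - floor(quota)
    fr[sizes == 1L] <- -1
    ord <- order(-fr, seq_along(lev))
    ord <- ord[k[ord] < sizes[ord]]
    take <- head(ord, rem)
    k[take] <- k[take] + 1L
  }
  train <- withSeed(seed, unlist(lapply(seq_along(lev), function(i) {
    sids <- ids[strata == lev[i]]
    if (k[i] >= length(sids)) sids else sample(sids, k[i])
  }), use.names = FALSE))
  test <- setdiff(ids, train)
  if (!length(test)) warning("empty test set (train_fraction = ",
                             train_fraction, ")")
  list(train = train, test = test)
}

#' LASSO-Cox feature selection
#'
#' L1-penalized Cox partial likelihood (glmnet) with the penalty chosen by
#' k-fold cross-validation on the partial-likelihood deviance; nonzero
#' coefficients at the chosen penalty define the selected features. Feature
#' columns are z-scored internally (training mean / population SD, stored in
#' the model for reuse on held-out data). Fold assignment is stratified on
#' the event indicator and re-drawn (up to 25 times) if any fold lacks
#' events.
#'
#' @param features data.frame (subject_id + numeric feature columns) or
#'   numeric matrix.
#' @param outcomes data.frame with \code{os_days} and \code{event}.
#' @param folds number of CV folds, default 3.
#' @param seed integer seed for the fold assignment.
#' @param lambdaRule \code{"min"} (deviance-minimizing, default) or
#'   \code{"1se"}.
#' @param lambda optional fixed penalty: skips cross-validation and fits at
#'   this value directly.
#' @return a \linkS4class{RiskModel} (cutpoint not yet set); attribute
#'   \code{empty} is TRUE when the selection is empty.
#' @export
fitLassoCox <- function(features, outcomes, folds = 3L, seed = 1L,
                        lambdaRule = c("min", "1se"), lambda = NULL) {
  lambdaRule <- match.arg(lambdaRule)
  df <- as.data.frame(features)
  ids <- if ("subject_id" %in% names(df)) as.character(df$subject_id)
         else sprintf("S%03d", seq_len(nrow(df)))
  num <- vapply(df, is.numeric, logical(1))
  X <- as.matrix(df[num])
  bad <- apply(X, 2, function(v) anyNA(v) || sd(v) == 0)
  if (any(bad)) {
    warning("dropping constant/NA feature column(s): ",
            paste(colnames(X)[bad], collapse = ", "))
    X <- X[, !bad, drop = FALSE]
  }
  if (sum(outcomes$event) == 0) stop("no events: cannot fit a Cox model")
  ctr <- colMeans(X)
  scl <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  y <- Surv(outcomes$os_days, outcomes$event)

  ids0 <- ids
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(Z, y, family = "cox", standardize = FALSE)
    co <- as.numeric(coef(fit, s = lambda, exact = FALSE))
    names(co) <- rownames(coef(fit, s = lambda))
    sel <- co != 0
    model <- new("RiskModel", features = names(co)[sel],
                 coefficients = unname(co[sel]),
                 center = unname(ctr[names(co)[sel]]),
                 scale = unname(scl[names(co)[sel]]),
                 cutpoint = NA_real_, lambda = lambda, trainingIds = ids0)
    attr(model, "empty") <- !any(sel)
    return(model)
  }

  foldid <- NULL
  for (try in seq_len(25L)) {
    cand <- withSeed(streamSeed(seed, paste0("folds", try)), {
      fid <- integer(nrow(Z))
      for (ev in unique(outcomes$event)) {
        idx <- which(outcomes$event == ev)
        fid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      fid
    })
    evPerFold <- vapply(seq_len(folds), function(f)
      sum(outcomes$event[cand == f]), numeric(1))
    if (all(evPerFold > 0)) {
      foldid <- cand
      break
    }
  }
  if (is.null(foldid)) stop("could not build folds with events in each fold")

  cv <- glmnet::cv.glmnet(Z, y, family = "cox", foldid = foldid,
                          standardize = FALSE)
  lam <- if (lambdaRule == "min") cv$lambda.min else cv$lambda.1se
  co <- as.numeric(coef(cv, s = lam))
  names(co) <- rownames(coef(cv, s = lam))
  sel <- co != 0
  model <- new("RiskModel", features = names(co)[sel],
               coefficients = unname(co[sel]),
               center = unname(ctr[names(co)[sel]]),
               scale = unname(scl[names(co)[sel]]),
               cutpoint = NA_real_, lambda = lam, trainingIds = ids)
  if (!any(sel)) {
    message("LASSO selected no features (all coefficients zero)")
    attr(model, "empty") <- TRUE
  } else attr(model, "empty") <- FALSE
  model
}

#' Radiomic risk score
#'
#' The weighted sum of the model's selected features, z-scored with the
#' stored training parameters: RRS(x) = sum_j coef_j * z_j. Unselected
#' feature values never enter the score.
#'
#' @param features data.frame or matrix containing (at least) the selected
#'   feature columns.
#' @param model a \linkS4class{RiskModel}.
#' @return numeric vector of per-subject scores.
#' @export
computeRRS <- function(features, model) {
  stopifnot(is(model, "RiskModel"))
  df <- as.data.frame(features)
  if (!length(model@features)) return(rep(0, nrow(df)))
  missing <- setdiff(model@features, names(df))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  Z <- sweep(sweep(as.matrix(df[model@features]), 2, model@center), 2,
             model@scale, "/")
  as.numeric(Z %*% model@coefficients)
}

#' Log-rank-optimal cutpoint for a risk score
#'
#' X-tile-style grid search: every midpoint between consecutive sorted
#' unique scores whose induced low/high groups both hold at least
#' \code{min_group_frac} of the subjects is evaluated by the two-sample
#' log-rank chi-square; the maximizing cut is returned, ties resolved to
#' the lower cutpoint. No optimism correction is applied; an optional
#' permutation-adjusted p-value for the selected cut is available via
#' \code{nPermute}.
#'
#' @param scores numeric risk scores (>= 2 distinct values).
#' @param outcomes data.frame with \code{os_days}, \code{event}.
#' @param min_group_frac minimum group fraction, default 0.1.
#' @param nPermute optional number of permutations for an adjusted p-value
#'   of the maximal chi-square (0 = none).
#' @param seed seed for the permutations.
#' @return the cutpoint (numeric), with attributes \code{chisq} and, when
#'   requested, \code{p_adjusted}.
#' @export
findCutpoint <- function(scores, outcomes, min_group_frac = 0.1,
                         nPermute = 0L, seed = 1L) {
  u <- sort(unique(scores))
  if (length(u) < 2L) stop("need at least 2 distinct scores")
  cuts <- (u[-1] + u[-length(u)]) / 2
  n <- length(scores)
  minN <- ceiling(min_group_frac * n)
  ok <- vapply(cuts, function(cc)
    sum(scores <= cc) >= minN && sum(scores > cc) >= minN, logical(1))
  cuts <- cuts[ok]
  if (!length(cuts)) stop("no admissible cutpoint for min_group_frac = ",
                          min_group_frac)
  chis <- vapply(cuts, function(cc)
    .logrankChisq(scores > cc, outcomes), numeric(1))
  best <- which(chis >= max(chis) - 1e-12)[1]  # ties -> lower cutpoint
  out <- cuts[best]
  attr(out, "chisq") <- chis[best]
  if (nPermute > 0) {
    obs <- max(chis)
    perm <- withSeed(streamSeed(seed, "cutperm"), vapply(seq_len(nPermute),
      function(i) {
        sc <- sample(scores)
        max(vapply(cuts, function(cc) .logrankChisq(sc > cc, outcomes),
                   numeric(1)))
      }, numeric(1)))
    attr(out, "p_adjusted") <- (1 + sum(perm >= obs)) / (1 + nPermute)
  }
  out
}

.logrankChisq <- function(groups, outcomes) {
  if (sum(outcomes$event) == 0) return(0)
  sd <- tryCatch(survdiff(Surv(outcomes$os_days, outcomes$event) ~ groups),
                 error = function(e) NULL)  # degenerate (zero-variance) table
  if (is.null(sd)) return(0)
  x <- unname(sd$chisq)
  if (!is.finite(x)) 0 else x
}

#' Kaplan-Meier curves and two-sample log-rank test
#'
#' Product-limit survival estimates per group and the log-rank chi-square
#' with its p-value. A group without events triggers a warning, not an
#' error.
#'
#' @param groups two-level grouping vector.
#' @param outcomes data.frame with \code{os_days}, \code{event}.
#' @return list with \code{chisq}, \code{p}, \code{km} (survfit), \code{n}.
#' @export
kmLogrank <- function(groups, outcomes) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("exactly 2 groups required")
  ev <- tapply(outcomes$event, g, sum)
  if (any(ev == 0)) warning("group(s) with zero events: ",
                            paste(names(ev)[ev == 0], collapse = ", "))
  y <- Surv(outcomes$os_days, outcomes$event)
  sd <- survdiff(y ~ g)
  km <- survfit(y ~ g)
  list(chisq = unname(sd$chisq),
       p = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE),
       km = km, n = table(g))
}

#' Cox proportional-hazards fit with per-stratum hazard ratios
#'
#' Partial-likelihood fit (Efron tie handling) of survival on the supplied
#' covariates. Categorical covariates are dummy-coded against a declared
#' baseline stratum (first level by default), whose hazard ratio is printed
#' as 1; Harrell's C-index and its SE are reported, together with the score
#' (log-rank) test p-value. Rows with missing covariates are dropped with a
#' logged count. Monotone-likelihood / separation warnings from the fit are
#' captured and flagged.
#'
#' @param covariates data.frame of covariates (numeric or factor).
#' @param outcomes data.frame with \code{os_days}, \code{event}, aligned.
#' @param baselines named list: covariate -> baseline level for factors.
#' @return list of class \code{deformbat_coxfit}: \code{hr} (data.frame of
#'   covariate, stratum, HR), \code{c_index}, \code{c_index_se}, \code{p},
#'   \code{n}, \code{fit}, \code{flagged}.
#' @export
coxFit <- function(covariates, outcomes, baselines = list()) {
  df <- as.data.frame(covariates)
  keep <- complete.cases(df) & !is.na(outcomes$os_days) &
    !is.na(outcomes$event)
  dropped <- sum(!keep)
  if (dropped) message(dropped, " row(s) with missing values excluded")
  df <- df[keep, , drop = FALSE]
  oc <- outcomes[keep, , drop = FALSE]
  if (sum(oc$event) == 0) stop("no events: cannot fit a Cox model")
  for (cn in names(df)) {
    if (is.character(df[[cn]])) df[[cn]] <- factor(df[[cn]])
    if (is.factor(df[[cn]])) {
      df[[cn]] <- droplevels(df[[cn]])
      if (!is.null(baselines[[cn]]))
        df[[cn]] <- stats::relevel(df[[cn]], ref = baselines[[cn]])
    }
  }
  dat <- cbind(df, .os = oc$os_days, .ev = oc$event)
  flagged <- character(0)
  fit <- withCallingHandlers(
    coxph(Surv(.os, .ev) ~ ., data = dat, ties = "efron"),
    warning = function(w) {
      flagged <<- c(flagged, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  hrRows <- list()
  for (cn in names(df)) {
    if (is.factor(df[[cn]])) {
      levs <- levels(df[[cn]])
      hrRows[[cn]] <- data.frame(
        covariate = cn, stratum = levs,
        HR = c(1, vapply(levs[-1], function(l) {
          nm <- paste0(cn, l)
          unname(exp(coef(fit)[nm]))
        }, numeric(1))))
    } else {
      hrRows[[cn]] <- data.frame(covariate = cn, stratum = "-",
                                 HR = unname(exp(coef(fit)[cn])))
    }
  }
  conc <- fit$concordance
  list2 <- list(hr = do.call(rbind, c(hrRows, make.row.names = FALSE)),
                c_index = unname(conc["concordance"]),
                c_index_se = unname(conc["std"]),
                p = unname(s$sctest["pvalue"]),
                n = nrow(dat), fit = fit,
                flagged = flagged)
  class(list2) <- "deformbat_coxfit"
  list2
}

#' @export
print.deformbat_coxfit <- function(x, ...) {
  cat(sprintf("Cox PH fit: n = %d, C-index = %.3f +/- %.3f, p = %.3g\n",
              x$n, x$c_index, x$c_index_se, x$p))
  print(x$hr, row.names = FALSE)
  if (length(x$flagged)) cat("flagged:", x$flagged[1], "\n")
  invisible(x)
}

#' McNemar's test for correlated proportions
#'
#' Statistic (b - c)^2 / (b + c) on the discordant cells of a 2 x 2 table,
#' compared to chi-square with 1 df; b + c = 0 yields statistic 0, p = 1 by
#' convention.
#'
#' @param table 2 x 2 matrix of nonnegative counts (rows/cols: the two
#'   raters' low/high calls).
#' @return list with \code{statistic}, \code{p}.
#' @export
mcnemarTest <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(table < 0)) stop("negative counts")
  b <- table[1, 2]
  cc <- table[2, 1]
  if (b + cc == 0) return(list(statistic = 0, p = 1))
  stat <- (b - cc)^2 / (b + cc)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Pearson chi-square test of independence
#'
#' Pearson chi-square with (R - 1)(C - 1) degrees of freedom, no continuity
#' correction; all-zero rows/columns are dropped with a warning.
#'
#' @param table R x C matrix of nonnegative counts.
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
chi2Independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("negative counts")
  zr <- rowSums(table) == 0
  zc <- colSums(table) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero row(s)/column(s)")
    table <- table[!zr, !zc, drop = FALSE]
  }
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("need at least 2 rows and 2 columns")
  ts <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ts$statistic), df = unname(ts$parameter),
       p = unname(ts$p.value))
}

#' End-to-end survival risk stratification (Experiments 2-3 chain)
#'
#' Stratified 70/30 split, LASSO-Cox on the training features, RRS for all
#' subjects, log-rank-optimal cutpoint on the training scores (transferred
#' unchanged to the test cohort), and Kaplan-Meier / log-rank per cohort.
#'
#' @param features data.frame: subject_id + band feature columns.
#' @param clinical data.frame with subject_id, subgroup, os_days, event.
#' @param train_fraction,folds,seed see [splitCohort()] and [fitLassoCox()].
#' @param min_group_frac cutpoint admissibility guard, default 0.1.
#' @return list: \code{model} (\linkS4class{RiskModel} incl. cutpoint),
#'   \code{split}, \code{scores} (per subject), \code{train}, \code{test}
#'   (each: logrank list, groups).
#' @export
survivalPipeline <- function(features, clinical, train_fraction = 0.7,
                             folds = 3L, seed = 1L, min_group_frac = 0.1) {
  stopifnot(identical(as.character(features$subject_id),
                      as.character(clinical$subject_id)))
  sp <- splitCohort(clinical, train_fraction, seed = streamSeed(seed, "split"))
  isTr <- clinical$subject_id %in% sp$train
  model <- fitLassoCox(features[isTr, , drop = FALSE],
                       clinical[isTr, c("os_days", "event")],
                       folds = folds, seed = streamSeed(seed, "lasso"))
  scores <- computeRRS(features, model)
  cut <- findCutpoint(scores[isTr], clinical[isTr, c("os_days", "event")],
                      min_group_frac = min_group_frac)
  model@cutpoint <- as.numeric(cut)
  evalCohort <- function(sel) {
    grp <- factor(ifelse(scores[sel] > model@cutpoint, "high", "low"),
                  levels = c("low", "high"))
    lr <- if (nlevels(droplevels(grp)) == 2L)
      kmLogrank(grp, clinical[sel, c("os_days", "event")])
    else list(chisq = NA_real_, p = NA_real_, km = NULL, n = table(grp))
    list(groups = grp, logrank = lr)
  }
  list(model = model, split = sp, scores = scores,
       train = evalCohort(isTr), test = evalCohort(!isTr))
}
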