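# Experiment-1 statistics: correlation pruning, z-scoring, multiclass ANOVA
# with Tukey post-hoc across molecular subgroups, one-vs-all semantic
# feature tests, and hierarchical clustering of significant features.

.CANONICAL_SUBGROUPS <- c("WNT", "SHH", "G3", "G4")

#' Greedy correlation pruning of feature columns
#'
#' Iterates the feature columns in canonical order and drops any column
#' whose absolute Pearson correlation with an already-retained column
#' exceeds the threshold; deterministic and order-stable. Constant columns
#' are excluded (with a warning) before correlations are computed.
#'
#' @param features data.frame or matrix of feature columns (non-feature
#'   columns such as \code{subject_id} are passed through untouched).
#' @param threshold absolute-correlation threshold, default 0.95.
#' @return the pruned table, with attribute \code{dropped} naming the
#'   removed columns.
#' @export
pruneCorrelated <- function(features, threshold = 0.95) {
  isNum <- vapply(features, is.numeric, logical(1))
  featCols <- names(features)[isNum]
  if (length(featCols) < 2L) stop("need at least 2 feature columns")
  X <- as.matrix(features[featCols])
  sds <- apply(X, 2, sd)
  const <- featCols[!is.finite(sds) | sds == 0]
  if (length(const))
    warning("constant column(s) excluded: ", paste(const, collapse = ", "))
  candidates <- setdiff(featCols, const)
  kept <- character(0)
  dropped <- const
  for (cn in candidates) {
    if (length(kept) == 0L) {
      kept <- cn
      next
    }
    r <- suppressWarnings(abs(cor(X[, cn], X[, kept, drop = FALSE],
                                  use = "complete.obs")))
    if (any(r > threshold, na.rm = TRUE)) dropped <- c(dropped, cn)
    else kept <- c(kept, cn)
  }
  out <- features[c(names(features)[!isNum], kept)]
  attr(out, "dropped") <- dropped
  out
}

#' Z-score feature columns, storing the transform for reuse
#'
#' Per-column standardization using the fitting cohort's mean and
#' (population) SD; the parameters are stored so held-out data are
#' transformed with the training parameters rather than refit.
#'
#' @param features data.frame; numeric columns are scaled.
#' @param transform optional stored transform (the \code{transform}
#'   attribute of a previous call) to apply instead of fitting.
#' @return the scaled table with attribute \code{transform} (list of
#'   \code{center}, \code{scale}).
#' @export
scaleFeatures <- function(features, transform = NULL) {
  isNum <- vapply(features, is.numeric, logical(1))
  cols <- names(features)[isNum]
  if (is.null(transform)) {
    ctr <- vapply(features[cols], mean, numeric(1))
    n <- nrow(features)
    scl <- vapply(features[cols],
                  function(v) sqrt(mean((v - mean(v))^2)), numeric(1))
    if (any(scl == 0))
      stop("zero-SD column(s): ", paste(cols[scl == 0], collapse = ", "),
           " (prune constants first)")
    transform <- list(center = ctr, scale = scl)
  } else {
    cols <- intersect(cols, names(transform$center))
  }
  out <- features
  for (cn in cols)
    out[[cn]] <- (features[[cn]] - transform$center[[cn]]) /
      transform$scale[[cn]]
  attr(out, "transform") <- transform
  out
}

#' One-way ANOVA of a feature across molecular subgroups
#'
#' Fixed-effects multiclass ANOVA restricted to the four canonical
#' subgroups (WNT, SHH, G3, G4); transitional G3/G4 and missing labels are
#' excluded, as are groups with fewer than 2 members (with a warning).
#'
#' @param feature numeric vector.
#' @param labels subgroup labels, parallel to \code{feature}.
#' @return list with \code{F}, \code{p}, \code{df} and the \code{fit}.
#' @export
anovaSubgroups <- function(feature, labels) {
  keep <- labels %in% .CANONICAL_SUBGROUPS & !is.na(feature)
  f <- feature[keep]
  g <- labels[keep]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("subgroup(s) with < 2 members excluded: ",
            paste(small, collapse = ", "))
    keep2 <- !(g %in% small)
    f <- f[keep2]
    g <- g[keep2]
  }
  if (length(unique(g)) < 2L) stop("need >= 2 groups with >= 2 members each")
  fit <- aov(f ~ factor(g))
  s <- summary(fit)[[1]]
  list(F = s[1, "F value"], p = s[1, "Pr(>F)"], df = s[["Df"]], fit = fit)
}

#' Tukey HSD post-hoc pairwise comparison of subgroup means
#'
#' The "multiple comparison of means" post-hoc: family-wise adjusted
#' p-values for every subgroup pair after the ANOVA.
#'
#' @inheritParams anovaSubgroups
#' @param method \code{"tukey"} (default) or \code{"bonferroni"}
#'   (Bonferroni-adjusted pairwise t-tests).
#' @return data.frame: comparison, difference, adjusted p.
#' @export
posthocPairwise <- function(feature, labels, method = c("tukey",
                                                        "bonferroni")) {
  method <- match.arg(method)
  keep <- labels %in% .CANONICAL_SUBGROUPS & !is.na(feature)
  f <- feature[keep]
  g <- factor(labels[keep])
  sizes <- table(g)
  keep2 <- g %in% names(sizes)[sizes >= 2]
  f <- f[keep2]
  g <- droplevels(g[keep2])
  if (method == "tukey") {
    tk <- TukeyHSD(aov(f ~ g))$g
    data.frame(comparison = rownames(tk), diff = tk[, "diff"],
               p_adj = tk[, "p adj"], row.names = NULL)
  } else {
    pt <- stats::pairwise.t.test(f, g, p.adjust.method = "bonferroni")$p.value
    idx <- which(!is.na(pt), arr.ind = TRUE)
    data.frame(comparison = paste(rownames(pt)[idx[, 1]],
                                  colnames(pt)[idx[, 2]], sep = "-"),
               diff = NA_real_, p_adj = pt[idx], row.names = NULL)
  }
}

#' One-vs-all association tests of a semantic feature with subgroups
#'
#' For each subgroup (including transitional G3/G4 when present), builds the
#' (group vs rest) x levels contingency table and applies Fisher's exact
#' test when the semantic feature has two levels, Pearson's chi-square
#' otherwise. Degenerate features (a single observed level) are skipped with
#' an explicit status.
#'
#' @param feature character/factor vector of semantic levels (e.g.
#'   Midline/Lateral).
#' @param labels subgroup labels (up to five groups).
#' @return data.frame: group, test, p, status.
#' @export
semanticAssociation <- function(feature, labels) {
  keep <- !is.na(feature) & !is.na(labels)
  f <- factor(feature[keep])
  g <- factor(labels[keep])
  if (any(table(g) == 0)) stop("empty group")
  out <- lapply(levels(g), function(grp) {
    if (nlevels(f) < 2L)
      return(data.frame(group = grp, test = NA_character_, p = NA_real_,
                        status = "skipped: single level"))
    tab <- table(factor(g == grp, levels = c(TRUE, FALSE)), f)
    if (nlevels(f) == 2L) {
      data.frame(group = grp, test = "fisher",
                 p = fisher.test(tab)$p.value, status = "ok")
    } else {
      ts <- suppressWarnings(chisq.test(tab, correct = FALSE))
      status <- if (any(ts$expected < 5))
        "warning: expected cell count < 5" else "ok"
      data.frame(group = grp, test = "chisq", p = ts$p.value,
                 status = status)
    }
  })
  do.call(rbind, out)
}

#' Hierarchical clustering of subjects on significant features
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances) of the
#' z-scored significant features, with the two-cluster cut.
#'
#' @param features numeric matrix or data.frame (subjects x features),
#'   already z-scored.
#' @param k number of clusters for the cut, default 2.
#' @return list with \code{tree} (hclust) and \code{clusters} (cut labels).
#' @export
hierarchicalCluster <- function(features, k = 2L) {
  X <- as.matrix(features[vapply(as.data.frame(features), is.numeric,
                                 logical(1))])
  if (nrow(X) < 2L) stop("need at least 2 subjects")
  tree <- hclust(dist(X), method = "ward.D2")
  list(tree = tree, clusters = cutree(tree, k = min(k, nrow(X))))
}

#' Run the full subgroup-association analysis (Experiment-1 chain)
#'
#' Prune correlated features, z-score the survivors, ANOVA each retained
#' feature across the four subgroups, and Tukey post-hoc for the features
#' significant at \code{alpha}. An optional Benjamini-Hochberg adjustment
#' across features is available but off by default (per-feature p-values
#' are reported as-is).
#'
#' @param features data.frame with subject_id + feature columns.
#' @param labels subgroup labels, parallel to the rows.
#' @param alpha significance level, default 0.05.
#' @param threshold correlation-pruning threshold, default 0.95.
#' @param adjust apply BH adjustment across features (default FALSE).
#' @return list with \code{results} (feature, F, p, significant),
#'   \code{posthoc} (per significant feature), \code{pruned} feature names.
#' @export
subgroupAnalysis <- function(features, labels, alpha = 0.05,
                             threshold = 0.95, adjust = FALSE) {
  pruned <- pruneCorrelated(features, threshold)
  scaled <- scaleFeatures(pruned)
  cols <- names(scaled)[vapply(scaled, is.numeric, logical(1))]
  res <- do.call(rbind, lapply(cols, function(cn) {
    a <- anovaSubgroups(scaled[[cn]], labels)
    data.frame(feature = cn, F = a$F, p = a$p)
  }))
  if (adjust) res$p_adj <- stats::p.adjust(res$p, "BH")
  pcol <- if (adjust) res$p_adj else res$p
  res$significant <- pcol < alpha
  ph <- lapply(res$feature[res$significant], function(cn)
    posthocPairwise(scaled[[cn]], labels))
  names(ph) <- res$feature[res$significant]
  list(results = res, posthoc = ph, pruned = attr(pruned, "dropped"))
}
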