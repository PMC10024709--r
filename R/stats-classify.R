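# Unsupervised phenotype discrimination: standardize -> PCA to 2-D ->
# k-means (k = 2), per-biomarker ROC with Youden cutoff, the APD20/APD90
# cutoff classifier, and the group-comparison statistics.

#' Canonical biomarker column names of a cohort table
#' @export
biomarker_columns <- function() {
  c("Cm_pF", "Ediast_mV", "EdiastDC_mV", "APD90_ms", "APD50_ms", "APD20_ms",
    "APD20_APD90", "dVdtmax_Vps", "APA_mV")
}

# Impute a mostly-present column by its median (with a warning), or drop it
# when more than half the cells lack it.
prepare_features <- function(table, cols = biomarker_columns()) {
  stopifnot(all(cols %in% names(table)))
  X <- table[, cols, drop = FALSE]
  keep <- vapply(cols, function(cl) {
    frac_na <- mean(is.na(X[[cl]]))
    if (frac_na > 0.5) {
      warning(sprintf("dropping '%s': %.0f%% missing", cl, 100 * frac_na),
              call. = FALSE)
      return(FALSE)
    }
    if (frac_na > 0) {
      warning(sprintf("imputing %d missing value(s) in '%s' by cohort median",
                      sum(is.na(X[[cl]])), cl), call. = FALSE)
      X[[cl]][is.na(X[[cl]])] <<- stats::median(X[[cl]], na.rm = TRUE)
    }
    TRUE
  }, logical(1))
  X[, keep, drop = FALSE]
}

#' Standardize a cohort table and project onto two principal components
#'
#' Each biomarker column is z-scored (the raw units span orders of
#' magnitude) before the principal-component projection; the first two
#' components are retained. The sign convention is canonicalized so that the
#' APD90 loading on PC1 is non-negative (and the largest-magnitude loading
#' on PC2 is positive); a global sign flip is an equivalent solution.
#' Constant features are dropped with a warning.
#'
#' @param table cohort data frame containing the [biomarker_columns()];
#'   >= 3 cells.
#' @param cols feature columns to use.
#' @return list of class `pca2`: `scores` (n x 2), `loadings` (p x 2),
#'   `variance_explained` (length-2 fractions), `sdev`, `features`.
#' @export
standardize_and_pca2 <- function(table, cols = biomarker_columns()) {
  X <- prepare_features(table, cols)
  if (nrow(X) < 3) stop("need >= 3 cells for the 2-D projection")
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(names(X)[sds == 0], collapse = ", ")),
            call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
  }
  Z <- scale(as.matrix(X))
  p <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  scores <- p$x[, 1:2, drop = FALSE]
  load <- p$rotation[, 1:2, drop = FALSE]
  if ("APD90_ms" %in% rownames(load) && load["APD90_ms", 1] < 0) {
    load[, 1] <- -load[, 1]; scores[, 1] <- -scores[, 1]
  }
  if (load[which.max(abs(load[, 2])), 2] < 0) {
    load[, 2] <- -load[, 2]; scores[, 2] <- -scores[, 2]
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = load,
                 variance_explained = ve[1:2], sdev = p$sdev,
                 features = colnames(X)),
            class = "pca2")
}

#' Two-cluster k-means on PCA scores
#'
#' k = 2 with 10 random restarts (best within-cluster sum of squares kept),
#' deterministic under `seed`.
#'
#' @param scores n x 2 matrix of PC scores (>= 2 rows).
#' @param seed integer seed.
#' @return integer labels in `{1, 2}` with the `kmeans` fit as attribute
#'   `fit`.
#' @export
kmeans2 <- function(scores, seed = 1L) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop("need >= 2 cells to form two clusters")
  if (all(apply(scores, 2, function(x) diff(range(x))) == 0))
    stop("degenerate clustering: all points identical")
  fit <- with_preserved_seed(seed,
                             stats::kmeans(scores, centers = 2, nstart = 10))
  structure(as.integer(fit$cluster), fit = fit)
}

#' Assign atrial/ventricular semantics to cluster labels
#'
#' The cluster with the lower mean APD90 is called atrial-like (triangular,
#' short AP), the other ventricular-like.
#'
#' @param labels integer cluster labels in `{1, 2}`.
#' @param apd90 per-cell APD90 values, ms.
#' @return factor with levels `atrial-like`, `ventricular-like`.
#' @export
cluster_semantics <- function(labels, apd90) {
  stopifnot(length(labels) == length(apd90))
  m1 <- mean(apd90[labels == 1]); m2 <- mean(apd90[labels == 2])
  atr_cluster <- if (m1 <= m2) 1L else 2L
  factor(ifelse(labels == atr_cluster, "atrial-like", "ventricular-like"),
         levels = c("atrial-like", "ventricular-like"))
}

#' ROC analysis with Youden-index cutoff
#'
#' AUC by the rank (Mann-Whitney) identity; orientation chosen so the AUC is
#' >= 0.5; the cutoff maximizes the Youden index
#' `J = sensitivity + specificity - 1`, ties broken toward the lower
#' threshold. Candidate thresholds are midpoints between adjacent distinct
#' values (plus outer sentinels); a value on the positive side of the cutoff
#' (per `direction`) predicts the positive class.
#'
#' @param values numeric feature, one per cell.
#' @param labels logical (or coercible) indicator of the positive class.
#' @return list of class `roc_result`: `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, `youden_J`, `direction` (`">="` if values at or above
#'   the cutoff predict positive, `"<"` otherwise).
#' @export
roc_youden <- function(values, labels) {
  labels <- as.logical(labels)
  if (anyNA(values) || anyNA(labels)) stop("missing values in ROC input")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(values)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  direction <- ">="
  if (auc < 0.5) { auc <- 1 - auc; direction <- "<" }
  v <- sort(unique(values))
  thr <- if (length(v) > 1) c(v[1] - 1, (v[-1] + v[-length(v)]) / 2,
                              v[length(v)] + 1)
         else c(v - 1, v + 1)
  best <- list(J = -Inf)
  for (ct in thr) {
    pred <- if (direction == ">=") values >= ct else values < ct
    sens <- sum(pred & labels) / n1
    spec <- sum(!pred & !labels) / n0
    J <- sens + spec - 1
    if (J > best$J + 1e-12) best <- list(J = J, cutoff = ct, sens = sens,
                                         spec = spec)
  }
  structure(list(auc = auc, cutoff = best$cutoff,
                 sensitivity = best$sens, specificity = best$spec,
                 youden_J = best$J, direction = direction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f | cutoff %.4g (positive if value %s cutoff) | sens %.3f spec %.3f (J %.3f)\n",
    x$auc, x$cutoff, x$direction, x$sensitivity, x$specificity, x$youden_J))
  invisible(x)
}

#' Classify a cell by its APD20/APD90 triangulation ratio
#'
#' A ratio below the cutoff means a triangular (atrial-like) AP; at or above
#' the cutoff, a plateau (ventricular-like) AP — the boundary itself is
#' ventricular.
#'
#' @param x an `ap_biomarkers` object or a numeric APD20/APD90 ratio.
#' @param cutoff dimensionless cutoff (default 0.44).
#' @return factor with levels `atrial-like`, `ventricular-like`.
#' @export
classify_by_cutoff <- function(x, cutoff = 0.44) {
  ratio <- if (inherits(x, "ap_biomarkers")) x$ratio_20_90 else x
  if (any(!is.finite(ratio))) stop("APD20/APD90 ratio must be finite")
  factor(ifelse(ratio < cutoff, "atrial-like", "ventricular-like"),
         levels = c("atrial-like", "ventricular-like"))
}

#' Mann-Whitney U test
#'
#' Two-sided; exact when both groups have n <= 8 and there are no ties,
#' normal approximation (with tie/continuity correction) otherwise.
#'
#' @param a,b numeric value vectors (both non-empty).
#' @return list: `U`, `p`.
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Levene test for equality of variances
#'
#' Classic (mean-centred) Levene statistic on absolute deviations from the
#' group mean, with the p-value from the F distribution.
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return list: `W`, `p`.
#' @export
levene_w <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("`groups` must list >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs >= 2 values")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  lt <- car::leveneTest(y, g, center = mean)
  list(W = lt[1, "F value"], p = lt[1, "Pr(>F)"])
}

#' Agreement between cluster labels and ground truth
#'
#' Reports the adjusted Rand index and the best-permutation accuracy of a
#' two-way labelling against known phenotypes.
#'
#' @param labels cluster labels (any two-level coding).
#' @param truth true labels.
#' @return list: `ari`, `accuracy`.
#' @export
cluster_agreement <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  labels <- as.integer(factor(labels)); truth <- as.integer(factor(truth))
  acc <- mean(labels == truth)
  list(ari = mclust::adjustedRandIndex(labels, truth),
       accuracy = max(acc, 1 - acc))
}
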