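# End-to-end glue: virtual cohort -> DC recordings -> biomarker table ->
# unsupervised classification.

#' Record a cohort: dynamic-clamp plus companion no-injection runs
#'
#' For each cell, runs a no-injection recording (unassisted diastolic
#' potential) and a DC recording under `cfg`, extracts the nine biomarkers,
#' and assembles the per-cell feature table with the canonical column names.
#'
#' @param cells list of `virtual_cell` objects (e.g. [generate_cohort()]).
#' @param cfg the injected [ik1_config()] (default: atrial formulation at
#'   scaling 1).
#' @param protocol a [stim_protocol()].
#' @param ... passed to the integrator (`dt`, `dt_internal`, ...).
#' @return data frame of class `cohort_table`: `cell_id`, `phenotype`
#'   (ground truth of the synthetic cells), and the [biomarker_columns()].
#' @export
cohort_biomarkers <- function(cells, cfg = ik1_config("atr", scaling_DC = 1),
                              protocol = stim_protocol(), ...) {
  stopifnot(length(cells) >= 1)
  rows <- lapply(seq_along(cells), function(i) {
    cell <- cells[[i]]
    plain <- simulate_ap(cell, protocol, ...)
    dc <- run_dc(cell, cfg, protocol, ...)
    bm <- extract_biomarkers(dc$voltage, trace_no_dc = plain, Cm = cell$Cm,
                             discard_beats = protocol$discard_beats)
    data.frame(cell_id = names(cells)[i] %||% sprintf("cell_%02d", i),
               phenotype = cell$phenotype,
               Cm_pF = bm$Cm, Ediast_mV = bm$E_diast,
               EdiastDC_mV = bm$E_diast_DC, APD90_ms = bm$APD90,
               APD50_ms = bm$APD50, APD20_ms = bm$APD20,
               APD20_APD90 = bm$ratio_20_90, dVdtmax_Vps = bm$dVdt_max,
               APA_mV = bm$APA)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unsupervised classification of a recorded cohort
#'
#' The discrimination chain: z-score the nine biomarkers, project onto two
#' principal components, split with k-means (k = 2), name the clusters by
#' mean APD90 (lower = atrial-like), then derive a per-biomarker ROC (AUC,
#' Youden cutoff) for discriminating the two clusters, and apply the
#' triangulation-ratio cutoff classifier.
#'
#' @param table a `cohort_table` (or data frame with [biomarker_columns()]).
#' @param seed seed for the k-means restarts.
#' @param cutoff APD20/APD90 cutoff for the rule-based classifier.
#' @return list of class `cluster_result`: `pca` (scores, loadings,
#'   variance explained), `labels` (cluster index), `phenotype_call`
#'   (factor), `roc` (per-biomarker data frame), `cutoff_call` (factor from
#'   [classify_by_cutoff()]), `agreement` (vs `table$phenotype`, when
#'   present).
#' @export
classify_cohort <- function(table, seed = 1L, cutoff = 0.44) {
  pca <- standardize_and_pca2(table)
  labels <- kmeans2(pca$scores, seed = seed)
  call <- cluster_semantics(labels, table$APD90_ms)
  pos <- call == "ventricular-like"
  roc <- do.call(rbind, lapply(biomarker_columns(), function(cl) {
    vals <- table[[cl]]
    if (anyNA(vals) || length(unique(vals)) < 2 || !any(pos) || all(pos))
      return(NULL)
    r <- roc_youden(vals, pos)
    data.frame(biomarker = cl, auc = r$auc, cutoff = r$cutoff,
               sensitivity = r$sensitivity, specificity = r$specificity,
               direction = r$direction)
  }))
  res <- list(pca = pca, labels = labels, phenotype_call = call, roc = roc,
              cutoff_call = classify_by_cutoff(table$APD20_APD90, cutoff),
              cutoff = cutoff)
  if ("phenotype" %in% names(table)) {
    truth <- factor(table$phenotype)
    res$agreement <- cluster_agreement(
      call, factor(ifelse(truth == "atrial", "atrial-like",
                          "ventricular-like"),
                   levels = c("atrial-like", "ventricular-like")))
  }
  class(res) <- "cluster_result"
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("cluster result: %d cells -> %d atrial-like, %d ventricular-like\n",
              n, sum(x$phenotype_call == "atrial-like"),
              sum(x$phenotype_call == "ventricular-like")))
  cat(sprintf("  PC1/PC2 variance explained: %.1f%% / %.1f%%\n",
              100 * x$pca$variance_explained[1],
              100 * x$pca$variance_explained[2]))
  if (!is.null(x$agreement))
    cat(sprintf("  agreement with ground truth: ARI %.3f, accuracy %.3f\n",
                x$agreement$ari, x$agreement$accuracy))
  if (!is.null(x$roc)) {
    top <- x$roc[order(-x$roc$auc), ][1:min(4, nrow(x$roc)), ]
    cat("  top discriminating biomarkers (cluster 1 vs 2):\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %-12s AUC %.3f, cutoff %.4g\n",
                  top$biomarker[i], top$auc[i], top$cutoff[i]))
  }
  invisible(x)
}
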