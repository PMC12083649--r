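# Recapitulation benchmark: spatial sgRNA detection vs pooled-screen
# detection, as an ROC problem. The pooled per-sgRNA detection fraction
# (fraction of tumor sample lobes in which the sgRNA was detected) is the
# continuous predictor; spatial detection (sgRNA area above a spot cutoff)
# is the binary response.

#' Build the ROC benchmark from a detection table
#'
#' @param table data.frame with columns `sgrna`, `pooled_fraction` (in
#'   [0, 1]) and `spatial_area` (spots).
#' @param area_cutoff Spatial response cutoff: positive when
#'   `spatial_area > area_cutoff` (default 2).
#' @param pooled_cutoff Binarized-predictor cutoff for the reported confusion
#'   matrix: pooled-detected when `pooled_fraction > pooled_cutoff`
#'   (default 0.25).
#' @return List: `scores` (pooled fractions), `labels` (0/1 spatial
#'   response), `confusion` (2x2 table at the binarized predictor), `table`.
#' @export
build_benchmark <- function(table, area_cutoff = 2, pooled_cutoff = 0.25) {
  need <- c("sgrna", "pooled_fraction", "spatial_area")
  if (!all(need %in% names(table))) {
    stop("detection table needs columns: ", paste(need, collapse = ", "))
  }
  if (!nrow(table)) stop("empty detection table")
  labels <- as.integer(table$spatial_area > area_cutoff)
  if (length(unique(labels)) < 2L) {
    stop("degenerate ROC: only one response class at area cutoff ", area_cutoff)
  }
  pred <- factor(table$pooled_fraction > pooled_cutoff, levels = c(FALSE, TRUE),
                 labels = c("pooled_neg", "pooled_pos"))
  resp <- factor(labels, levels = c(0, 1),
                 labels = c("spatial_neg", "spatial_pos"))
  list(scores = table$pooled_fraction, labels = labels,
       confusion = table(predictor = pred, response = resp), table = table)
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score threshold to build the ROC curve; the AUC is
#' the trapezoidal integral, which equals the Mann-Whitney U statistic
#' normalized by `n_pos * n_neg` with half-credit for tied scores.
#'
#' @param scores Numeric predictor scores (higher = more positive).
#' @param labels 0/1 (or logical) response labels.
#' @return List: `curve` (data.frame `threshold, fpr, tpr`), `auc`, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with NA dropped")
    scores <- scores[ok]; labels <- labels[ok]
  }
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n_neg, 0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       auc = auc, n_pos = n_pos, n_neg = n_neg)
}
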