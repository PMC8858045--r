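# Internal helpers shared across modules.

# Upper-tail hypergeometric p-value: P(X >= k) where X counts successes in
# `n` draws without replacement from a universe of size `N` containing `K`
# successes. Used for module/disease-gene overlap, ORA, and disease-neighbor
# enrichment.
hyper_upper_p <- function(k, K, N, n) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= K, N >= n)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Benjamini-Hochberg FDR; thin wrapper so every module corrects the same way.
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")

# Pearson correlation p-value via the t transform, two-sided.
cor_test_p <- function(r, n) {
  if (is.na(r) || n < 3) return(NA_real_)
  r <- max(min(r, 1), -1)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

# ROC curve from continuous scores (higher score = more case-like).
# Returns the (FPR, TPR) step points and the trapezoidal AUC.
roc_curve <- function(scores, labels, positive = "case") {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  if (!any(pos) || all(pos)) {
    stop("ROC needs both classes present")
  }
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]
  s <- scores[ord]
  # collapse tied scores into single operating points
  uniq <- !duplicated(s, fromLast = TRUE) # last index of each tie block
  tpr <- cumsum(pos) / sum(pos)
  fpr <- cumsum(!pos) / sum(!pos)
  tpr <- c(0, tpr[uniq])
  fpr <- c(0, fpr[uniq])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# Mann-Whitney AUC with ties counted 1/2 (rank-sum formulation).
rank_auc <- function(case_values, control_values) {
  n1 <- length(case_values)
  n2 <- length(control_values)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(case_values, control_values))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

check_condition <- function(condition, n = NULL) {
  condition <- as.character(condition)
  if (!all(condition %in% c("case", "control"))) {
    stop("condition labels must be 'case' or 'control'")
  }
  if (!is.null(n) && length(condition) != n) {
    stop("condition length does not match number of samples")
  }
  condition
}
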