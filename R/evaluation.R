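#' Confusion counts and per-residue rates at a threshold
#'
#' A residue is called MoRF when `score > threshold` (strict). Residues
#' with NA labels (ignored, e.g. after [mask_regions()]) are excluded
#' from all counts. Rates: `ACC = (TP + TN) / (N_MoRF + N_non)`,
#' `TPR = TP / N_MoRF`, `FPR = FP / N_non`.
#'
#' @param scores numeric score vector
#' @param labels binary labels (1 = MoRF, 0 = non-MoRF, NA = ignore)
#' @param threshold decision threshold (default 0)
#' @return object of class `confusion_counts` with TP, TN, FP, FN,
#'   N_MoRF, N_non, ACC, TPR, FPR
#' @export
confusion <- function(scores, labels, threshold = 0) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  keep <- !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  call_ <- scores > threshold
  TP <- sum(call_ & labels == 1L)
  FP <- sum(call_ & labels == 0L)
  FN <- sum(!call_ & labels == 1L)
  TN <- sum(!call_ & labels == 0L)
  n_morf <- TP + FN; n_non <- TN + FP
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 N_MoRF = n_morf, N_non = n_non,
                 ACC = (TP + TN) / (n_morf + n_non),
                 TPR = if (n_morf > 0L) TP / n_morf else NA_real_,
                 FPR = if (n_non > 0L) FP / n_non else NA_real_),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP", x$TP, "FP", x$FP, "TN", x$TN, "FN", x$FN, "\n")
  cat("  ACC", format(x$ACC, digits = 4), " TPR", format(x$TPR, digits = 4),
      " FPR", format(x$FPR, digits = 4), "\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' The ROC curve is traced by sweeping the threshold over the observed
#' scores (strict calls); the AUC is computed by the rank (Mann-Whitney)
#' method with half credit for ties, which equals the probability that a
#' random positive outscores a random negative.
#'
#' @param scores numeric score vector
#' @param labels binary labels (NA = ignore); both classes required
#' @return list with `auc` and `curve` (data.frame threshold, fpr, tpr,
#'   including the all-call point at threshold -Inf)
#' @export
roc_auc <- function(scores, labels) {
  keep <- !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs both classes present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores > t & labels == 0L) / n_neg,
                 numeric(1)),
    tpr = vapply(thr, function(t) sum(scores > t & labels == 1L) / n_pos,
                 numeric(1))
  )
  list(auc = auc, curve = curve)
}

#' Operating points at fixed true-positive rates
#'
#' For each target TPR, picks the largest threshold achieving
#' `TPR >= target` (strict calls) and reports the achieved
#' (TPR, FPR, ACC) triple there.
#'
#' @param scores numeric score vector
#' @param labels binary labels (NA = ignore); both classes required
#' @param tpr_targets numeric vector of target TPRs in \[0, 1\]
#' @return data.frame with columns target_tpr, threshold, tpr, fpr, acc
#' @export
metrics_at_tpr <- function(scores, labels, tpr_targets) {
  keep <- !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop("both classes must be present", call. = FALSE)
  if (any(tpr_targets < 0 | tpr_targets > 1))
    stop("TPR targets must lie in [0, 1]", call. = FALSE)
  cand <- c(sort(unique(scores), decreasing = TRUE), -Inf)
  rows <- lapply(tpr_targets, function(tgt) {
    for (th in cand) {
      cc <- confusion(scores, labels, th)
      if (cc$TPR >= tgt)
        return(data.frame(target_tpr = tgt, threshold = th,
                          tpr = cc$TPR, fpr = cc$FPR, acc = cc$ACC))
    }
  })
  do.call(rbind, rows)
}
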