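#' ROC area under the curve for presence vs background scores
#'
#' Computed with the rank (Mann-Whitney) formulation, which equals the
#' exhaustive pairwise probability
#' `P(presence score > background score) + 0.5 P(equal)`.
#'
#' @param presence_scores,background_scores non-empty numeric vectors.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(presence_scores, background_scores) {
  n1 <- length(presence_scores); n0 <- length(background_scores)
  if (n1 == 0L || n0 == 0L)
    stop("both score vectors must be non-empty", call. = FALSE)
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts at a threshold
#'
#' Presences scored `>= t` are true positives (misses are omission errors);
#' background cells scored `>= t` are false positives (commission errors),
#' with background standing in for absences as usual in presence-only
#' evaluation.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @param t threshold in \[0, 1\].
#' @return A named list with `TP`, `FN`, `TN`, `FP`.
#' @export
confusion_at <- function(presence_scores, background_scores, t) {
  stopifnot(length(t) == 1L, is.finite(t))
  list(TP = sum(presence_scores >= t),
       FN = sum(presence_scores < t),
       TN = sum(background_scores < t),
       FP = sum(background_scores >= t))
}

#' True skill statistic
#'
#' `TSS = sensitivity + specificity - 1`, in \[-1, 1\]; 0 is chance-level.
#'
#' @param counts confusion counts (list with `TP`, `FN`, `TN`, `FP`).
#' @return TSS.
#' @export
tss <- function(counts) {
  np <- counts$TP + counts$FN
  nb <- counts$TN + counts$FP
  if (np == 0 || nb == 0)
    stop("TSS is undefined without both presences and background",
         call. = FALSE)
  counts$TP / np + counts$TN / nb - 1
}

#' Cohen's kappa of a confusion table
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (TP + TN) / N` and chance agreement
#' `p_e = ((TP+FN)(TP+FP) + (TN+FP)(TN+FN)) / N^2`.
#'
#' @param counts confusion counts (list with `TP`, `FN`, `TN`, `FP`).
#' @return kappa in \[-1, 1\].
#' @export
kappa_statistic <- function(counts) {
  N <- counts$TP + counts$FN + counts$TN + counts$FP
  if (N == 0) stop("empty confusion table", call. = FALSE)
  p_o <- (counts$TP + counts$TN) / N
  p_e <- ((counts$TP + counts$FN) * (counts$TP + counts$FP) +
            (counts$TN + counts$FP) * (counts$TN + counts$FN)) / N^2
  if (p_e >= 1) stop("kappa is undefined when chance agreement is 1",
                     call. = FALSE)
  (p_o - p_e) / (1 - p_e)
}

#' Maximum training sensitivity-plus-specificity threshold
#'
#' Scans the distinct observed scores (plus 0) as candidate thresholds and
#' returns the one maximising sensitivity + specificity; ties go to the
#' smallest threshold. This is the MTSS rule used to binarise cloglog
#' suitability maps.
#'
#' @param presence_scores,background_scores non-empty numeric vectors.
#' @return The selected threshold.
#' @export
mtss_threshold <- function(presence_scores, background_scores) {
  if (length(presence_scores) == 0L || length(background_scores) == 0L)
    stop("both score vectors must be non-empty", call. = FALSE)
  cand <- sort(unique(c(0, presence_scores, background_scores)))
  np <- length(presence_scores); nb <- length(background_scores)
  ss <- vapply(cand, function(t) {
    sum(presence_scores >= t) / np + sum(background_scores < t) / nb
  }, numeric(1))
  cand[which.max(ss)]  # which.max takes the first (smallest) maximiser
}

#' Full evaluation report for one model run
#'
#' Threshold-free AUC plus TSS and kappa at the MTSS threshold computed on
#' the same scores.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return A one-row tibble: `auc`, `threshold`, `tss`, `kappa`, `tp`,
#'   `fn`, `tn`, `fp`, `n_presence`, `n_background`.
#' @export
evaluate_scores <- function(presence_scores, background_scores) {
  t <- mtss_threshold(presence_scores, background_scores)
  cc <- confusion_at(presence_scores, background_scores, t)
  tibble::tibble(
    auc = roc_auc(presence_scores, background_scores),
    threshold = t,
    tss = tss(cc),
    kappa = kappa_statistic(cc),
    tp = cc$TP, fn = cc$FN, tn = cc$TN, fp = cc$FP,
    n_presence = length(presence_scores),
    n_background = length(background_scores)
  )
}
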