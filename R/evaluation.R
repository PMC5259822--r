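# Residue-level evaluation: ROC AUC, operating points at fixed TPR, and
# the per-sequence success rate.

.check_binary <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels have different lengths")
  }
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L) {
    stop("both classes must be present to build a ROC curve")
  }
  labels
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the empirical ROC curve built from the score
#' vector, with tied scores grouped into single ROC vertices (so ties
#' contribute half, exactly as in the Mann-Whitney pairwise statistic).
#'
#' @param scores Numeric per-residue scores, higher = more MoRF-like.
#' @param labels Binary vector (1 = MoRF residue, 0 = non-MoRF).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- .check_binary(scores, labels)
  r <- .roc_points(scores, labels)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1L) + utils::tail(r$tpr, -1L)) / 2)
}

# Empirical ROC vertices: one point per distinct score (descending),
# prepended with (0, 0). Also returns the counts at each vertex.
.roc_points <- function(scores, labels) {
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- cumsum(rle(s)$lengths)  # last index of each distinct score
  tp <- cumsum(l == 1L)[last]
  fp <- cumsum(l == 0L)[last]
  list(threshold = c(Inf, s[last]),
       tpr = c(0, tp / P), fpr = c(0, fp / N),
       tp = c(0L, tp), fp = c(0L, fp), P = P, N = N)
}

# Most conservative ROC vertex reaching TPR >= level (no interpolation).
.vertex_at_tpr <- function(scores, labels, tpr_level) {
  stopifnot(tpr_level > 0, tpr_level <= 1)
  r <- .roc_points(scores, labels)
  i <- which(r$tpr >= tpr_level)[1L]
  list(threshold = r$threshold[i], tpr = r$tpr[i], fpr = r$fpr[i],
       tp = r$tp[i], fp = r$fp[i], P = r$P, N = r$N)
}

#' False-positive rate at a fixed true-positive rate
#'
#' Finds the most conservative score threshold whose TPR reaches at least
#' `tpr_level` on the empirical ROC (no interpolation between vertices)
#' and returns the FPR at that threshold.
#'
#' @inheritParams roc_auc
#' @param tpr_level Target TPR in `(0, 1]`; the operating points used to
#'   benchmark MoRF predictors are 0.222 and 0.389.
#' @return FPR in `[0, 1]`.
#' @export
fpr_at_tpr <- function(scores, labels, tpr_level) {
  labels <- .check_binary(scores, labels)
  .vertex_at_tpr(scores, labels, tpr_level)$fpr
}

#' Classification accuracy at a fixed true-positive rate
#'
#' Uses the same threshold rule as [fpr_at_tpr()] and returns
#' `(TP + TN) / (P + N)` at that threshold.
#'
#' @inheritParams fpr_at_tpr
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_at_tpr <- function(scores, labels, tpr_level) {
  labels <- .check_binary(scores, labels)
  v <- .vertex_at_tpr(scores, labels, tpr_level)
  tn <- v$N - v$fp
  (v$tp + tn) / (v$P + v$N)
}

#' Per-sequence success rate
#'
#' A sequence counts as a success when the mean propensity over its true
#' MoRF residues strictly exceeds the mean over its non-MoRF residues.
#' Sequences lacking one of the two classes are excluded from the
#' denominator (a message reports how many).
#'
#' @param per_sequence List of records, each with numeric `scores` and
#'   binary `labels` of equal length.
#' @return Fraction of evaluable sequences in `[0, 1]`.
#' @export
success_rate <- function(per_sequence) {
  if (length(per_sequence) == 0L) stop("no sequences to evaluate")
  ok <- vapply(per_sequence, function(r) {
    l <- as.integer(r$labels)
    any(l == 1L) && any(l == 0L)
  }, TRUE)
  if (any(!ok)) {
    message(sum(!ok), " sequence(s) lacking MoRF or non-MoRF residues ",
            "excluded from the success rate")
  }
  per_sequence <- per_sequence[ok]
  if (length(per_sequence) == 0L) stop("no evaluable sequences")
  hits <- vapply(per_sequence, function(r) {
    l <- as.integer(r$labels)
    mean(r$scores[l == 1L]) > mean(r$scores[l == 0L])
  }, TRUE)
  mean(hits)
}

#' Full evaluation report over a set of scored sequences
#'
#' Pools all residues for the ROC-based metrics (every non-MoRF residue,
#' flanks included, counts as a negative) and computes the per-sequence
#' success rate.
#'
#' @param per_sequence List of records with numeric `scores` and binary
#'   `labels` (1 = MoRF) per sequence.
#' @param tpr_levels TPR operating points for the FPR/accuracy readouts.
#' @return List with elements `auc`, `success_rate`, `fpr_at_tpr`,
#'   `accuracy_at_tpr` (both named by TPR level), `n_pos`, `n_neg` and
#'   `n_sequences`.
#' @export
evaluation_report <- function(per_sequence, tpr_levels = c(0.222, 0.389)) {
  scores <- unlist(lapply(per_sequence, `[[`, "scores"), use.names = FALSE)
  labels <- unlist(lapply(per_sequence, `[[`, "labels"), use.names = FALSE)
  labels <- .check_binary(scores, labels)
  lvl_names <- format(tpr_levels, trim = TRUE)
  list(
    auc = roc_auc(scores, labels),
    success_rate = success_rate(per_sequence),
    fpr_at_tpr = stats::setNames(
      vapply(tpr_levels, function(t) fpr_at_tpr(scores, labels, t), 0),
      lvl_names),
    accuracy_at_tpr = stats::setNames(
      vapply(tpr_levels, function(t) accuracy_at_tpr(scores, labels, t), 0),
      lvl_names),
    n_pos = sum(labels == 1L),
    n_neg = sum(labels == 0L),
    n_sequences = length(per_sequence)
  )
}
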