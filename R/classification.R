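# ROC discrimination between disease stages and the MGUS -> MM progression
# analysis. AUC is the tie-corrected Mann-Whitney probability; the operating
# cutoff maximizes Youden's J over midpoints between adjacent distinct
# scores, so a cutoff never coincides with an observed score.

#' ROC curve and AUC
#'
#' AUC equals the probability that a random positive outscores a random
#' negative, ties counting one half (computed from mid-ranks). The curve is
#' evaluated at every distinct score threshold.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels 0/1 class labels; both classes must be present.
#' @return list with \code{auc}, \code{curve} (data.frame fpr, tpr,
#'   threshold, from (0,0) to (1,1)), and the inputs.
#' @export
rocAuc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0, 0)
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                      threshold = c(Inf, thr))
  list(auc = auc, curve = curve, scores = scores, labels = labels)
}

#' Optimal ROC cutoff by Youden's J
#'
#' Candidate cutoffs are midpoints between adjacent distinct sorted scores;
#' the cutoff maximizing J = sensitivity + specificity - 1 is returned
#' (smallest cutoff on ties). Sensitivity is the proportion of positives
#' strictly above the cutoff; specificity the proportion of negatives at or
#' below it.
#'
#' @param roc result of \code{\link{rocAuc}}.
#' @return list with \code{cutoff}, \code{sensitivity}, \code{specificity},
#'   \code{youden_j}.
#' @export
optimalCutoff <- function(roc) {
  scores <- roc$scores; labels <- roc$labels
  s <- sort(unique(scores))
  if (length(s) < 2L) stop("need >= 2 distinct scores")
  cand <- (s[-1L] + s[-length(s)]) / 2
  sens <- vapply(cand, function(c) mean(scores[labels == 1L] > c), 0)
  spec <- vapply(cand, function(c) mean(scores[labels == 0L] <= c), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))[1L]   # candidates ascend, so earliest = smallest
  list(cutoff = cand[best], sensitivity = sens[best],
       specificity = spec[best], youden_j = j[best])
}

#' Pairwise stage discrimination AUCs
#'
#' For every ordered pair of disease stages (earlier vs later), the AUC of
#' the score with the later stage as the positive class. Stages with fewer
#' than 2 samples produce NA for their pairs, with a message.
#'
#' @param scores per-sample scores.
#' @param stages ordered factor of stage labels (e.g. Healthy < MGUS < SMM
#'   < NDMM < RRMM).
#' @return numeric matrix, rows = earlier stage, columns = later stage.
#' @export
stageDiscrimination <- function(scores, stages) {
  stages <- if (is.ordered(stages)) droplevels(stages)
            else factor(stages, ordered = TRUE)
  lv <- levels(stages)
  if (length(lv) < 2L) stop("need >= 2 stages present")
  counts <- table(stages)
  small <- names(counts)[counts < 2L]
  if (length(small))
    message("stage(s) with < 2 samples, pairs reported NA: ",
            paste(small, collapse = ", "))
  out <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (a in seq_along(lv)) for (b in seq_along(lv)) if (a < b) {
    if (counts[lv[a]] < 2L || counts[lv[b]] < 2L) next
    sel <- stages %in% lv[c(a, b)]
    out[a, b] <- rocAuc(scores[sel], as.integer(stages[sel] == lv[b]))$auc
  }
  out
}

#' Progression analysis: ROC, optimal cutoff, and high/low progression rates
#'
#' Computes the ROC of the score for progression, picks the Youden-optimal
#' cutoff, splits samples at it (high = score > cutoff), and tests the
#' resulting 2x2 progression table with Fisher's exact test.
#'
#' @param scores per-sample scores.
#' @param progressed 0/1 progression outcome.
#' @return list with \code{roc}, \code{cutoff} (list from
#'   \code{\link{optimalCutoff}}), \code{table} (2x2 group x outcome),
#'   \code{rate_high}, \code{rate_low}, \code{rate_ratio},
#'   \code{fisher_p}.
#' @export
progressionEval <- function(scores, progressed) {
  roc <- rocAuc(scores, progressed)
  cut <- optimalCutoff(roc)
  high <- scores > cut$cutoff
  tab <- matrix(c(sum(high & progressed == 1), sum(high & progressed == 0),
                  sum(!high & progressed == 1), sum(!high & progressed == 0)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("high", "low"),
                                c("progressed", "not_progressed")))
  rateHigh <- tab["high", 1L] / sum(tab["high", ])
  rateLow <- tab["low", 1L] / sum(tab["low", ])
  fp <- tryCatch(fisherExactTest(tab)$p_value, error = function(e) NA_real_)
  list(roc = roc, cutoff = cut, table = tab,
       rate_high = rateHigh, rate_low = rateLow,
       rate_ratio = rateHigh / rateLow, fisher_p = fp)
}
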