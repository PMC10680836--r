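#' Scored prediction set
#'
#' Pairs classifier scores with ground truth, optionally carrying per-item
#' strata (chromosome, U fraction, read length) for stratified evaluation.
#'
#' @param scores numeric scores in `[0, 1]` (finite).
#' @param truth positives/negatives: logical, 0/1 numeric, or the strings
#'   `"positive"`/`"negative"` (also accepts `"labeled"`/`"unlabeled"`).
#' @param strata optional data frame with any of `chromosome`,
#'   `u_fraction`, `length` columns, one row per item.
#' @return an object of class `scored_set`.
#' @export
scored_set <- function(scores, truth, strata = NULL) {
  scores <- as.numeric(scores)
  if (any(!is.finite(scores))) stop("scores must be finite")
  truth <- if (is.character(truth) || is.factor(truth)) {
    as.character(truth) %in% c("positive", "labeled", "1", "TRUE")
  } else {
    as.logical(truth)
  }
  if (length(scores) != length(truth)) {
    stop("scores and truth must have equal length")
  }
  if (!is.null(strata)) {
    stopifnot(is.data.frame(strata), nrow(strata) == length(scores))
  }
  structure(list(scores = scores, truth = truth, strata = strata),
            class = "scored_set")
}

.check_both_classes <- function(s, what) {
  if (!any(s$truth) || all(s$truth)) {
    stop(what, " is undefined: input contains a single class")
  }
}

#' Area under the ROC curve
#'
#' The probability that a uniformly random positive outranks a uniformly
#' random negative, with ties counted one half (the Mann-Whitney identity),
#' computed via the rank-sum formula.
#'
#' @param s a [scored_set] with at least one positive and one negative.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(s) {
  stopifnot(inherits(s, "scored_set"))
  .check_both_classes(s, "ROC AUC")
  n_pos <- sum(s$truth)
  n_neg <- sum(!s$truth)
  r <- rank(s$scores, ties.method = "average")
  (sum(r[s$truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise summation over all score thresholds (average precision), not
#' trapezoidal interpolation, which is optimistically biased for PR curves.
#'
#' @param s a [scored_set] with at least one positive.
#' @return PR AUC in `[0, 1]`.
#' @export
pr_auc <- function(s) {
  stopifnot(inherits(s, "scored_set"))
  if (!any(s$truth)) stop("PR AUC is undefined: no positives")
  o <- order(s$scores, decreasing = TRUE)
  truth <- s$truth[o]
  scores <- s$scores[o]
  tp <- cumsum(truth)
  fp <- cumsum(!truth)
  # collapse tied scores onto a single threshold (last index of each tie run)
  last_of_tie <- c(scores[-1] != scores[-length(scores)], TRUE)
  tp <- tp[last_of_tie]
  fp <- fp[last_of_tie]
  n_pos <- sum(s$truth)
  prec <- tp / (tp + fp)
  d_tp <- diff(c(0, tp))
  sum(prec * d_tp) / n_pos
}

#' Balanced accuracy at a threshold
#'
#' Mean of sensitivity and specificity, `(TPR + TNR) / 2`, with the call
#' rule `score >= threshold` predicting positive.
#'
#' @param s a [scored_set] with both classes present.
#' @param threshold call threshold.
#' @return balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(s, threshold = 0.5) {
  stopifnot(inherits(s, "scored_set"))
  .check_both_classes(s, "balanced accuracy")
  called <- s$scores >= threshold
  tpr <- sum(called & s$truth) / sum(s$truth)
  tnr <- sum(!called & !s$truth) / sum(!s$truth)
  (tpr + tnr) / 2
}

#' F1 score at a threshold
#'
#' Harmonic mean of precision and recall; defined as 0 when
#' `precision + recall` is 0.
#'
#' @inheritParams balanced_accuracy
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(s, threshold = 0.5) {
  stopifnot(inherits(s, "scored_set"))
  called <- s$scores >= threshold
  if (!any(called) && !any(s$truth)) {
    stop("F1 is undefined: no predicted or actual positives")
  }
  tp <- sum(called & s$truth)
  fp <- sum(called & !s$truth)
  fn <- sum(!called & s$truth)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

#' Stratified evaluation
#'
#' Computes per-stratum AUC and PR-AUC: by chromosome, by U-content bins,
#' or by read-length bins. Strata in which a class is missing are reported
#' with `NA` metrics rather than dropped, so stratum sizes always sum to
#' the total.
#'
#' @param s a [scored_set] whose `strata` carry the requested key.
#' @param by one of `"chromosome"`, `"u_fraction"`, `"length"`.
#' @param bins numeric bin edges for the continuous keys (left-closed,
#'   right-open; the last bin is open-ended). Defaults: U-content quintiles
#'   of the data; length edges 0, 1, 2, 3 kb.
#' @return data frame `label`, `n`, `auc`, `pr_auc` (one row per stratum).
#' @export
stratified_eval <- function(s, by = c("chromosome", "u_fraction", "length"),
                            bins = NULL) {
  stopifnot(inherits(s, "scored_set"))
  by <- match.arg(by)
  if (is.null(s$strata) || !(by %in% names(s$strata))) {
    stop("stratification key '", by, "' missing from the scored set")
  }
  v <- s$strata[[by]]
  if (by == "chromosome") {
    grp <- as.character(v)
  } else {
    if (is.null(bins)) {
      bins <- if (by == "length") {
        c(0, 1000, 2000, 3000)
      } else {
        unique(stats::quantile(v, probs = seq(0, 0.8, by = 0.2)))
      }
    }
    edges <- c(bins, Inf)
    grp <- as.character(cut(v, breaks = edges, right = FALSE,
                            include.lowest = TRUE))
  }
  out <- lapply(sort(unique(grp)), function(g) {
    idx <- grp == g
    sub <- scored_set(s$scores[idx], s$truth[idx])
    both <- any(sub$truth) && !all(sub$truth)
    data.frame(
      label = g, n = sum(idx),
      auc = if (both) roc_auc(sub) else NA_real_,
      pr_auc = if (any(sub$truth)) pr_auc(sub) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Pearson or Spearman correlation
#'
#' Thin, validating wrapper over [stats::cor()]; Spearman uses average
#' ranks for ties.
#'
#' @param x,y numeric vectors of equal length, at least 3 values.
#' @param method `"pearson"` or `"spearman"`.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation is undefined: zero variance")
  }
  cor(x, y, method = method)
}
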