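#' Aggregate per-read calls to transcript (or gene) level
#'
#' Counts modified and unmodified calls per assignment target. Whether the
#' aggregation is transcript- or gene-level is decided entirely by the
#' assignment table supplied. Targets below the read-support floor are
#' excluded (default 100 reads, so estimates rest on substantial support);
#' reads without an assignment are ignored. Exclusion counts are attached
#' as the `"summary"` attribute.
#'
#' @param preds data frame from [predict_reads()]`$predictions` (needs
#'   `read_id` and `call`).
#' @param assignment data frame `read_id`, `target_id`, optional
#'   `condition`.
#' @param min_reads minimum reads per target.
#' @return data frame `target_id`, `n_mod`, `n_unmod`, `n_total`,
#'   `mod_fraction` and (if supplied) `condition`, with a `"summary"`
#'   attribute counting unassigned reads and support-excluded targets.
#' @export
aggregate_by_transcript <- function(preds, assignment, min_reads = 100L) {
  stopifnot(is.data.frame(preds),
            all(c("read_id", "call") %in% names(preds)),
            is.data.frame(assignment),
            all(c("read_id", "target_id") %in% names(assignment)),
            min_reads >= 1L)
  has_cond <- "condition" %in% names(assignment)
  m <- merge(preds[, c("read_id", "call")], assignment, by = "read_id")
  unassigned <- nrow(preds) - nrow(m)
  if (nrow(m) == 0L) {
    out <- data.frame(target_id = character(0), n_mod = integer(0),
                      n_unmod = integer(0), n_total = integer(0),
                      mod_fraction = numeric(0))
    if (has_cond) out$condition <- character(0)
    attr(out, "summary") <- c(unassigned_reads = unassigned,
                              excluded_low_support = 0L)
    return(out)
  }
  key <- if (has_cond) {
    interaction(m$target_id, m$condition, drop = TRUE, sep = "\r")
  } else {
    factor(m$target_id)
  }
  n_mod <- tapply(m$call == "modified", key, sum)
  n_tot <- tapply(m$call, key, length)
  parts <- strsplit(names(n_tot), "\r", fixed = TRUE)
  out <- data.frame(
    target_id = vapply(parts, `[`, character(1), 1L),
    n_mod = as.integer(n_mod),
    n_unmod = as.integer(n_tot - n_mod),
    n_total = as.integer(n_tot),
    mod_fraction = as.numeric(n_mod / n_tot),
    stringsAsFactors = FALSE
  )
  if (has_cond) out$condition <- vapply(parts, `[`, character(1), 2L)
  keep <- out$n_total >= min_reads
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "summary") <- c(unassigned_reads = unassigned,
                            excluded_low_support = sum(!keep))
  res
}

#' Relative modification increase between two conditions
#'
#' `100 * (mod_fraction_condition / mod_fraction_control - 1)`: the
#' percentage increase in the modified-read fraction of a target under the
#' experimental condition relative to control. Positive values indicate a
#' higher prevalence of modified reads in the condition experiment.
#'
#' @param condition,control single rows (or lists) with `target_id` and
#'   `mod_fraction`, as produced by [aggregate_by_transcript()].
#' @return signed percentage.
#' @export
relative_modification_increase <- function(condition, control) {
  if (!identical(as.character(condition$target_id),
                 as.character(control$target_id))) {
    stop("condition and control rows refer to different targets")
  }
  fc <- as.numeric(condition$mod_fraction)
  f0 <- as.numeric(control$mod_fraction)
  if (f0 == 0) {
    stop("relative modification increase is undefined: ",
         "control modification fraction is zero")
  }
  100 * (fc / f0 - 1)
}

#' Estimate transcript half-life from modified/unmodified counts
#'
#' Under first-order turnover during a 5EU pulse of duration `label_time`
#' hours, the newly synthesized fraction is `f_new = 1 - exp(-k * t)`, so
#' `k = -log(1 - f_new) / label_time` and `t_half = log(2) / k`. The
#' modified-read fraction estimates `f_new`; when classifier error rates
#' are supplied it is first corrected to
#' `(mod_fraction - fpr) / (tpr - fpr)` and clamped to `[0, 1]`. Boundary
#' fractions are flagged rather than silently clipped: `f_new = 0` yields
#' an infinite half-life (flag `"no_new"`), `f_new = 1` a zero half-life
#' (flag `"saturated"`).
#'
#' @param stats data frame from [aggregate_by_transcript()] (one or more
#'   rows).
#' @param label_time pulse duration in hours (> 0).
#' @param correction optional `list(tpr =, fpr =)` with
#'   `0 <= fpr < tpr <= 1`.
#' @return data frame `target_id`, `n_total`, `f_new`, `k_decay`,
#'   `t_half`, `label_time`, `flag`.
#' @export
estimate_half_life <- function(stats, label_time, correction = NULL) {
  stopifnot(is.data.frame(stats), nrow(stats) >= 1L,
            all(c("target_id", "mod_fraction", "n_total") %in% names(stats)),
            all(stats$n_total > 0))
  if (!is.numeric(label_time) || length(label_time) != 1L || label_time <= 0) {
    stop("label_time must be a positive number of hours")
  }
  f <- as.numeric(stats$mod_fraction)
  if (!is.null(correction)) {
    stopifnot(is.list(correction),
              all(c("tpr", "fpr") %in% names(correction)))
    tpr <- correction$tpr
    fpr <- correction$fpr
    if (!(fpr >= 0 && fpr < tpr && tpr <= 1)) {
      stop("error-rate correction requires 0 <= fpr < tpr <= 1")
    }
    f <- pmin(1, pmax(0, (f - fpr) / (tpr - fpr)))
  }
  k <- ifelse(f >= 1, Inf, -log(1 - f) / label_time)
  t_half <- ifelse(f == 0, Inf, log(2) / k)
  flag <- ifelse(f == 0, "no_new", ifelse(f >= 1, "saturated", "ok"))
  data.frame(
    target_id = stats$target_id, n_total = stats$n_total,
    f_new = f, k_decay = ifelse(f == 0, 0, k), t_half = t_half,
    label_time = label_time, flag = flag, stringsAsFactors = FALSE
  )
}

#' Concordance with reference half-lives at increasing read support
#'
#' For each read-support threshold, correlates log half-lives of the
#' transcripts meeting it against a reference table (Pearson and Spearman).
#' Boundary estimates (infinite or zero half-life) are excluded from the
#' correlations. Thresholds with fewer than 3 overlapping transcripts give
#' `NA` entries rather than an error.
#'
#' @param estimates data frame from [estimate_half_life()].
#' @param reference data frame `target_id`, `t_half`.
#' @param thresholds integer vector of minimum `n_total` values.
#' @return data frame `threshold`, `n`, `pearson`, `spearman`.
#' @export
coverage_stratified_concordance <- function(estimates, reference,
                                            thresholds = c(1, 50, 100, 200)) {
  stopifnot(is.data.frame(estimates),
            all(c("target_id", "t_half", "n_total") %in% names(estimates)),
            is.data.frame(reference),
            all(c("target_id", "t_half") %in% names(reference)))
  m <- merge(estimates, reference, by = "target_id",
             suffixes = c("_est", "_ref"))
  m <- m[is.finite(m$t_half_est) & m$t_half_est > 0 &
           is.finite(m$t_half_ref) & m$t_half_ref > 0, , drop = FALSE]
  out <- lapply(thresholds, function(th) {
    sub <- m[m$n_total >= th, , drop = FALSE]
    if (nrow(sub) < 3L) {
      return(data.frame(threshold = th, n = nrow(sub),
                        pearson = NA_real_, spearman = NA_real_))
    }
    data.frame(
      threshold = th, n = nrow(sub),
      pearson = correlate(log(sub$t_half_est), log(sub$t_half_ref),
                          "pearson"),
      spearman = correlate(log(sub$t_half_est), log(sub$t_half_ref),
                           "spearman")
    )
  })
  do.call(rbind, out)
}
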