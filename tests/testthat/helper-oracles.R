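# Independent brute-force oracles and small fixture builders used across
# the suite.  These deliberately use the slowest, most literal formulation
# of each quantity so they cannot share a bug with the vectorized
# implementations they check.

# O(n^2) pairwise Mann-Whitney AUC: ties count one half.
roc_auc_oracle <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  wins <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) wins <- wins + 1 else if (p == q) wins <- wins + 0.5
    }
  }
  wins / (length(pos) * length(neg))
}

# Average precision by exhaustive enumeration of every distinct score as a
# threshold (call rule: score >= threshold), summing precision * delta-recall.
pr_auc_oracle <- function(scores, truth) {
  n_pos <- sum(truth)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_rec <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(called & truth)
    prec <- tp / sum(called)
    rec <- tp / n_pos
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

# a minimal pore model with constant levels, handy for deterministic checks
flat_pore_model <- function(k = 5L, mean_pA = 100, sd_pA = 2) {
  pm <- make_default_pore_model(seed = 1L, k = k)
  pm$mean_pA[] <- mean_pA
  pm$sd_pA[] <- sd_pA
  pm
}

random_rna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# tiny architecture used wherever the full reference net would be overkill
tiny_classifier_config <- function() {
  classifier_config(conv_channels = c(3L, 4L), kernel_size = 3L,
                    stride = 2L, gru_hidden = 5L, head_hidden = 6L)
}

make_read <- function(id, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  signal_read(id, rnorm(n, 100, 10))
}

# no-crop preprocessing used for synthetic reads (they carry no adapter head)
sim_preprocess <- function() {
  preprocess_config(crop_head = 0L, min_raw_length = 60L,
                    max_raw_length = 400000L)
}
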