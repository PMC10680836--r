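test_that("per-transcript aggregation counts calls and applies the support floor", {
  preds <- data.frame(
    read_id = paste0("r", 1:5),
    call = c("modified", "modified", "modified", "unmodified", "modified")
  )
  asg <- data.frame(read_id = paste0("r", 1:4),
                    target_id = c("t1", "t1", "t1", "t2"))
  out <- aggregate_by_transcript(preds, asg, min_reads = 1L)
  t1 <- out[out$target_id == "t1", ]
  expect_equal(t1$n_mod, 3L)
  expect_equal(t1$n_unmod, 0L)
  expect_equal(t1$mod_fraction, 1.0)
  expect_equal(attr(out, "summary")[["unassigned_reads"]], 1)

  # a 99-read transcript is excluded at the default 100-read floor
  preds99 <- data.frame(read_id = paste0("x", 1:99),
                        call = rep("modified", 99))
  asg99 <- data.frame(read_id = paste0("x", 1:99), target_id = "t9")
  out99 <- aggregate_by_transcript(preds99, asg99, min_reads = 100L)
  expect_equal(nrow(out99), 0L)
  expect_equal(attr(out99, "summary")[["excluded_low_support"]], 1)

  empty <- aggregate_by_transcript(preds[0, ], asg, min_reads = 1L)
  expect_equal(nrow(empty), 0L)
})

test_that("aggregation keeps conditions separate", {
  preds <- data.frame(read_id = paste0("r", 1:6),
                      call = c(rep("modified", 4), rep("unmodified", 2)))
  asg <- data.frame(read_id = paste0("r", 1:6), target_id = "g1",
                    condition = rep(c("hs", "ctrl"), each = 3))
  out <- aggregate_by_transcript(preds, asg, min_reads = 1L)
  expect_equal(nrow(out), 2L)
  expect_equal(out$mod_fraction[out$condition == "hs"], 1.0)
  expect_equal(out$mod_fraction[out$condition == "ctrl"], 1 / 3)
})

test_that("relative modification increase reproduces its defining arithmetic", {
  row <- function(f) list(target_id = "g", mod_fraction = f)
  expect_equal(relative_modification_increase(row(0.2), row(0.2)), 0)
  expect_equal(relative_modification_increase(row(0.3), row(0.2)), 50)
  expect_equal(relative_modification_increase(row(0.0), row(0.2)), -100)
  expect_error(relative_modification_increase(row(0.3), row(0)), "zero")
  expect_error(relative_modification_increase(
    list(target_id = "a", mod_fraction = 0.1),
    list(target_id = "b", mod_fraction = 0.1)), "different targets")
})

test_that("swapping condition and control follows the reciprocal identity", {
  row <- function(f) list(target_id = "g", mod_fraction = f)
  for (fc in c(0.05, 0.2, 0.4, 0.8)) {
    for (f0 in c(0.1, 0.25, 0.5)) {
      r <- relative_modification_increase(row(fc), row(f0))
      r_swap <- relative_modification_increase(row(f0), row(fc))
      expect_equal(r_swap, 100 * (1 / (1 + r / 100) - 1), tolerance = 1e-12)
    }
  }
})

test_that("half-life estimation inverts first-order pulse labeling", {
  st <- function(f, n = 100L) data.frame(
    target_id = "t", n_mod = round(f * n), n_unmod = n - round(f * n),
    n_total = n, mod_fraction = f
  )
  expect_equal(estimate_half_life(st(0.5), 2)$t_half, 2)
  expect_equal(estimate_half_life(st(0.75), 2)$t_half, 1)
  # n_mod=20, n_unmod=60: f_new = 0.25, t_half = 2*log(2)/(-log(0.75))
  est <- estimate_half_life(
    data.frame(target_id = "t", n_mod = 20L, n_unmod = 60L, n_total = 80L,
               mod_fraction = 0.25), 2)
  expect_equal(est$t_half, 2 * log(2) / (-log(0.75)), tolerance = 1e-9)
  expect_equal(est$t_half, 4.818842, tolerance = 1e-4)
  expect_error(estimate_half_life(st(0.5), 0), "positive")
})

test_that("boundary fractions are flagged, not silently clipped", {
  st <- function(f) data.frame(target_id = "t", n_mod = 0L, n_unmod = 0L,
                               n_total = 10L, mod_fraction = f)
  none <- estimate_half_life(st(0), 2)
  expect_equal(none$flag, "no_new")
  expect_equal(none$t_half, Inf)
  expect_equal(none$k_decay, 0)
  all_new <- estimate_half_life(st(1), 2)
  expect_equal(all_new$flag, "saturated")
  expect_equal(all_new$t_half, 0)
})

test_that("half-life recovery is exact against the simulator's labeling rule", {
  t_true <- exp(seq(log(0.5), log(24), length.out = 40))
  f_new <- 1 - 2^(-2 / t_true)
  st <- data.frame(target_id = paste0("t", seq_along(t_true)),
                   n_mod = 0L, n_unmod = 0L, n_total = 1000L,
                   mod_fraction = f_new)
  est <- estimate_half_life(st, 2)
  expect_lt(max(abs(est$t_half - t_true) / t_true), 1e-9)
  # strict monotonicity: larger f_new, shorter half-life
  expect_true(all(diff(est$t_half[order(est$f_new)]) < 0))
})

test_that("classifier-error correction recovers the true fraction", {
  tpr <- 0.9
  fpr <- 0.1
  f_true <- c(0.1, 0.3, 0.5, 0.8)
  f_obs <- f_true * tpr + (1 - f_true) * fpr
  st <- data.frame(target_id = paste0("t", 1:4), n_mod = 0L, n_unmod = 0L,
                   n_total = 100L, mod_fraction = f_obs)
  est <- estimate_half_life(st, 2, correction = list(tpr = tpr, fpr = fpr))
  expect_equal(est$f_new, f_true, tolerance = 1e-12)
  expect_error(
    estimate_half_life(st, 2, correction = list(tpr = 0.4, fpr = 0.6)),
    "fpr < tpr")
})

test_that("kinetics-mode simulation with perfect calls recovers half-lives", {
  cfg <- sim_config(kinetics_mode = TRUE, reads_per_transcript = 120L,
                    transcripts_per_chromosome = 10L,
                    half_life_range_h = c(0.5, 24), label_time_h = 2,
                    read_length_range = c(50L, 60L), seed = 23L)
  ds <- simulate_dataset(cfg, signals = FALSE)
  man <- ds$manifest
  preds <- data.frame(
    read_id = man$read_id,
    call = ifelse(man$label == "labeled", "modified", "unmodified")
  )
  asg <- data.frame(read_id = man$read_id, target_id = man$transcript_id)
  agg <- aggregate_by_transcript(preds, asg, min_reads = 1L)
  est <- estimate_half_life(agg, cfg$label_time_h)
  truth <- ds$transcripts[match(est$target_id,
                                ds$transcripts$transcript_id), ]
  ok <- is.finite(est$t_half) & est$t_half > 0
  expect_gt(mean(ok), 0.9)
  rho <- correlate(log(est$t_half[ok]), log(truth$true_half_life_h[ok]),
                   "spearman")
  expect_gt(rho, 0.9)
})

test_that("degraded calls with correction are unbiased in the median", {
  set.seed(41)
  tpr <- 0.92
  fpr <- 0.08
  n_tr <- 60
  t_true <- exp(runif(n_tr, log(1), log(12)))
  f_true <- 1 - 2^(-2 / t_true)
  n_reads <- 400L
  est_rows <- lapply(seq_len(n_tr), function(i) {
    labeled <- runif(n_reads) < f_true[i]
    called <- ifelse(labeled, runif(n_reads) < tpr, runif(n_reads) < fpr)
    data.frame(target_id = paste0("t", i), n_mod = sum(called),
               n_unmod = sum(!called), n_total = n_reads,
               mod_fraction = mean(called))
  })
  st <- do.call(rbind, est_rows)
  est <- estimate_half_life(st, 2, correction = list(tpr = tpr, fpr = fpr))
  ok <- is.finite(est$t_half) & est$t_half > 0
  log_ratio <- log(est$t_half[ok] / t_true[ok])
  # bootstrap CI for the median log-ratio must cover zero
  boots <- replicate(500, median(sample(log_ratio, replace = TRUE)))
  expect_gte(stats::quantile(boots, 0.995), 0)
  expect_lte(stats::quantile(boots, 0.005), 0)
})

test_that("coverage-stratified concordance behaves at its edges", {
  est <- data.frame(target_id = paste0("t", 1:10),
                    t_half = exp(seq(0, 2, length.out = 10)),
                    n_total = seq(20, 200, by = 20))
  ref <- data.frame(target_id = est$target_id, t_half = est$t_half)
  out <- coverage_stratified_concordance(est, ref,
                                         thresholds = c(1, 100, 180))
  expect_equal(out$pearson[1:2], rep(1, 2), tolerance = 1e-12)
  expect_equal(out$spearman[1:2], rep(1, 2), tolerance = 1e-12)
  expect_equal(out$n, c(10L, 6L, 2L))
  expect_true(is.na(out$pearson[3]))  # < 3 transcripts: undefined, not error
})
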