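test_that("chromosome-holdout splits follow the rule exactly", {
  tab <- data.frame(
    read_id = c("r1", "r2", "r3", "r4", "r5"),
    chromosome = c("chr1", "unmapped", "chr5", "chr20", "chr7"),
    is_secondary = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  sp <- assign_splits(tab)
  expect_equal(sp$split, c("test", "excluded", "excluded", "validation",
                           "train"))
  expect_error(
    assign_splits(data.frame(read_id = c("a", "a"),
                             chromosome = c("chr1", "chr2"))),
    "duplicate"
  )
  # splits are exhaustive and disjoint by construction
  expect_true(all(sp$split %in% c("train", "validation", "test", "excluded")))
})

test_that("the balanced sampler is calibrated and proportional", {
  mk <- function(prefix, n) lapply(seq_len(n), function(i)
    signal_read(paste0(prefix, i), c(1, 2, 3)))
  pool <- dataset_pool(list(mk("p", 200)),
                       list(mk("nA", 300), mk("nB", 100)))
  draw <- balanced_sampler(pool, seed = 42)
  draws <- replicate(10000, {
    d <- draw()
    c(d$label, if (d$label == 0) d$source else NA_integer_)
  })
  pos_frac <- mean(draws[1, ])
  expect_lt(abs(pos_frac - 0.5), 3 * sqrt(0.25 / 10000))
  src <- draws[2, !is.na(draws[2, ])]
  n_neg <- length(src)
  expect_lt(abs(mean(src == 1) - 0.75), 3 * sqrt(0.75 * 0.25 / n_neg))

  # single negative source: everything comes from it
  pool1 <- dataset_pool(list(mk("p", 5)), list(mk("n", 5)))
  d1 <- balanced_sampler(pool1, seed = 1)
  expect_true(all(replicate(50, d1()$source) == 1L))
})

test_that("the sampler is deterministic and has its own RNG stream", {
  mk <- function(prefix, n) lapply(seq_len(n), function(i)
    signal_read(paste0(prefix, i), c(1, 2, 3)))
  pool <- dataset_pool(list(mk("p", 50)), list(mk("n", 50)))
  d1 <- balanced_sampler(pool, seed = 7)
  ids1 <- replicate(30, d1()$read_id)
  d2 <- balanced_sampler(pool, seed = 7)
  set.seed(999)  # outside noise must not perturb the stream
  ids2 <- vapply(1:30, function(i) { runif(1); d2()$read_id }, character(1))
  expect_identical(ids1, ids2)
})

test_that("learning-rate warmup is linear from zero", {
  cfg <- train_config(lr = 0.001, warmup_steps = 1000L)
  expect_equal(lr_at_step(0, cfg), 0)
  expect_equal(lr_at_step(500, cfg), 0.0005)
  expect_equal(lr_at_step(1000, cfg), 0.001)
  expect_equal(lr_at_step(5000, cfg), 0.001)
})

test_that("accumulated gradients equal the gradient of the mean loss", {
  cfg <- tiny_classifier_config()
  m <- build_model(cfg, seed = 11)
  ccfg <- eukinet:::.cfg_for_cpp(cfg)
  set.seed(11)
  xs <- lapply(1:3, function(i) rnorm(30 + 5 * i))
  ys <- c(1, 0, 1)
  # accumulate per-sequence gradients, average over the window
  gs <- lapply(1:3, function(i)
    eukinet:::.flatten_params(
      eukinet:::.nn_grad_cpp(xs[[i]], ys[i], m$params, ccfg, m$bn_run,
                             0)$grads[names(m$params)]))
  g_acc <- Reduce(`+`, gs) / 3
  # independent route: finite differences of the jointly computed mean loss
  # (batch-norm statistics frozen per sequence, as in training)
  theta <- eukinet:::.flatten_params(m$params)
  mean_loss <- function(th) {
    p <- eukinet:::.unflatten_params(th, m$params)
    mean(vapply(1:3, function(i)
      eukinet:::.nn_loss_cpp(xs[[i]], ys[i], p, ccfg, m$bn_run, TRUE),
      numeric(1)))
  }
  set.seed(12)
  for (j in sample(length(theta), 40)) {
    eps <- 1e-6
    tp <- theta; tp[j] <- tp[j] + eps
    tm <- theta; tm[j] <- tm[j] - eps
    num <- (mean_loss(tp) - mean_loss(tm)) / (2 * eps)
    expect_lt(abs(num - g_acc[j]) / max(1e-6, abs(num) + abs(g_acc[j])),
              1e-3)
  }
})

# a small trainable problem: short flat-pore reads where labeled reads carry
# a guaranteed incorporation, so a few optimizer steps suffice
small_training_problem <- function(n = 120, seed = 5) {
  pm <- flat_pore_model(sd_pA = 1.5)
  cfg <- sim_config(delta_mean_pA = 10, dwell_mean = 8, seed = seed)
  set.seed(seed)
  chroms <- c("chr1", "chr20", "chr2", "chr3")
  mk <- function(i, labeled) {
    seqc <- random_rna(60)
    upos <- which(strsplit(seqc, "")[[1]] == "U")
    ip <- if (labeled && length(upos)) {
      upos[sample.int(length(upos), min(3L, length(upos)))]
    } else {
      integer(0)
    }
    r <- simulate_read(seqc, ip, pm, cfg,
                       read_id = sprintf("%s%04d",
                                         if (labeled) "p" else "n", i))
    r$meta$chromosome <- sample(chroms, 1, prob = c(0.2, 0.15, 0.35, 0.3))
    r
  }
  pos <- lapply(seq_len(n / 2), mk, labeled = TRUE)
  neg <- lapply(seq_len(n / 2), mk, labeled = FALSE)
  all <- c(pos, neg)
  tab <- data.frame(
    read_id = vapply(all, `[[`, character(1), "read_id"),
    chromosome = vapply(all, function(r) r$meta$chromosome, character(1))
  )
  list(pool = dataset_pool(list(pos), list(neg)),
       splits = assign_splits(tab))
}

test_that("one optimizer step happens per accumulation window", {
  prob <- small_training_problem()
  tcfg <- train_config(accumulate = 64L, warmup_steps = 10L,
                       max_epochs = 1L, epoch_size = 130L,
                       eval_every = 1L, seed = 2L)
  ck <- train_classifier(prob$pool, prob$splits,
                         tiny_classifier_config(), tcfg, sim_preprocess())
  # floor(130 / 64) = 2 optimizer steps, each followed by an evaluation
  expect_equal(max(ck$log$step), 2)
  expect_equal(nrow(ck$log), 2)
})

test_that("training never leaks held-out reads into gradients and keeps the best state", {
  prob <- small_training_problem(n = 160, seed = 6)
  tcfg <- train_config(accumulate = 16L, warmup_steps = 5L,
                       max_epochs = 30L, epoch_size = 80L, eval_every = 2L,
                       early_stop_patience = 4L, seed = 3L)
  ck <- train_classifier(prob$pool, prob$splits,
                         tiny_classifier_config(), tcfg, sim_preprocess())
  held_out <- prob$splits$read_id[prob$splits$split %in%
                                    c("test", "validation")]
  expect_length(intersect(ck$consumed_read_ids, held_out), 0)
  expect_gt(length(ck$consumed_read_ids), 0)
  # early stopping: the returned state is never worse than any evaluation
  expect_equal(ck$best_val_auroc, max(ck$log$val_auroc))
  # patience 4 with eval every 2 steps: must have stopped well before the cap
  max_steps <- with(ck$log, max(step))
  expect_lt(max_steps, 30 * 80 / 16)
  expect_equal(ck$training_meta$best_val_auroc, ck$best_val_auroc)
})

test_that("training is reproducible under fixed seeds", {
  prob <- small_training_problem(n = 80, seed = 9)
  tcfg <- train_config(accumulate = 8L, warmup_steps = 5L, max_epochs = 2L,
                       epoch_size = 24L, eval_every = 3L, seed = 4L)
  ck1 <- train_classifier(prob$pool, prob$splits,
                          tiny_classifier_config(), tcfg, sim_preprocess())
  ck2 <- train_classifier(prob$pool, prob$splits,
                          tiny_classifier_config(), tcfg, sim_preprocess())
  expect_equal(ck1$log$loss, ck2$log$loss)
  expect_equal(ck1$model$params, ck2$model$params)
})

test_that("degenerate pools and single-class validation are rejected", {
  mk <- function(prefix, n, chrom) lapply(seq_len(n), function(i) {
    r <- make_read(paste0(prefix, i), 100)
    r$meta$chromosome <- chrom
    r
  })
  expect_error(dataset_pool(list(), list(mk("n", 3, "chr2"))), "positive")
  pos <- mk("p", 6, "chr2")
  neg <- mk("n", 6, "chr2")  # no validation reads at all
  tab <- data.frame(read_id = c(paste0("p", 1:6), paste0("n", 1:6)),
                    chromosome = "chr2")
  expect_error(
    train_classifier(dataset_pool(list(pos), list(neg)), assign_splits(tab),
                     tiny_classifier_config(),
                     train_config(max_epochs = 1L),
                     sim_preprocess()),
    "validation"
  )
})
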