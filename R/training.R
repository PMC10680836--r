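#' Chromosome-holdout split rule
#'
#' Reads mapping to a test chromosome go to the test set, reads mapping to
#' a validation chromosome to the validation set (used for early stopping),
#' every other mapped primary read to training; unmapped and secondary
#' reads are excluded. Splitting by chromosome rather than by random
#' shuffling prevents leakage of transcript-level signal between splits.
#'
#' @param test_chromosomes,validation_chromosomes character vectors of
#'   chromosome names.
#' @return a `split_rule` object.
#' @export
split_rule <- function(test_chromosomes = "chr1",
                       validation_chromosomes = "chr20") {
  if (length(intersect(test_chromosomes, validation_chromosomes))) {
    stop("test and validation chromosomes must be disjoint")
  }
  structure(list(test_chromosomes = test_chromosomes,
                 validation_chromosomes = validation_chromosomes),
            class = "split_rule")
}

#' Assign reads to train/validation/test splits by chromosome
#'
#' @param read_table data frame with columns `read_id`, `chromosome`
#'   (`"unmapped"` for unaligned reads) and optionally `is_secondary`
#'   (logical, defaults to all-primary).
#' @param rule a [split_rule].
#' @return data frame `read_id`, `split` with `split` one of `"train"`,
#'   `"validation"`, `"test"`, `"excluded"`.
#' @export
assign_splits <- function(read_table, rule = split_rule()) {
  stopifnot(is.data.frame(read_table),
            all(c("read_id", "chromosome") %in% names(read_table)))
  if (anyDuplicated(read_table$read_id)) {
    stop("duplicate read_id in read table: ",
         read_table$read_id[duplicated(read_table$read_id)][1])
  }
  sec <- if ("is_secondary" %in% names(read_table)) {
    as.logical(read_table$is_secondary)
  } else {
    rep(FALSE, nrow(read_table))
  }
  chrom <- as.character(read_table$chromosome)
  split <- ifelse(
    sec | chrom == "unmapped" | is.na(chrom), "excluded",
    ifelse(chrom %in% rule$test_chromosomes, "test",
           ifelse(chrom %in% rule$validation_chromosomes, "validation",
                  "train"))
  )
  data.frame(read_id = read_table$read_id, split = split,
             stringsAsFactors = FALSE)
}

#' Positive/negative dataset pool
#'
#' Positives are one or more sources of labeled reads; negatives may come
#' from several independent unlabeled experiments, and during sampling a
#' negative source is chosen proportionally to the number of reads it
#' contains.
#'
#' @param positives list of positive sources, each a list of [signal_read].
#' @param negatives list of negative sources, likewise.
#' @return a `dataset_pool` object.
#' @export
dataset_pool <- function(positives, negatives) {
  if (!is.list(positives) || !length(positives) ||
      !all(vapply(positives, length, integer(1)) > 0)) {
    stop("at least one non-empty positive source is required")
  }
  if (!is.list(negatives) || !length(negatives) ||
      !all(vapply(negatives, length, integer(1)) > 0)) {
    stop("at least one non-empty negative source is required")
  }
  structure(list(positives = positives, negatives = negatives),
            class = "dataset_pool")
}

#' Balanced proportional sampler
#'
#' Infinite read stream with marginal class probability 1/2 for each of
#' positive and negative; within a class, a source is selected with
#' probability proportional to its read count, then a read uniformly within
#' the source. Deterministic under `seed`.
#'
#' @param pool a [dataset_pool].
#' @param seed integer seed for the sampler's private RNG stream.
#' @return a function of no arguments; each call returns
#'   `list(read =, label =, read_id =, class =, source =)` with `label` 1
#'   for positive, 0 for negative.
#' @export
balanced_sampler <- function(pool, seed = 1L) {
  stopifnot(inherits(pool, "dataset_pool"))
  n_pos <- vapply(pool$positives, length, integer(1))
  n_neg <- vapply(pool$negatives, length, integer(1))
  rng <- new.env(parent = emptyenv())
  local({
    old <- .save_rng()
    set.seed(seed)
    rng$state <- .save_rng()
    .restore_rng(old)
  })
  function() {
    old <- .save_rng()
    .restore_rng(rng$state)
    positive <- runif(1) < 0.5
    sources <- if (positive) pool$positives else pool$negatives
    ns <- if (positive) n_pos else n_neg
    s <- if (length(sources) == 1L) 1L else {
      sample.int(length(sources), 1L, prob = ns / sum(ns))
    }
    i <- sample.int(ns[s], 1L)
    rng$state <- .save_rng()
    .restore_rng(old)
    read <- sources[[s]][[i]]
    list(read = read, label = as.integer(positive), read_id = read$read_id,
         class = if (positive) "positive" else "negative", source = s)
  }
}

#' Training configuration
#'
#' Defaults follow the reference optimization recipe: AdamW with learning
#' rate 0.001 and weight decay 0.01, batch size 1 with gradients
#' accumulated (averaged) over 64 sequences per optimizer step, a 1000-step
#' linear learning-rate warmup from 0, up to 1000 epochs, and early
#' stopping on validation AUROC with improvement threshold 0 and patience
#' of 50 evaluations.
#'
#' @param lr peak learning rate.
#' @param weight_decay decoupled (AdamW) weight decay.
#' @param accumulate sequences per optimizer step.
#' @param warmup_steps optimizer steps over which the learning rate rises
#'   linearly from 0 to `lr`.
#' @param max_epochs maximum epochs.
#' @param epoch_size sampler draws per epoch; `NULL` means the total size
#'   of the positive pool.
#' @param eval_every optimizer steps between validation evaluations.
#' @param early_stop_metric only `"val_auroc"` is implemented.
#' @param early_stop_min_delta minimum AUROC improvement that resets
#'   patience.
#' @param early_stop_patience evaluations without improvement before
#'   stopping.
#' @param bn_momentum batch-norm running-statistics momentum.
#' @param seed seed controlling initialization and sampling.
#' @return a `train_config` object.
#' @export
train_config <- function(lr = 0.001, weight_decay = 0.01, accumulate = 64L,
                         warmup_steps = 1000L, max_epochs = 1000L,
                         epoch_size = NULL, eval_every = 200L,
                         early_stop_metric = "val_auroc",
                         early_stop_min_delta = 0,
                         early_stop_patience = 50L, bn_momentum = 0.1,
                         seed = 1L) {
  stopifnot(lr > 0, weight_decay >= 0, accumulate >= 1L, warmup_steps >= 0L,
            max_epochs >= 1L, eval_every >= 1L, early_stop_min_delta >= 0,
            early_stop_patience >= 1L, bn_momentum > 0, bn_momentum <= 1,
            identical(early_stop_metric, "val_auroc"))
  structure(
    list(lr = lr, weight_decay = weight_decay, batch_size = 1L,
         accumulate = as.integer(accumulate),
         warmup_steps = as.integer(warmup_steps),
         max_epochs = as.integer(max_epochs),
         epoch_size = if (is.null(epoch_size)) NULL else as.integer(epoch_size),
         eval_every = as.integer(eval_every),
         early_stop_metric = early_stop_metric,
         early_stop_min_delta = early_stop_min_delta,
         early_stop_patience = as.integer(early_stop_patience),
         bn_momentum = bn_momentum, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Learning rate at an optimizer step
#'
#' Linear warmup from 0 to `cfg$lr` over the first `cfg$warmup_steps`
#' optimizer steps, constant afterwards: `lr * min(1, step / warmup_steps)`.
#'
#' @param step optimizer-step index (0 = before any update).
#' @param cfg a [train_config].
#' @return learning rate.
#' @export
lr_at_step <- function(step, cfg) {
  stopifnot(all(step >= 0))
  if (cfg$warmup_steps == 0L) return(rep(cfg$lr, length(step)))
  cfg$lr * pmin(1, step / cfg$warmup_steps)
}

# one AdamW update on a flat parameter vector (decoupled weight decay)
.adamw_step <- function(theta, grad, state, lr, weight_decay,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * theta)
  list(theta = theta, state = state)
}

.flatten_params <- function(params) {
  unlist(lapply(params, as.numeric), use.names = FALSE)
}

.unflatten_params <- function(theta, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    v <- theta[(pos + 1L):(pos + n)]
    out[[nm]] <- if (is.matrix(template[[nm]])) {
      matrix(v, nrow(template[[nm]]), ncol(template[[nm]]))
    } else {
      v
    }
    pos <- pos + n
  }
  out
}

#' Train the classifier
#'
#' Full optimization loop: balanced proportional sampling from the training
#' split only, per-sequence binary cross-entropy on the sigmoid output,
#' gradient accumulation (averaged over the window) with one AdamW step per
#' `accumulate` sequences, linear warmup, periodic validation AUROC, and
#' early stopping returning the best-validation state. Reads are
#' preprocessed (filtered, cropped, med-MAD normalized) once up front;
#' reads removed by preprocessing are dropped from the pool. Only reads
#' whose split is `"train"` ever contribute a gradient; the returned
#' `consumed_read_ids` records every gradient contributor so leakage can be
#' audited.
#'
#' @param pool a [dataset_pool] of raw reads.
#' @param split data frame from [assign_splits()] covering the pool's read
#'   ids; reads absent from the table are excluded.
#' @param model_cfg a [classifier_config].
#' @param cfg a [train_config].
#' @param preprocess a [preprocess_config] applied to every read.
#' @param verbose print progress lines.
#' @return an `eukinet_checkpoint`-style list with fields `model` (best
#'   validation state), `training_meta`, `log` (data frame of `step`, `lr`,
#'   `loss`, `val_auroc`), `consumed_read_ids`, and `best_val_auroc`.
#' @export
train_classifier <- function(pool, split, model_cfg = classifier_config(),
                             cfg = train_config(),
                             preprocess = preprocess_config(),
                             verbose = FALSE) {
  stopifnot(inherits(pool, "dataset_pool"), inherits(cfg, "train_config"))
  split_of <- setNames(split$split, split$read_id)
  lmin <- min_input_length(model_cfg)

  prep_source <- function(src, keep_split) {
    out <- list()
    for (r in src) {
      sp <- split_of[[r$read_id]]
      if (is.null(sp) || is.na(sp) || sp != keep_split) next
      n <- length(r$signal)
      if (n <= preprocess$min_raw_length || n > preprocess$max_raw_length) next
      x <- r$signal
      if (preprocess$crop_head > 0L) x <- x[-seq_len(preprocess$crop_head)]
      if (length(x) < max(lmin, 2L)) next
      med <- median(x)
      mad0 <- median(abs(x - med))
      if (mad0 == 0) next
      r$signal <- (x - med) / mad0
      out[[length(out) + 1L]] <- r
    }
    out
  }

  train_pos <- Filter(length, lapply(pool$positives, prep_source, "train"))
  train_neg <- Filter(length, lapply(pool$negatives, prep_source, "train"))
  if (!length(train_pos) || !length(train_neg)) {
    stop("training split is empty for one of the classes after preprocessing")
  }
  val_pos <- unlist(lapply(pool$positives, prep_source, "validation"),
                    recursive = FALSE)
  val_neg <- unlist(lapply(pool$negatives, prep_source, "validation"),
                    recursive = FALSE)
  if (!length(val_pos) || !length(val_neg)) {
    stop("validation AUROC undefined: validation split lacks a class")
  }

  train_pool <- dataset_pool(train_pos, train_neg)
  draw <- balanced_sampler(train_pool, seed = cfg$seed)
  epoch_size <- cfg$epoch_size %||%
    sum(vapply(train_pos, length, integer(1)))

  model <- build_model(model_cfg, seed = cfg$seed)
  cpp_cfg <- .cfg_for_cpp(model_cfg)
  theta <- .flatten_params(model$params)
  opt <- list(t = 0L, m = numeric(length(theta)), v = numeric(length(theta)))

  val_auroc <- function(params, bn_run) {
    m <- model
    m$params <- params
    m$bn_run <- bn_run
    scores <- c(
      vapply(val_pos, function(r) .predict_signal(m, r$signal), numeric(1)),
      vapply(val_neg, function(r) .predict_signal(m, r$signal), numeric(1))
    )
    truth <- c(rep(1L, length(val_pos)), rep(0L, length(val_neg)))
    roc_auc(scored_set(scores, truth))
  }

  grad_acc <- NULL
  n_acc <- 0L
  step <- 0L
  window_losses <- numeric(0)
  log_rows <- list()
  consumed <- new.env(parent = emptyenv())
  best <- list(auroc = -Inf, params = model$params, bn_run = model$bn_run,
               step = 0L, epoch = 0L)
  since_best <- 0L
  stopped <- FALSE

  for (epoch in seq_len(cfg$max_epochs)) {
    for (d in seq_len(epoch_size)) {
      ex <- draw()
      consumed[[ex$read_id]] <- TRUE
      res <- .nn_grad_cpp(ex$read$signal, ex$label, model$params, cpp_cfg,
                          model$bn_run, cfg$bn_momentum)
      model$bn_run <- res$bn_run
      g <- .flatten_params(res$grads[names(model$params)])
      grad_acc <- if (is.null(grad_acc)) g else grad_acc + g
      n_acc <- n_acc + 1L
      window_losses <- c(window_losses, res$loss)
      if (n_acc == cfg$accumulate) {
        step <- step + 1L
        lr <- lr_at_step(step, cfg)
        upd <- .adamw_step(theta, grad_acc / n_acc, opt, lr, cfg$weight_decay)
        theta <- upd$theta
        opt <- upd$state
        model$params <- .unflatten_params(theta, model$params)
        grad_acc <- NULL
        n_acc <- 0L
        if (step %% cfg$eval_every == 0L) {
          auc <- val_auroc(model$params, model$bn_run)
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            step = step, epoch = epoch, lr = lr,
            loss = mean(window_losses), val_auroc = auc
          )
          window_losses <- numeric(0)
          if (verbose) {
            message(sprintf("epoch %d step %d lr %.2e loss %.4f val AUROC %.4f",
                            epoch, step, lr,
                            log_rows[[length(log_rows)]]$loss, auc))
          }
          if (auc > best$auroc + cfg$early_stop_min_delta) {
            best <- list(auroc = auc, params = model$params,
                         bn_run = model$bn_run, step = step, epoch = epoch)
            since_best <- 0L
          } else {
            since_best <- since_best + 1L
            if (since_best >= cfg$early_stop_patience) {
              stopped <- TRUE
              break
            }
          }
        }
      }
    }
    if (stopped) break
  }

  # ensure at least one evaluation happened (short runs)
  if (is.infinite(best$auroc)) {
    auc <- val_auroc(model$params, model$bn_run)
    best <- list(auroc = auc, params = model$params, bn_run = model$bn_run,
                 step = step, epoch = min(cfg$max_epochs, 1L))
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      step = step, epoch = best$epoch, lr = lr_at_step(step, cfg),
      loss = if (length(window_losses)) mean(window_losses) else NA_real_,
      val_auroc = auc
    )
  }

  model$params <- best$params
  model$bn_run <- best$bn_run
  structure(
    list(
      model = model,
      training_meta = list(epoch = best$epoch, step = best$step,
                           best_val_auroc = best$auroc, seed = cfg$seed),
      log = do.call(rbind, log_rows),
      consumed_read_ids = ls(consumed),
      best_val_auroc = best$auroc
    ),
    class = "eukinet_checkpoint"
  )
}
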