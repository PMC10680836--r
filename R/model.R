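#' Classifier architecture configuration
#'
#' The reference configuration — three 1-D convolution blocks (channels
#' 1 -> 16 -> 32 -> 64, kernel 5, stride 3, batch norm, ReLU), a
#' bidirectional GRU with 48 hidden units over the conv feature sequence,
#' and a dense head 288 -> 70 -> 1 fed by the concatenation of max-pool,
#' mean-pool and the two final GRU hidden states — totals 66,349 trainable
#' parameters (66,061 under the one-bias GRU convention), i.e. ~66k. The
#' network accepts a single normalized signal of any length at or above
#' [min_input_length()] with no padding anywhere.
#'
#' @param conv_channels integer vector of conv output channels.
#' @param kernel_size,stride convolution kernel width and stride (shared by
#'   all blocks; no padding).
#' @param use_batch_norm add a batch-norm layer after each convolution.
#' @param gru_hidden GRU hidden size per direction.
#' @param gru_bidirectional run the GRU in both directions.
#' @param head_hidden hidden width of the dense head.
#' @param activation activation name (only `"relu"` is implemented).
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(conv_channels = c(16L, 32L, 64L),
                              kernel_size = 5L, stride = 3L,
                              use_batch_norm = TRUE,
                              gru_hidden = 48L, gru_bidirectional = TRUE,
                              head_hidden = 70L, activation = "relu") {
  conv_channels <- as.integer(conv_channels)
  stopifnot(length(conv_channels) >= 1L, all(conv_channels >= 1L),
            kernel_size >= 1L, stride >= 1L, gru_hidden >= 1L,
            head_hidden >= 1L, identical(tolower(activation), "relu"))
  structure(
    list(conv_channels = conv_channels,
         kernel_size = as.integer(kernel_size), stride = as.integer(stride),
         use_batch_norm = isTRUE(use_batch_norm),
         gru_hidden = as.integer(gru_hidden),
         gru_bidirectional = isTRUE(gru_bidirectional),
         head_hidden = as.integer(head_hidden), activation = "relu"),
    class = "classifier_config"
  )
}

#' Minimum accepted input length
#'
#' Smallest signal length for which every convolution layer still emits at
#' least one feature (53 samples for the reference kernel-5 stride-3
#' three-layer stack).
#'
#' @param cfg a [classifier_config].
#' @return integer number of samples.
#' @export
min_input_length <- function(cfg) {
  l <- 1L
  for (i in seq_along(cfg$conv_channels)) {
    l <- (l - 1L) * cfg$stride + cfg$kernel_size
  }
  l
}

# dimension of the pooled feature vector fed to the dense head
.head_input_dim <- function(cfg) {
  d <- cfg$gru_hidden * (if (cfg$gru_bidirectional) 2L else 1L)
  # max-pool + mean-pool over the GRU output sequence, plus the final
  # hidden state of each direction
  2L * d + cfg$gru_hidden * (if (cfg$gru_bidirectional) 2L else 1L)
}

# expected shape of every parameter tensor, in a fixed order
.param_shapes <- function(cfg) {
  shapes <- list()
  c_in <- 1L
  for (i in seq_along(cfg$conv_channels)) {
    c_out <- cfg$conv_channels[i]
    shapes[[paste0("conv", i, "_W")]] <- c(c_out, c_in * cfg$kernel_size)
    shapes[[paste0("conv", i, "_b")]] <- c_out
    if (cfg$use_batch_norm) {
      shapes[[paste0("bn", i, "_gamma")]] <- c_out
      shapes[[paste0("bn", i, "_beta")]] <- c_out
    }
    c_in <- c_out
  }
  h <- cfg$gru_hidden
  dirs <- if (cfg$gru_bidirectional) c("fwd", "bwd") else "fwd"
  for (d in dirs) {
    shapes[[paste0("gru_", d, "_Wi")]] <- c(3L * h, c_in)
    shapes[[paste0("gru_", d, "_Wh")]] <- c(3L * h, h)
    shapes[[paste0("gru_", d, "_bi")]] <- 3L * h
    shapes[[paste0("gru_", d, "_bh")]] <- 3L * h
  }
  shapes[["fc1_W"]] <- c(cfg$head_hidden, .head_input_dim(cfg))
  shapes[["fc1_b"]] <- cfg$head_hidden
  shapes[["fc2_W"]] <- c(1L, cfg$head_hidden)
  shapes[["fc2_b"]] <- 1L
  shapes
}

#' Build a classifier with deterministic initialization
#'
#' Weights are initialized uniformly in `(-1/sqrt(fan_in), 1/sqrt(fan_in))`
#' (GRU tensors use `fan_in = gru_hidden`), batch-norm scale/shift start at
#' 1/0 and running statistics at 0/1. The same seed always yields
#' bit-identical parameters.
#'
#' @param cfg a [classifier_config].
#' @param seed integer RNG seed for the initialization.
#' @return an object of class `eukinet_model` with fields `config`,
#'   `params`, `bn_run` and `meta`.
#' @export
build_model <- function(cfg = classifier_config(), seed = 1L) {
  stopifnot(inherits(cfg, "classifier_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  shapes <- .param_shapes(cfg)
  params <- list()
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    if (grepl("^bn", nm)) {
      params[[nm]] <- if (grepl("_gamma$", nm)) rep(1, sh) else rep(0, sh)
      next
    }
    bound <- if (grepl("^gru", nm)) {
      1 / sqrt(cfg$gru_hidden)
    } else if (length(sh) == 2L) {
      1 / sqrt(sh[2])
    } else {
      # bias: use the matching weight fan-in
      wnm <- sub("_b$", "_W", nm)
      1 / sqrt(shapes[[wnm]][2])
    }
    vals <- runif(prod(sh), -bound, bound)
    params[[nm]] <- if (length(sh) == 2L) matrix(vals, sh[1], sh[2]) else vals
  }
  bn_run <- list()
  if (cfg$use_batch_norm) {
    for (i in seq_along(cfg$conv_channels)) {
      bn_run[[paste0("bn", i, "_mean")]] <- rep(0, cfg$conv_channels[i])
      bn_run[[paste0("bn", i, "_var")]] <- rep(1, cfg$conv_channels[i])
    }
  }
  structure(
    list(config = cfg, params = params, bn_run = bn_run,
         meta = list(seed = as.integer(seed))),
    class = "eukinet_model"
  )
}

#' @export
print.eukinet_model <- function(x, ...) {
  cat(sprintf(
    "<eukinet_model: conv [%s] k=%d s=%d, %sGRU h=%d, head %d; %s params>\n",
    paste(x$config$conv_channels, collapse = ","), x$config$kernel_size,
    x$config$stride, if (x$config$gru_bidirectional) "bi-" else "",
    x$config$gru_hidden, x$config$head_hidden,
    format(count_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model an `eukinet_model`.
#' @param gru_bias `"two"` counts separate input-side and hidden-side GRU
#'   bias vectors (as stored); `"one"` reports the count under the merged
#'   single-bias convention.
#' @return integer total of trainable scalars.
#' @export
count_parameters <- function(model, gru_bias = c("two", "one")) {
  gru_bias <- match.arg(gru_bias)
  n <- sum(vapply(model$params, length, integer(1)))
  if (gru_bias == "one") {
    bh <- grep("^gru_.*_bh$", names(model$params), value = TRUE)
    n <- n - sum(vapply(model$params[bh], length, integer(1)))
  }
  as.integer(n)
}

# cfg in the plain-list form the C++ routines consume
.cfg_for_cpp <- function(cfg) {
  list(conv_channels = as.integer(cfg$conv_channels),
       kernel_size = as.integer(cfg$kernel_size),
       stride = as.integer(cfg$stride),
       use_batch_norm = cfg$use_batch_norm,
       gru_bidirectional = cfg$gru_bidirectional)
}

# forward pass on one normalized signal, eval mode
.predict_signal <- function(model, x) {
  .nn_predict_cpp(as.numeric(x), model$params, .cfg_for_cpp(model$config),
                  model$bn_run)
}

#' Predict modification status for raw reads
#'
#' Applies the standard preprocessing internally (length filters, head
#' crop, med-MAD normalization) and runs the classifier on each surviving
#' read; reads removed by the filters, too short for the network, or with
#' degenerate (zero-MAD) signal are reported in a `skipped` table with
#' reasons rather than silently dropped. Containers given as file paths are
#' loaded one at a time so memory does not grow with the number of reads.
#'
#' @param model an `eukinet_model` (or a checkpoint loaded with
#'   [load_checkpoint()]).
#' @param reads list of [signal_read] objects, or a character vector of
#'   container paths.
#' @param preprocess a [preprocess_config]; applied before inference.
#' @param threshold call threshold: `probability >= threshold` is called
#'   `"modified"`.
#' @param format container format when `reads` is a path vector.
#' @return list with `predictions` (data frame `read_id`, `probability`,
#'   `call`, in input order of the survivors) and `skipped` (data frame
#'   `read_id`, `reason`).
#' @export
predict_reads <- function(model, reads, preprocess = preprocess_config(),
                          threshold = 0.5, format = "fixture") {
  if (inherits(model, "eukinet_checkpoint")) model <- model$model
  stopifnot(inherits(model, "eukinet_model"),
            threshold >= 0, threshold <= 1)
  if (is.character(reads)) {
    out <- lapply(reads, function(p) {
      predict_reads(model, load_reads(p, format), preprocess, threshold)
    })
    return(list(
      predictions = do.call(rbind, lapply(out, `[[`, "predictions")),
      skipped = do.call(rbind, lapply(out, `[[`, "skipped"))
    ))
  }
  lmin <- min_input_length(model$config)
  ids <- character(0); probs <- numeric(0)
  sk_id <- character(0); sk_reason <- character(0)
  for (r in reads) {
    n <- length(r$signal)
    reason <- NULL
    if (n <= preprocess$min_raw_length) {
      reason <- "too_short"
    } else if (n > preprocess$max_raw_length) {
      reason <- "too_long"
    } else {
      x <- r$signal
      if (preprocess$crop_head > 0L) x <- x[-seq_len(preprocess$crop_head)]
      if (length(x) < max(lmin, 2L)) {
        reason <- "too_short_after_crop"
      } else {
        med <- median(x)
        mad0 <- median(abs(x - med))
        if (mad0 == 0) {
          reason <- "degenerate_mad"
        } else {
          ids <- c(ids, r$read_id)
          probs <- c(probs, .predict_signal(model, (x - med) / mad0))
        }
      }
    }
    if (!is.null(reason)) {
      sk_id <- c(sk_id, r$read_id)
      sk_reason <- c(sk_reason, reason)
    }
  }
  list(
    predictions = data.frame(
      read_id = ids, probability = probs,
      call = ifelse(probs >= threshold, "modified", "unmodified"),
      stringsAsFactors = FALSE
    ),
    skipped = data.frame(read_id = sk_id, reason = sk_reason,
                         stringsAsFactors = FALSE)
  )
}

.CHECKPOINT_VERSION <- 1L

.config_canonical <- function(cfg) {
  paste(
    paste(cfg$conv_channels, collapse = ","), cfg$kernel_size, cfg$stride,
    as.integer(cfg$use_batch_norm), cfg$gru_hidden,
    as.integer(cfg$gru_bidirectional), cfg$head_hidden, cfg$activation,
    sep = "|"
  )
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single JSON file holding the architecture
#' configuration, all weights and batch-norm running statistics at full
#' double precision, training metadata, and a root-level format version.
#' Loading verifies the format version, the stored configuration string and
#' every tensor shape; reloaded models reproduce probabilities to within
#' 1e-6 of the saved model.
#'
#' @param model an `eukinet_model`.
#' @param path checkpoint file path.
#' @param training_meta optional list, e.g. `list(epoch =, best_val_auroc =,
#'   seed =)`, recorded verbatim.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns an object of class `eukinet_checkpoint` with fields `model`
#'   and `training_meta`.
#' @export
save_checkpoint <- function(model, path, training_meta = list()) {
  stopifnot(inherits(model, "eukinet_model"))
  obj <- list(
    format_version = .CHECKPOINT_VERSION,
    config = unclass(model$config),
    config_canonical = .config_canonical(model$config),
    weights = lapply(model$params, function(p)
      list(dim = if (is.matrix(p)) dim(p) else length(p),
           data = as.numeric(p))),
    bn_run = model$bn_run,
    training_meta = training_meta
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) ||
      obj$format_version != .CHECKPOINT_VERSION) {
    stop("incompatible checkpoint format version: ",
         obj$format_version %||% "<missing>", " (expected ",
         .CHECKPOINT_VERSION, ")")
  }
  cfg <- classifier_config(
    conv_channels = obj$config$conv_channels,
    kernel_size = obj$config$kernel_size, stride = obj$config$stride,
    use_batch_norm = obj$config$use_batch_norm,
    gru_hidden = obj$config$gru_hidden,
    gru_bidirectional = obj$config$gru_bidirectional,
    head_hidden = obj$config$head_hidden, activation = obj$config$activation
  )
  if (!identical(.config_canonical(cfg), obj$config_canonical)) {
    stop("checkpoint config does not match its recorded canonical form; ",
         "file is corrupt or was edited")
  }
  shapes <- .param_shapes(cfg)
  if (!setequal(names(shapes), names(obj$weights))) {
    stop("checkpoint weights do not match the configured architecture")
  }
  params <- list()
  for (nm in names(shapes)) {
    w <- obj$weights[[nm]]
    sh <- shapes[[nm]]
    if (!identical(as.integer(unlist(w$dim)), as.integer(sh))) {
      stop("checkpoint tensor '", nm, "' has shape [",
           paste(unlist(w$dim), collapse = "x"), "], expected [",
           paste(sh, collapse = "x"), "]")
    }
    params[[nm]] <- if (length(sh) == 2L) {
      matrix(as.numeric(w$data), sh[1], sh[2])
    } else {
      as.numeric(w$data)
    }
  }
  bn_run <- lapply(obj$bn_run, as.numeric)
  model <- structure(
    list(config = cfg, params = params, bn_run = bn_run,
         meta = list(seed = NA_integer_)),
    class = "eukinet_model"
  )
  structure(list(model = model, training_meta = obj$training_meta),
            class = "eukinet_checkpoint")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
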