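#' Build a deterministic synthetic pore model
#'
#' A pore model maps every k-mer over `{A,C,G,U}` to the mean and standard
#' deviation of the current it produces while occupying the pore. The
#' synthetic table draws means uniformly in a plausible 60-130 pA band and
#' standard deviations in 1-4 pA; it stands in for the physical pore
#' response that a classifier learns from, and is deterministic under
#' `seed`.
#'
#' @param seed integer RNG seed.
#' @param k k-mer length (default 5).
#' @return an object of class `pore_model` with fields `k`, `kmers`,
#'   `mean_pA` and `sd_pA` (the latter two named by k-mer).
#' @export
make_default_pore_model <- function(seed = 1L, k = 5L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  bases <- c("A", "C", "G", "U")
  grid <- do.call(expand.grid, c(rep(list(bases), k),
                                 stringsAsFactors = FALSE))
  # column 1 varies fastest; paste in reverse so kmers sort lexicographically
  kmers <- do.call(paste0, rev(grid))
  kmers <- sort(kmers)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  mean_pA <- setNames(runif(length(kmers), 60, 130), kmers)
  sd_pA <- setNames(runif(length(kmers), 1, 4), kmers)
  structure(list(k = k, kmers = kmers, mean_pA = mean_pA, sd_pA = sd_pA),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("<pore_model: k=%d, %d k-mers, means %.1f-%.1f pA>\n",
              x$k, length(x$kmers), min(x$mean_pA), max(x$mean_pA)))
  invisible(x)
}

#' Write / read a pore model as TSV
#'
#' @param pore a `pore_model`.
#' @param path TSV file with columns `kmer`, `mean_pA`, `sd_pA`.
#' @return `write_pore_model` the path invisibly; `read_pore_model` a
#'   `pore_model`.
#' @export
write_pore_model <- function(pore, path) {
  df <- data.frame(kmer = pore$kmers, mean_pA = unname(pore$mean_pA),
                   sd_pA = unname(pore$sd_pA))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pore_model
#' @export
read_pore_model <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("kmer", "mean_pA", "sd_pA") %in% names(df)))
  k <- nchar(df$kmer[1])
  structure(list(k = k, kmers = df$kmer,
                 mean_pA = setNames(df$mean_pA, df$kmer),
                 sd_pA = setNames(df$sd_pA, df$kmer)),
            class = "pore_model")
}

# save/restore the global RNG state so constructors with a `seed` argument
# do not perturb the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulation configuration
#'
#' Defines the study conditions for synthetic squiggle generation. Defaults
#' emulate a direct-RNA experiment with sparse 5EU incorporation: 2.5% of U
#' positions incorporate the analog in a labeled molecule, each
#' incorporation shifts the mean current of every overlapping k-mer by
#' `delta_mean_pA`, and dwell per k-mer is geometric with mean `dwell_mean`
#' samples.
#'
#' @param n_reads total reads to simulate.
#' @param labeled_fraction probability a read is labeled (ignored in
#'   kinetics mode).
#' @param p_incorporation per-U incorporation probability in labeled reads.
#' @param delta_mean_pA current shift (pA) added to k-mers overlapping an
#'   incorporated 5EU.
#' @param dwell_mean mean samples per k-mer (geometric dwell).
#' @param dwell_dispersion reserved for a negative-binomial dwell
#'   extension; must be `NULL`.
#' @param noise_sd_scale multiplier on the pore-model standard deviations.
#' @param read_length_range integer `(min_nt, max_nt)`; transcript (and
#'   hence read) lengths are drawn uniformly in this range.
#' @param chromosomes data frame with columns `name`, `weight` giving
#'   chromosome assignment probabilities.
#' @param transcripts_per_chromosome transcripts simulated per chromosome.
#' @param half_life_range_h kinetics mode: log-uniform range (hours) for
#'   true transcript half-lives.
#' @param label_time_h kinetics mode: 5EU pulse duration in hours.
#' @param kinetics_mode if `TRUE`, per-read label probability follows
#'   first-order turnover, `f_new = 1 - 2^(-label_time_h / t_half)`.
#' @param reads_per_transcript kinetics mode only: exact reads per
#'   transcript (overrides `n_reads`).
#' @param seed integer seed; a fixed seed makes the output bit-identical.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_reads = 2000L,
                       labeled_fraction = 0.5,
                       p_incorporation = 0.025,
                       delta_mean_pA = 5,
                       dwell_mean = 30,
                       dwell_dispersion = NULL,
                       noise_sd_scale = 1,
                       read_length_range = c(200L, 2000L),
                       chromosomes = data.frame(
                         name = c("chr1", "chr2", "chr3", "chr4", "chr5",
                                  "chr20"),
                         weight = c(0.2, 0.2, 0.2, 0.15, 0.15, 0.1)
                       ),
                       transcripts_per_chromosome = 20L,
                       half_life_range_h = c(0.5, 24),
                       label_time_h = 2,
                       kinetics_mode = FALSE,
                       reads_per_transcript = NULL,
                       seed = 1L) {
  stopifnot(
    n_reads >= 0,
    labeled_fraction >= 0, labeled_fraction <= 1,
    p_incorporation >= 0, p_incorporation <= 1,
    dwell_mean >= 1, is.null(dwell_dispersion),
    noise_sd_scale >= 0,
    length(read_length_range) == 2L,
    read_length_range[1] >= 1, read_length_range[1] <= read_length_range[2],
    is.data.frame(chromosomes), nrow(chromosomes) >= 1L,
    all(c("name", "weight") %in% names(chromosomes)),
    all(chromosomes$weight > 0),
    transcripts_per_chromosome >= 1L,
    length(half_life_range_h) == 2L, half_life_range_h[1] > 0,
    half_life_range_h[1] <= half_life_range_h[2],
    label_time_h > 0
  )
  structure(
    list(n_reads = as.integer(n_reads), labeled_fraction = labeled_fraction,
         p_incorporation = p_incorporation, delta_mean_pA = delta_mean_pA,
         dwell_mean = dwell_mean, dwell_dispersion = dwell_dispersion,
         noise_sd_scale = noise_sd_scale,
         read_length_range = as.integer(read_length_range),
         chromosomes = chromosomes,
         transcripts_per_chromosome = as.integer(transcripts_per_chromosome),
         half_life_range_h = half_life_range_h, label_time_h = label_time_h,
         kinetics_mode = isTRUE(kinetics_mode),
         reads_per_transcript = reads_per_transcript,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate one squiggle from an RNA sequence
#'
#' Each k-mer window emits a geometric number of samples (mean
#' `cfg$dwell_mean`) drawn from a normal distribution with the pore model's
#' mean (plus `cfg$delta_mean_pA` if the window overlaps an incorporated
#' 5EU position) and the pore model's sd scaled by `cfg$noise_sd_scale`.
#' Consumes the global RNG stream; seed upstream for reproducibility.
#'
#' @param sequence RNA string over `A`,`C`,`G`,`U`, at least `pore$k` long.
#' @param incorporated_positions integer positions of incorporated 5EU;
#'   must all be U positions in `sequence`.
#' @param pore a [make_default_pore_model()] style `pore_model`.
#' @param cfg a [sim_config].
#' @param read_id identifier for the resulting read.
#' @return a [signal_read] with simulation metadata.
#' @export
simulate_read <- function(sequence, incorporated_positions = integer(0),
                          pore, cfg = sim_config(), read_id = "sim_read") {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(bases %in% c("A", "C", "G", "U"))) {
    stop("sequence must be over the RNA alphabet {A,C,G,U}")
  }
  L <- length(bases)
  k <- pore$k
  if (L < k) stop("sequence shorter than the pore-model k-mer length")
  ip <- as.integer(incorporated_positions)
  if (length(ip)) {
    if (any(ip < 1L | ip > L)) stop("incorporated position out of range")
    if (any(bases[ip] != "U")) stop("incorporated position is not a U")
  }
  nw <- L - k + 1L
  kmers <- substring(sequence, seq_len(nw), seq_len(nw) + k - 1L)
  mu <- unname(pore$mean_pA[kmers])
  sd <- unname(pore$sd_pA[kmers]) * cfg$noise_sd_scale
  if (length(ip) && cfg$delta_mean_pA != 0) {
    shifted <- rep(FALSE, nw)
    for (p in ip) {
      lo <- max(1L, p - k + 1L)
      hi <- min(nw, p)
      if (lo <= hi) shifted[lo:hi] <- TRUE
    }
    mu[shifted] <- mu[shifted] + cfg$delta_mean_pA
  }
  dwell <- 1L + rgeom(nw, prob = 1 / cfg$dwell_mean)
  sig <- rep(mu, dwell) + rnorm(sum(dwell), 0, rep(sd, dwell))
  signal_read(read_id, sig, meta = list(
    base_length = L,
    u_fraction = mean(bases == "U"),
    n_U_incorporated = length(ip)
  ))
}

#' Simulate a labeled/unlabeled squiggle dataset with ground truth
#'
#' Builds a transcriptome (i.i.d. uniform RNA sequences per chromosome,
#' lengths uniform in `cfg$read_length_range`), assigns reads to
#' chromosomes by the configured weights, labels reads, samples sparse 5EU
#' incorporation in labeled reads (each U independently with
#' `cfg$p_incorporation`), and emits squiggles plus a ground-truth
#' manifest. In kinetics mode each transcript receives a true half-life
#' drawn log-uniformly from `cfg$half_life_range_h` and its reads are
#' labeled with probability `1 - 2^(-label_time_h / t_half)`. Output is
#' bit-identical for a fixed `cfg$seed`.
#'
#' @param cfg a [sim_config].
#' @param pore pore model; defaults to [make_default_pore_model()] seeded
#'   from `cfg$seed`.
#' @param signals if `FALSE`, skip squiggle emission and return only the
#'   manifest (useful for kinetics-scale simulations where only the labels
#'   matter); `reads` is then `NULL`.
#' @return list with elements `reads` (list of [signal_read] or `NULL`),
#'   `manifest` (one row per read: `read_id`, `label`, `chromosome`,
#'   `transcript_id`, `n_U_incorporated`, `base_length`, `u_fraction`,
#'   `true_half_life_h`) and `transcripts` (per-transcript table).
#' @export
simulate_dataset <- function(cfg = sim_config(),
                             pore = make_default_pore_model(cfg$seed),
                             signals = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "U")

  chroms <- as.character(cfg$chromosomes$name)
  w <- cfg$chromosomes$weight / sum(cfg$chromosomes$weight)
  n_tr <- cfg$transcripts_per_chromosome
  transcripts <- data.frame(
    transcript_id = unlist(lapply(chroms, function(ch)
      paste0(ch, "_t", seq_len(n_tr)))),
    chromosome = rep(chroms, each = n_tr),
    stringsAsFactors = FALSE
  )
  tr_len <- sample(cfg$read_length_range[1]:cfg$read_length_range[2],
                   nrow(transcripts), replace = TRUE)
  tr_seq <- vapply(tr_len, function(L)
    paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))
  transcripts$base_length <- tr_len
  transcripts$sequence <- tr_seq
  transcripts$u_fraction <- vapply(tr_seq, function(s)
    mean(strsplit(s, "", fixed = TRUE)[[1]] == "U"), numeric(1),
    USE.NAMES = FALSE)
  if (cfg$kinetics_mode) {
    lr <- log(cfg$half_life_range_h)
    transcripts$true_half_life_h <- exp(runif(nrow(transcripts), lr[1], lr[2]))
  } else {
    transcripts$true_half_life_h <- NA_real_
  }

  # read -> transcript assignment
  if (cfg$kinetics_mode && !is.null(cfg$reads_per_transcript)) {
    tr_idx <- rep(seq_len(nrow(transcripts)), each = cfg$reads_per_transcript)
    n <- length(tr_idx)
  } else {
    n <- cfg$n_reads
    read_chrom <- sample(chroms, n, replace = TRUE, prob = w)
    tr_idx <- vapply(read_chrom, function(ch) {
      idx <- which(transcripts$chromosome == ch)
      idx[sample.int(length(idx), 1L)]
    }, integer(1), USE.NAMES = FALSE)
  }

  if (cfg$kinetics_mode) {
    f_new <- 1 - 2^(-cfg$label_time_h / transcripts$true_half_life_h[tr_idx])
    labeled <- runif(n) < f_new
  } else {
    labeled <- runif(n) < cfg$labeled_fraction
  }

  read_ids <- sprintf("read_%06d", seq_len(n))
  tr_upos <- lapply(tr_seq, function(s)
    which(strsplit(s, "", fixed = TRUE)[[1]] == "U"))
  reads <- if (signals) vector("list", n) else NULL
  n_inc <- integer(n)
  for (i in seq_len(n)) {
    tr <- transcripts[tr_idx[i], ]
    ip <- integer(0)
    if (labeled[i] && cfg$p_incorporation > 0) {
      upos <- tr_upos[[tr_idx[i]]]
      ip <- upos[runif(length(upos)) < cfg$p_incorporation]
    }
    n_inc[i] <- length(ip)
    if (signals) {
      r <- simulate_read(tr$sequence, ip, pore, cfg, read_id = read_ids[i])
      r$meta$chromosome <- tr$chromosome
      r$meta$transcript_id <- tr$transcript_id
      r$meta$label <- if (labeled[i]) "labeled" else "unlabeled"
      reads[[i]] <- r
    }
  }

  manifest <- data.frame(
    read_id = read_ids,
    label = ifelse(labeled, "labeled", "unlabeled"),
    chromosome = transcripts$chromosome[tr_idx],
    transcript_id = transcripts$transcript_id[tr_idx],
    n_U_incorporated = n_inc,
    base_length = transcripts$base_length[tr_idx],
    u_fraction = transcripts$u_fraction[tr_idx],
    true_half_life_h = transcripts$true_half_life_h[tr_idx],
    stringsAsFactors = FALSE
  )
  list(reads = reads, manifest = manifest, transcripts = transcripts)
}
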