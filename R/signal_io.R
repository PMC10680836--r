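#' Construct a raw-signal read
#'
#' A `signal_read` is the unit all downstream computation operates on: one
#' sequenced molecule's raw current trace plus identifying metadata.
#'
#' @param read_id unique read identifier.
#' @param signal numeric vector of current samples (raw DAC units or pA).
#' @param meta optional named list; recognized fields are `chromosome`
#'   (string or `"unmapped"`), `transcript_id`, `label` (one of
#'   `"labeled"`, `"unlabeled"`, `"unknown"`), `u_fraction` and
#'   `base_length`.
#' @return an object of class `signal_read`.
#' @export
signal_read <- function(read_id, signal, meta = list()) {
  stopifnot(is.character(read_id), length(read_id) == 1L, nzchar(read_id))
  signal <- as.numeric(signal)
  if (length(signal) < 1L) {
    stop("signal_read '", read_id, "': signal must contain at least one sample")
  }
  if (!is.list(meta)) stop("meta must be a list")
  structure(
    list(read_id = read_id, signal = signal, meta = meta),
    class = "signal_read"
  )
}

#' @export
length.signal_read <- function(x) length(x$signal)

#' @export
print.signal_read <- function(x, ...) {
  cat(sprintf(
    "<signal_read %s: %d samples%s>\n", x$read_id, length(x$signal),
    if (!is.null(x$meta$label)) paste0(", ", x$meta$label) else ""
  ))
  invisible(x)
}

#' Preprocessing configuration
#'
#' Holds the per-read preprocessing thresholds: the number of leading
#' samples cropped to avoid adapter/stall sequencing artifacts, and the
#' raw-length window outside which reads are discarded. Both length bounds
#' apply to the raw (pre-crop) length; a read of exactly `min_raw_length`
#' samples is discarded, since it would be empty after cropping.
#'
#' @param crop_head samples removed from the start of each kept read.
#' @param min_raw_length reads with raw length `<=` this are discarded.
#' @param max_raw_length reads with raw length `>` this are discarded.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(crop_head = 5000L, min_raw_length = 5000L,
                              max_raw_length = 400000L) {
  crop_head <- as.integer(crop_head)
  min_raw_length <- as.integer(min_raw_length)
  max_raw_length <- as.integer(max_raw_length)
  stopifnot(crop_head >= 0L, min_raw_length > 0L,
            min_raw_length <= max_raw_length)
  structure(
    list(crop_head = crop_head, min_raw_length = min_raw_length,
         max_raw_length = max_raw_length),
    class = "preprocess_config"
  )
}

#' Length-filter and head-crop a set of reads
#'
#' Removes reads whose raw length is `<= min_raw_length` or
#' `> max_raw_length`, then crops the first `crop_head` samples from each
#' survivor. Input order is preserved. Per-call counts are attached as the
#' `"counts"` attribute (`input`, `discarded_short`, `discarded_long`,
#' `kept`) for logging.
#'
#' @param reads list of [signal_read] objects.
#' @param cfg a [preprocess_config].
#' @return the filtered, cropped list of reads (possibly empty), with a
#'   `"counts"` attribute.
#' @export
filter_and_crop <- function(reads, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  lens <- vapply(reads, function(r) length(r$signal), integer(1))
  short <- lens <= cfg$min_raw_length
  long <- lens > cfg$max_raw_length
  keep <- !short & !long
  out <- lapply(reads[keep], function(r) {
    if (cfg$crop_head > 0L) r$signal <- r$signal[-seq_len(cfg$crop_head)]
    r
  })
  attr(out, "counts") <- c(
    input = length(reads), discarded_short = sum(short),
    discarded_long = sum(long), kept = sum(keep)
  )
  out
}

#' Median/MAD-normalize a read's signal
#'
#' Centers the signal at its median and scales by the median absolute
#' deviation, `MAD(x) = median(|x - median(x)|)` (no Gaussian consistency
#' constant). The result has median 0 and MAD 1 and is invariant to any
#' affine rescaling of the input with positive slope, so raw DAC units and
#' picoamperes produce identical classifier input.
#'
#' @param read a [signal_read] (or a bare numeric vector).
#' @return the read with normalized signal (or a numeric vector).
#' @export
normalize_med_mad <- function(read) {
  x <- if (inherits(read, "signal_read")) read$signal else as.numeric(read)
  if (length(x) < 2L) stop("med-MAD normalization needs at least 2 samples")
  med <- median(x)
  mad0 <- median(abs(x - med))
  if (mad0 == 0) {
    stop("degenerate signal: MAD is zero (constant or near-constant trace)")
  }
  x <- (x - med) / mad0
  if (inherits(read, "signal_read")) {
    read$signal <- x
    read
  } else {
    x
  }
}

.FIXTURE_VERSION <- 1L
.META_FIELDS <- c("chromosome", "transcript_id", "label", "u_fraction",
                  "base_length")

#' Load reads from a raw-signal container
#'
#' Two HDF5 layouts are supported. The `"fixture"` format is this package's
#' portable container: one group per read named by `read_id`, holding a
#' `signal` dataset plus optional scalar metadata attributes, with a
#' `format_version` attribute at the file root. The `"fast5_multi"` dialect
#' mirrors multi-read fast5 files: groups `read_<id>` with a `Raw/Signal`
#' integer dataset and a `channel_id` subgroup carrying `offset`, `range`
#' and `digitisation`; when those are present the raw DAC values are
#' converted to picoamperes as `(raw + offset) * range / digitisation`,
#' otherwise the values pass through unscaled. One container is loaded at a
#' time; unknown groups are ignored.
#'
#' @param path container file path.
#' @param format `"fixture"` or `"fast5_multi"`.
#' @return list of [signal_read] objects (empty list for an empty
#'   container). Reads with a missing signal dataset are skipped with a
#'   warning.
#' @export
load_reads <- function(path, format = c("fixture", "fast5_multi")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("raw-signal container not found: ", path)
  }
  ls <- tryCatch(
    rhdf5::h5ls(path, recursive = FALSE),
    error = function(e) stop("cannot open container ", path, ": ",
                             conditionMessage(e))
  )
  groups <- ls$name[ls$otype == "H5I_GROUP"]
  if (format == "fast5_multi") {
    groups <- groups[startsWith(groups, "read_")]
  }
  # restore insertion order if the writer recorded it
  root_attrs <- rhdf5::h5readAttributes(path, "/")
  if (!is.null(root_attrs$read_order)) {
    ord <- intersect(as.character(root_attrs$read_order), groups)
    groups <- c(ord, setdiff(groups, ord))
  }
  reads <- vector("list", length(groups))
  ok <- logical(length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    r <- tryCatch(
      if (format == "fixture") .load_fixture_read(path, g)
      else .load_fast5_read(path, g),
      error = function(e) {
        warning("skipping read group '", g, "' in ", path, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (!is.null(r)) {
      reads[[i]] <- r
      ok[i] <- TRUE
    }
  }
  reads[ok]
}

.load_fixture_read <- function(path, group) {
  sig <- rhdf5::h5read(path, paste0(group, "/signal"))
  at <- rhdf5::h5readAttributes(path, group)
  meta <- at[intersect(names(at), .META_FIELDS)]
  meta <- lapply(meta, function(v) if (is.array(v)) as.vector(v) else v)
  signal_read(group, as.numeric(sig), meta)
}

.load_fast5_read <- function(path, group) {
  sig <- as.numeric(rhdf5::h5read(path, paste0(group, "/Raw/Signal")))
  ch <- tryCatch(rhdf5::h5readAttributes(path, paste0(group, "/channel_id")),
                 error = function(e) NULL)
  if (!is.null(ch) && all(c("offset", "range", "digitisation") %in% names(ch))) {
    sig <- (sig + as.numeric(ch$offset)) *
      as.numeric(ch$range) / as.numeric(ch$digitisation)
  }
  signal_read(sub("^read_", "", group), sig, list())
}

#' Write reads to a raw-signal container
#'
#' Inverse of [load_reads()]. In `"fixture"` format the round trip is exact
#' on `(read_id, signal, meta)`; an absent `label` is serialized as
#' `"unknown"`. In `"fast5_multi"` format signals are written as the
#' `Raw/Signal` dataset, with channel scaling attributes taken from
#' `meta$offset`, `meta$range`, `meta$digitisation` when present.
#'
#' @param reads list of [signal_read] objects (may be empty).
#' @param path destination file (overwritten).
#' @param format `"fixture"` or `"fast5_multi"`.
#' @return number of reads written, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fixture", "fast5_multi")) {
  format <- match.arg(format)
  ids <- vapply(reads, function(r) r$read_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate read_id in container: ",
                               ids[duplicated(ids)][1])
  if (file.exists(path)) file.remove(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok)) stop("cannot create container at ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(.FIXTURE_VERSION, fid, "format_version")
  if (length(ids)) rhdf5::h5writeAttribute(ids, fid, "read_order")
  rhdf5::H5Fclose(fid)
  for (r in reads) {
    if (format == "fixture") .write_fixture_read(r, path)
    else .write_fast5_read(r, path)
  }
  invisible(length(reads))
}

.write_fixture_read <- function(r, path) {
  rhdf5::h5createGroup(path, r$read_id)
  rhdf5::h5write(r$signal, path, paste0(r$read_id, "/signal"))
  meta <- r$meta[intersect(names(r$meta), .META_FIELDS)]
  if (is.null(meta$label)) meta$label <- "unknown"
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, r$read_id)
  for (nm in names(meta)) {
    rhdf5::h5writeAttribute(meta[[nm]], gid, nm)
  }
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
}

.write_fast5_read <- function(r, path) {
  g <- paste0("read_", r$read_id)
  rhdf5::h5createGroup(path, g)
  rhdf5::h5createGroup(path, paste0(g, "/Raw"))
  rhdf5::h5write(as.integer(round(r$signal)), path, paste0(g, "/Raw/Signal"))
  rhdf5::h5createGroup(path, paste0(g, "/channel_id"))
  ch <- r$meta[intersect(names(r$meta), c("offset", "range", "digitisation"))]
  if (length(ch)) {
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, paste0(g, "/channel_id"))
    for (nm in names(ch)) {
      rhdf5::h5writeAttribute(as.numeric(ch[[nm]]), gid, nm)
    }
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
}
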