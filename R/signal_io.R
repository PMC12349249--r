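#' Raw sensor-array recording
#'
#' Container for one acquisition from a gas-sensor array: a numeric matrix of
#' sensor responses (rows = sampling points, columns = sensors) plus the
#' sampling interval and class metadata. Recordings containing missing values
#' are rejected outright; incomplete acquisitions are discarded, not imputed.
#'
#' @param channels numeric matrix, `[n_points x n_sensors]`.
#' @param sampling_interval seconds per sampling point (> 0).
#' @param label class name of the recording.
#' @param source dataset tag, `"meta_train"` or `"meta_test"`.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(channels, sampling_interval, label,
                          source = c("meta_train", "meta_test")) {
  source <- match.arg(source)
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  if (nrow(channels) < 1L || ncol(channels) < 1L)
    stop("recording must have at least one point and one sensor")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0)
    stop("sampling_interval must be positive")
  if (anyNA(channels))
    stop("recording contains missing values and is discarded")
  structure(
    list(channels = channels, sampling_interval = sampling_interval,
         label = as.character(label), source = source),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d points x %d sensors, dt = %g s, label = %s (%s)\n",
              nrow(x$channels), ncol(x$channels), x$sampling_interval,
              x$label, x$source))
  invisible(x)
}

#' Preprocessed sensor sample
#'
#' A fixed-shape `[T x C]` matrix (default 240 time steps by 8 sensors) that
#' every recording is reduced to before entering the few-shot models.
#'
#' @param matrix numeric matrix `[T x C]`.
#' @param label class name.
#' @param source dataset tag.
#' @return An object of class `enose_sample`.
#' @export
enose_sample <- function(matrix, label, source = c("meta_train", "meta_test")) {
  source <- match.arg(source)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (anyNA(matrix) || any(!is.finite(matrix)))
    stop("sample matrix must be finite")
  structure(list(matrix = matrix, label = as.character(label), source = source),
            class = "enose_sample")
}

#' Dataset bundle
#'
#' An ordered collection of preprocessed samples sharing one `[T x C]` shape,
#' together with the class vocabulary and the role the bundle plays in the
#' few-shot protocol (meta-training or meta-testing).
#'
#' @param samples list of [enose_sample] objects.
#' @param role `"meta_train"` or `"meta_test"`.
#' @param classes optional explicit class vocabulary; defaults to the sorted
#'   unique labels present.
#' @return An object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(samples, role = c("meta_train", "meta_test"),
                           classes = NULL) {
  role <- match.arg(role)
  if (length(samples) == 0L) stop("bundle must contain at least one sample")
  shapes <- vapply(samples, function(s) dim(s$matrix), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("all samples in a bundle must share the same [T x C] shape")
  labels <- vapply(samples, function(s) s$label, character(1))
  if (is.null(classes)) classes <- sort(unique(labels))
  if (!all(labels %in% classes)) stop("sample label outside class vocabulary")
  structure(list(samples = samples, classes = classes, role = role),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  d <- dim(x$samples[[1]]$matrix)
  tab <- table(bundle_labels(x))
  cat(sprintf("<dataset_bundle> %s: %d samples [%d x %d], %d classes\n",
              x$role, length(x$samples), d[1], d[2], length(x$classes)))
  print(tab)
  invisible(x)
}

#' Labels of every sample in a bundle
#' @param bundle a [dataset_bundle].
#' @return character vector of per-sample labels.
#' @export
bundle_labels <- function(bundle) {
  vapply(bundle$samples, function(s) s$label, character(1))
}

#' Delimited-text dialect for raw recordings
#'
#' Describes how a per-recording text table is laid out: delimiter, header
#' row, optional leading time column, and which columns hold the sensor
#' channels (in the desired channel order).
#'
#' @param delimiter field separator (default tab).
#' @param header logical, does the file start with a header row?
#' @param time_column logical, is the first column a time axis to drop?
#' @param channel_columns optional integer vector selecting/ordering channel
#'   columns after time-column removal; `NULL` keeps all columns in file order.
#' @param digits significant digits written by [write_fixture()]; 17 keeps
#'   doubles exact through a write/read round trip.
#' @return A list of class `io_dialect`.
#' @export
io_dialect <- function(delimiter = "\t", header = FALSE, time_column = FALSE,
                       channel_columns = NULL, digits = 17L) {
  structure(list(delimiter = delimiter, header = isTRUE(header),
                 time_column = isTRUE(time_column),
                 channel_columns = channel_columns,
                 digits = as.integer(digits)),
            class = "io_dialect")
}

#' Read one raw recording from a delimited text file
#'
#' Any missing or non-numeric cell makes the whole recording invalid: the
#' file is rejected with an error, mirroring the discard-not-impute rule used
#' when assembling meta-training data.
#'
#' @param path file to read.
#' @param dialect an [io_dialect].
#' @param sampling_interval seconds per row.
#' @param label class label to attach.
#' @param source dataset tag.
#' @return A [raw_recording].
#' @export
read_raw_table <- function(path, dialect = io_dialect(),
                           sampling_interval = 0.01, label = "unknown",
                           source = "meta_train") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = dialect$delimiter,
                          header = dialect$header,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  m <- suppressWarnings(apply(as.matrix(df), 2L, as.numeric))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(df))
  if (anyNA(m))
    stop("recording '", basename(path),
         "' has missing or non-numeric cells and is discarded")
  if (dialect$time_column) m <- m[, -1L, drop = FALSE]
  if (!is.null(dialect$channel_columns))
    m <- m[, dialect$channel_columns, drop = FALSE]
  dimnames(m) <- NULL
  raw_recording(m, sampling_interval, label, source)
}

#' Average a raw recording per second
#'
#' Collapses blocks of `points_per_second` consecutive sampling points to
#' their arithmetic mean, turning e.g. a 40,000-point acquisition sampled at
#' 10 ms into 400 one-second rows. A trailing partial block is dropped with a
#' message.
#'
#' @param x a [raw_recording] or a numeric matrix `[n_points x C]`.
#' @param points_per_second raw points per output row (default 100).
#' @return numeric matrix `[n_seconds x C]`.
#' @export
per_second_average <- function(x, points_per_second = 100L) {
  m <- if (inherits(x, "raw_recording")) x$channels else as.matrix(x)
  pps <- as.integer(points_per_second)
  if (pps <= 0L) stop("points_per_second must be positive")
  n <- nrow(m)
  n_full <- n %/% pps
  if (n_full < 1L) stop("recording shorter than one averaging block")
  rem <- n - n_full * pps
  if (rem > 0L) {
    message(sprintf("per_second_average: dropping trailing %d points", rem))
    m <- m[seq_len(n_full * pps), , drop = FALSE]
  }
  # mean over each pps-block: reshape [pps, n_full, C] and average dim 1
  a <- array(m, dim = c(pps, n_full, ncol(m)))
  out <- apply(a, c(2L, 3L), mean)
  matrix(out, nrow = n_full, ncol = ncol(m))
}

#' Truncate a per-second matrix to a fixed time window
#'
#' Keeps rows in the half-open, 0-based interval `[start_s, end_s)`, so the
#' default 17–257 s window over a 400-row matrix yields exactly 240 rows.
#'
#' @param m numeric matrix `[n_rows x C]` of per-second values.
#' @param start_s first second kept (0-based).
#' @param end_s one past the last second kept.
#' @return numeric matrix `[(end_s - start_s) x C]`.
#' @export
window_truncate <- function(m, start_s = 17L, end_s = 257L) {
  m <- as.matrix(m)
  start_s <- as.integer(start_s); end_s <- as.integer(end_s)
  if (start_s < 0L || start_s >= end_s || end_s > nrow(m))
    stop("window [", start_s, ", ", end_s, ") outside matrix with ",
         nrow(m), " rows")
  m[(start_s + 1L):end_s, , drop = FALSE]
}

#' Equal time-interval extraction
#'
#' Downsamples a matrix to `target` rows by selecting indices spaced evenly
#' from the first to the last row: 0-based indices
#' `round(i * (n_rows - 1) / (target - 1))` for `i = 0 .. target-1`
#' (round-half-to-even), endpoints always included.
#'
#' @param m numeric matrix `[n_rows x C]`.
#' @param target number of rows to keep (default 240).
#' @return numeric matrix `[target x C]`.
#' @export
equal_interval_extract <- function(m, target = 240L) {
  m <- as.matrix(m)
  target <- as.integer(target)
  n <- nrow(m)
  if (target < 2L) stop("target must be at least 2")
  if (target > n) stop("target (", target, ") exceeds available rows (", n, ")")
  idx <- as.integer(round((seq_len(target) - 1L) * (n - 1) / (target - 1)))
  m[idx + 1L, , drop = FALSE]
}

#' Per-sample per-channel min-max normalisation
#'
#' Rescales every channel of a sample independently to `[0, 1]`. A constant
#' channel has no scale and maps to all zeros by convention. Normalisation is
#' idempotent. Operating per sample (rather than per dataset) keeps test-set
#' statistics out of training.
#'
#' @param x an [enose_sample] or numeric matrix `[T x C]`.
#' @return same type as the input, normalised.
#' @export
normalize_sample <- function(x) {
  m <- if (inherits(x, "enose_sample")) x$matrix else as.matrix(x)
  lo <- apply(m, 2L, min)
  hi <- apply(m, 2L, max)
  rng <- hi - lo
  out <- sweep(m, 2L, lo, "-")
  nz <- rng > 0
  if (any(nz)) out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, rng[nz], "/")
  if (any(!nz)) out[, !nz] <- 0
  if (inherits(x, "enose_sample"))
    enose_sample(out, x$label, x$source)
  else out
}

#' Channel-shuffle augmentation
#'
#' Applies ONE random permutation of the sensor channels to every sample in a
#' batch (typically the support and query sets of one episode together).
#' Sharing the permutation preserves the channel correspondence across the
#' samples being compared, which is what lets a similarity model learn to
#' score samples under arbitrary channel orders.
#'
#' @param batch list of [enose_sample] objects (or numeric matrices).
#' @param permutation optional integer permutation of `1..C`; drawn from the
#'   current RNG when `NULL`.
#' @return the batch with channels permuted; the permutation used is attached
#'   as attribute `"permutation"`.
#' @export
channel_shuffle <- function(batch, permutation = NULL) {
  get_mat <- function(s) if (inherits(s, "enose_sample")) s$matrix else s
  C <- ncol(get_mat(batch[[1]]))
  if (is.null(permutation)) permutation <- sample.int(C)
  permutation <- as.integer(permutation)
  if (length(permutation) != C || !setequal(permutation, seq_len(C)))
    stop("permutation must be a bijection on 1..", C)
  out <- lapply(batch, function(s) {
    m <- get_mat(s)[, permutation, drop = FALSE]
    if (inherits(s, "enose_sample")) enose_sample(m, s$label, s$source) else m
  })
  attr(out, "permutation") <- permutation
  out
}

#' Preprocess a raw recording to the common [240 x 8] shape
#'
#' Meta-training-style recordings (long acquisitions at 10 ms) are averaged
#' per second and truncated to the 17-257 s window; meta-testing-style breath
#' recordings are reduced by equal time-interval extraction. Both paths end
#' with per-channel min-max normalisation unless disabled.
#'
#' @param rec a [raw_recording].
#' @param method `"per_second_window"` or `"equal_interval"`; default chosen
#'   from the recording's `source` tag.
#' @param points_per_second,start_s,end_s parameters of the averaging path.
#' @param target rows kept by the extraction path.
#' @param normalize apply [normalize_sample()] (default `TRUE`).
#' @return An [enose_sample].
#' @export
preprocess_recording <- function(rec,
                                 method = NULL,
                                 points_per_second = 100L,
                                 start_s = 17L, end_s = 257L,
                                 target = 240L, normalize = TRUE) {
  stopifnot(inherits(rec, "raw_recording"))
  if (is.null(method))
    method <- if (rec$source == "meta_train") "per_second_window" else "equal_interval"
  method <- match.arg(method, c("per_second_window", "equal_interval"))
  m <- switch(method,
    per_second_window = window_truncate(
      per_second_average(rec, points_per_second), start_s, end_s),
    equal_interval = equal_interval_extract(rec$channels, target))
  s <- enose_sample(m, rec$label, rec$source)
  if (normalize) s <- normalize_sample(s) else s
}

#' Preprocess a list of raw recordings into a dataset bundle
#'
#' @param recordings list of [raw_recording] objects.
#' @param role bundle role; defaults to the first recording's source tag.
#' @param ... passed to [preprocess_recording()].
#' @return A [dataset_bundle].
#' @export
preprocess_bundle <- function(recordings, role = NULL, ...) {
  if (is.null(role)) role <- recordings[[1]]$source
  dataset_bundle(lapply(recordings, preprocess_recording, ...), role = role)
}
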