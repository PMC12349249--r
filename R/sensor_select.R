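#' Static and dynamic response features per sample and sensor
#'
#' For every sample and sensor channel computes the temporal average response
#' (static behaviour) and the maximum absolute first difference of the series
#' (dynamic sensitivity, the largest instantaneous slope of the preprocessed
#' per-step series).
#'
#' @param bundle a [dataset_bundle] of preprocessed samples, or a list of
#'   [raw_recording] objects when slopes should be taken on the raw series.
#' @return list with `x_mean` and `x_slope`, numeric matrices
#'   `[n_samples x C]`, and `labels`, the per-sample class labels.
#' @export
extract_features <- function(bundle) {
  if (inherits(bundle, "dataset_bundle")) {
    mats <- lapply(bundle$samples, function(s) s$matrix)
    labels <- bundle_labels(bundle)
  } else if (is.list(bundle) && length(bundle) &&
             inherits(bundle[[1]], "raw_recording")) {
    mats <- lapply(bundle, function(r) r$channels)
    labels <- vapply(bundle, function(r) r$label, character(1))
  } else stop("need a dataset_bundle or a list of raw recordings")
  if (nrow(mats[[1]]) < 2L) stop("slope feature needs at least 2 time steps")
  C <- ncol(mats[[1]])
  x_mean <- t(vapply(mats, colMeans, numeric(C)))
  x_slope <- t(vapply(mats, function(m) apply(abs(diff(m)), 2L, max),
                      numeric(C)))
  list(x_mean = x_mean, x_slope = x_slope, labels = labels)
}

#' Histogram discretisation of a continuous feature
#'
#' Equal-width bins over `[min, max]`; the maximum lands in the last bin and
#' a constant feature occupies bin 1 alone.
#'
#' @param values finite numeric vector.
#' @param n_bins number of bins (default 20).
#' @return integer bin index in `1..n_bins` per value.
#' @export
histogram_discretize <- function(values, n_bins = 20L) {
  if (length(values) == 0L) stop("empty input")
  if (any(!is.finite(values))) stop("values must be finite")
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(rep.int(1L, length(values)))
  idx <- floor((values - lo) / (hi - lo) * n_bins) + 1L
  pmin(as.integer(idx), n_bins)
}

#' Mutual information of two discrete variables (nats)
#'
#' Plug-in estimate from empirical joint frequencies:
#' `MI = sum p(x,y) log( p(x,y) / (p(x) p(y)) )` with natural logarithm and
#' the convention `0 log 0 = 0`. Always nonnegative up to floating point.
#'
#' @param x_bins discrete feature values (bin indices or any labels).
#' @param y_labels class labels, same length.
#' @param base logarithm base; default `exp(1)` reports nats.
#' @return nonnegative mutual information.
#' @export
mutual_information <- function(x_bins, y_labels, base = exp(1)) {
  if (length(x_bins) != length(y_labels)) stop("length mismatch")
  if (length(x_bins) == 0L) stop("empty input")
  joint <- table(x = x_bins, y = y_labels)
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  terms <- p * (log(p) - outer(log(px), log(py), "+"))
  terms[p == 0] <- 0
  max(0, sum(terms) / log(base))
}

#' Combine static and dynamic MI contributions into one sensor score
#'
#' The combined score is the arithmetic mean of the mean-response MI and the
#' slope MI: `(mi_mean + mi_slope) / 2`. Vectorised.
#'
#' @param mi_mean,mi_slope nonnegative MI values (nats).
#' @return combined contribution score, between the two inputs.
#' @export
combined_score <- function(mi_mean, mi_slope) {
  if (any(mi_mean < 0) || any(mi_slope < 0)) stop("MI values must be >= 0")
  (mi_mean + mi_slope) / 2
}

#' Score every sensor of a bundle by mutual information
#'
#' Discretises each sensor's mean and slope features with equal-width
#' histograms fitted over the whole bundle, computes their MI against the
#' class label, and combines the two contributions.
#'
#' @param bundle a [dataset_bundle].
#' @param n_bins histogram bins (default 20).
#' @param base logarithm base (default natural: nats).
#' @return data.frame with columns `sensor_id`, `mi_mean`, `mi_slope`,
#'   `combined`, one row per sensor.
#' @export
sensor_scores <- function(bundle, n_bins = 20L, base = exp(1)) {
  ft <- extract_features(bundle)
  C <- ncol(ft$x_mean)
  mi_m <- vapply(seq_len(C), function(c)
    mutual_information(histogram_discretize(ft$x_mean[, c], n_bins),
                       ft$labels, base), numeric(1))
  mi_s <- vapply(seq_len(C), function(c)
    mutual_information(histogram_discretize(ft$x_slope[, c], n_bins),
                       ft$labels, base), numeric(1))
  data.frame(sensor_id = seq_len(C), mi_mean = mi_m, mi_slope = mi_s,
             combined = combined_score(mi_m, mi_s))
}

#' Rank sensors by combined MI score
#'
#' Descending by combined score; ties broken by ascending sensor id.
#'
#' @param scores data.frame as returned by [sensor_scores()] (needs columns
#'   `sensor_id` and `combined`).
#' @param k how many sensors to keep (default 8).
#' @return integer vector of the top-`k` sensor ids, best first.
#' @export
rank_sensors <- function(scores, k = 8L) {
  k <- as.integer(k)
  if (k <= 0L) stop("k must be positive")
  if (k > nrow(scores)) stop("k exceeds number of sensors")
  ord <- order(-scores$combined, scores$sensor_id)
  scores$sensor_id[ord][seq_len(k)]
}
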