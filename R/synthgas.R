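#' Configuration of the synthetic gas-response generator
#'
#' Each synthetic recording is a first-order sensor response: a flat baseline
#' while the chamber holds clean air, an exponential saturating rise once the
#' gas is introduced, a plateau, and an exponential decay after the gas is
#' flushed, plus white measurement noise and an optional linear baseline
#' drift. Classes differ in their per-sensor response amplitudes and in their
#' per-sensor rise/decay time constants; both differences are scaled by
#' `separation`, so `separation = 0` collapses every class onto the same
#' expected curve. Time-constant differences matter because per-channel
#' min-max normalisation removes absolute amplitude: after normalisation the
#' class signature lives in the *shape* of the rise and decay.
#'
#' @param n_classes number of gas classes.
#' @param samples_per_class integer vector (recycled) of recordings per class.
#' @param n_sensors sensor channels (default 8).
#' @param n_points sampling points per recording.
#' @param sampling_interval seconds per point.
#' @param gas_on,gas_off point indices at which gas flow starts and stops.
#' @param baseline per-sensor baseline level (recycled to `n_sensors`).
#' @param amplitude per-sensor mean response amplitude (recycled).
#' @param rise_tau,decay_tau nominal time constants in points.
#' @param separation nonnegative scale on between-class differences in
#'   amplitude and kinetics; 0 means identical classes.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param drift_sd standard deviation of the per-recording linear drift slope
#'   (total drift over the recording).
#' @param source dataset tag attached to recordings.
#' @param class_names optional class names; default `class_1 ...`.
#' @param seed integer seed making the dataset fully reproducible.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_classes = 4L, samples_per_class = 20L,
                         n_sensors = 8L, n_points = 4000L,
                         sampling_interval = 0.002,
                         gas_on = round(n_points * 0.1),
                         gas_off = round(n_points * 0.6),
                         baseline = 0.2, amplitude = 1,
                         rise_tau = n_points * 0.08,
                         decay_tau = n_points * 0.12,
                         separation = 1, noise_sd = 0.05, drift_sd = 0,
                         source = c("meta_test", "meta_train"),
                         class_names = NULL, seed = 1L) {
  source <- match.arg(source)
  n_classes <- as.integer(n_classes)
  spc <- rep_len(as.integer(samples_per_class), n_classes)
  if (gas_on >= gas_off || gas_off > n_points) stop("need gas_on < gas_off <= n_points")
  if (noise_sd < 0 || separation < 0) stop("noise_sd and separation must be >= 0")
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(n_classes))
  structure(list(
    n_classes = n_classes, samples_per_class = spc,
    n_sensors = as.integer(n_sensors), n_points = as.integer(n_points),
    sampling_interval = sampling_interval,
    gas_on = as.integer(gas_on), gas_off = as.integer(gas_off),
    baseline = rep_len(baseline, n_sensors),
    amplitude = rep_len(amplitude, n_sensors),
    rise_tau = rise_tau, decay_tau = decay_tau,
    separation = separation, noise_sd = noise_sd, drift_sd = drift_sd,
    source = source, class_names = class_names, seed = as.integer(seed)),
    class = "synth_config")
}

#' Generator presets for the two acquisition styles
#'
#' `"metatrain"` mimics the statistical layout of a wind-tunnel gas library:
#' long 40,000-point acquisitions at 10 ms with gas flowing from 20 s to
#' 200 s of 400 s. `"metatest"` mimics short breath recordings: 4,000 points
#' over 8 s with the unbalanced class sizes 40/8/20/10 of a COPD screening
#' set (patients / smokers / healthy controls / ambient air).
#'
#' @param preset `"metatrain"` or `"metatest"`.
#' @param ... overrides passed to [synth_config()].
#' @return a `synth_config`.
#' @export
synth_preset <- function(preset = c("metatest", "metatrain"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    metatrain = list(n_classes = 11L, samples_per_class = 20L,
                     n_points = 40000L, sampling_interval = 0.01,
                     gas_on = 2000L, gas_off = 20000L,
                     rise_tau = 2500, decay_tau = 4000,
                     source = "meta_train", seed = 2024L),
    metatest = list(n_classes = 4L, samples_per_class = c(40L, 8L, 20L, 10L),
                    n_points = 4000L, sampling_interval = 0.002,
                    gas_on = 400L, gas_off = 2400L,
                    rise_tau = 350, decay_tau = 500,
                    class_names = c("copd", "smokers", "control", "air"),
                    source = "meta_test", seed = 2025L))
  do.call(synth_config, utils::modifyList(args, list(...)))
}

# Class-by-sensor response parameters drawn once per dataset from the seed:
# amplitudes get a |N(0,1)| relative boost and the time constants a log-scale
# multiplier, both proportional to `separation`.
synth_class_params <- function(config) {
  K <- config$n_classes; C <- config$n_sensors; sep <- config$separation
  amp_dev <- matrix(abs(stats::rnorm(K * C)), K, C)
  tau_dev_r <- matrix(stats::runif(K * C, -0.8, 0.8), K, C)
  tau_dev_d <- matrix(stats::runif(K * C, -0.8, 0.8), K, C)
  list(
    amplitude = sweep(1 + sep * amp_dev, 2L, config$amplitude, "*"),
    rise_tau = config$rise_tau * exp(sep * tau_dev_r),
    decay_tau = config$decay_tau * exp(sep * tau_dev_d))
}

# Deterministic expected response curve of one (class, sensor) pair.
synth_curve <- function(n_points, gas_on, gas_off, baseline, amplitude,
                        rise_tau, decay_tau) {
  t <- seq_len(n_points)
  y <- rep(baseline, n_points)
  on <- t > gas_on & t <= gas_off
  y[on] <- baseline + amplitude * (1 - exp(-(t[on] - gas_on) / rise_tau))
  peak <- baseline + amplitude * (1 - exp(-(gas_off - gas_on) / rise_tau))
  off <- t > gas_off
  y[off] <- baseline + (peak - baseline) * exp(-(t[off] - gas_off) / decay_tau)
  y
}

#' Generate a seeded synthetic sensor-array dataset
#'
#' Draws class-specific response parameters once, then one noisy recording
#' per sample. The result is bit-reproducible for a given config (the
#' caller's RNG state is preserved).
#'
#' @param config a [synth_config].
#' @param preprocess reduce each recording to a normalised `[240 x C]`
#'   [enose_sample] and return a [dataset_bundle] (default); otherwise return
#'   the list of [raw_recording] objects.
#' @param target rows of the preprocessed sample (default 240).
#' @return a [dataset_bundle], or a list of raw recordings with the config
#'   attached as attribute `"config"`.
#' @export
generate_dataset <- function(config, preprocess = TRUE, target = 240L) {
  stopifnot(inherits(config, "synth_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  pars <- synth_class_params(config)
  np <- config$n_points; C <- config$n_sensors
  recs <- list(); r <- 0L
  for (k in seq_len(config$n_classes)) {
    base_mat <- vapply(seq_len(C), function(c)
      synth_curve(np, config$gas_on, config$gas_off, config$baseline[c],
                  pars$amplitude[k, c], pars$rise_tau[k, c],
                  pars$decay_tau[k, c]),
      numeric(np))
    for (s in seq_len(config$samples_per_class[k])) {
      m <- base_mat + matrix(stats::rnorm(np * C, sd = config$noise_sd), np, C)
      if (config$drift_sd > 0) {
        slope <- stats::rnorm(C, sd = config$drift_sd)
        m <- m + outer(seq_len(np) / np, slope)
      }
      r <- r + 1L
      recs[[r]] <- raw_recording(m, config$sampling_interval,
                                 config$class_names[k], config$source)
    }
  }
  if (!preprocess) {
    attr(recs, "config") <- config
    return(recs)
  }
  role <- config$source
  # synthetic recordings are reduced by equal-interval extraction regardless
  # of role: it is exact for any n_points and keeps memory bounded
  dataset_bundle(lapply(recs, preprocess_recording, method = "equal_interval",
                        target = target), role = role)
}

#' Write recordings as a directory of delimited text files plus a manifest
#'
#' One file per recording, values printed with `dialect$digits` significant
#' digits (17 round-trips doubles exactly), and a tab-separated
#' `manifest.tsv` mapping each file to its label and source tag. The layout
#' is readable back with [read_fixture_dir()] / [read_raw_table()].
#'
#' @param recordings list of [raw_recording] objects, or a [dataset_bundle]
#'   whose preprocessed samples are written one file each (sampling interval
#'   recorded as 1 second per preprocessed row).
#' @param dir output directory (created if needed).
#' @param dialect an [io_dialect] controlling delimiter and precision.
#' @return path of the manifest file, invisibly.
#' @export
write_fixture <- function(recordings, dir, dialect = io_dialect()) {
  if (inherits(recordings, "dataset_bundle"))
    recordings <- lapply(recordings$samples, function(s)
      raw_recording(s$matrix, 1, s$label, s$source))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(recordings)
  files <- character(n)
  for (i in seq_len(n)) {
    files[i] <- sprintf("rec_%04d.tsv", i)
    m <- recordings[[i]]$channels
    txt <- apply(m, 1L, function(row)
      paste(formatC(row, digits = dialect$digits, format = "g"),
            collapse = dialect$delimiter))
    writeLines(txt, file.path(dir, files[i]))
  }
  manifest <- data.frame(
    file = files,
    label = vapply(recordings, function(r) r$label, character(1)),
    source = vapply(recordings, function(r) r$source, character(1)),
    sampling_interval = vapply(recordings, function(r) r$sampling_interval,
                               numeric(1)))
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mp)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir directory containing `manifest.tsv` and per-recording files.
#' @param dialect an [io_dialect] matching the one used to write.
#' @return list of [raw_recording] objects in manifest order.
#' @export
read_fixture_dir <- function(dir, dialect = io_dialect()) {
  mp <- file.path(dir, "manifest.tsv")
  if (!file.exists(mp)) stop("no manifest.tsv in ", dir)
  manifest <- utils::read.table(mp, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i)
    read_raw_table(file.path(dir, manifest$file[i]), dialect,
                   sampling_interval = manifest$sampling_interval[i],
                   label = manifest$label[i], source = manifest$source[i]))
}
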