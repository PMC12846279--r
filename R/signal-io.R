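#' Transient load/response signals
#'
#' `transient_signal()` is the shared container for all time-series handled by
#' the package: pedal/seat accelerations (g), tibial axial force (kN) and
#' pelvis acceleration (g). Signals are uniformly sampled; `dt` is the sample
#' interval in seconds (default `1e-4`, i.e. 10 kHz).
#'
#' @param samples Numeric vector of samples (length >= 2, all finite).
#' @param dt Positive sample interval in seconds.
#' @param channel One of `"pedal_load"`, `"seat_load"`, `"tibial_force"`,
#'   `"pelvis_accel"`.
#' @param units One of `"g"`, `"kN"`, `"m_s2"`. Defaults to the conventional
#'   unit for the channel (g for accelerations, kN for tibial force).
#' @return An object of class `transient_signal` (a list with elements
#'   `samples`, `dt`, `channel`, `units`).
#' @export
transient_signal <- function(samples, dt = 1e-4,
                             channel = c("pedal_load", "seat_load",
                                         "tibial_force", "pelvis_accel"),
                             units = NULL) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a transient_signal needs at least 2 samples")
  if (!all(is.finite(samples)))
    stop("transient_signal samples must all be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  if (is.null(units))
    units <- if (channel == "tibial_force") "kN" else "g"
  units <- match.arg(units, c("g", "kN", "m_s2"))
  structure(list(samples = samples, dt = dt,
                 channel = channel, units = units),
            class = "transient_signal")
}

#' @export
print.transient_signal <- function(x, ...) {
  cat(sprintf("<transient_signal> %s [%s], %d samples @ %.6g s (%.4g s)\n",
              x$channel, x$units, length(x$samples), x$dt,
              x$dt * length(x$samples)))
  invisible(x)
}

#' @export
length.transient_signal <- function(x) length(x$samples)

#' Read a signal from a two-column CSV file
#'
#' Expects a header line `time_s,value` followed by comma-separated numeric
#' rows with a strictly increasing, uniformly spaced time column ('.' decimal
#' mark). `dt` is inferred from the median time step.
#'
#' @param path Path to the CSV file.
#' @param channel Channel role to attach, see [transient_signal()].
#' @param units Optional unit override.
#' @param tol Relative tolerance on time-step uniformity (default `1e-6`).
#' @return A [transient_signal()].
#' @export
read_signal <- function(path, channel, units = NULL, tol = 1e-6) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("signal file must contain a header and at least 2 rows: ", path)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad_shape <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad_shape))
    stop(sprintf("parse error at line %d of %s: expected 2 comma-separated fields",
                 bad_shape[1L] + 1L, path))
  tv <- suppressWarnings(vapply(parts, function(p) as.numeric(p[1L]), 0))
  vv <- suppressWarnings(vapply(parts, function(p) as.numeric(p[2L]), 0))
  bad <- which(!is.finite(tv) | !is.finite(vv))
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: non-numeric value",
                 bad[1L] + 1L, path))
  dts <- diff(tv)
  if (any(dts <= 0))
    stop("time column must be strictly increasing: ", path)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > tol * dt)
    stop(sprintf("non-uniform time spacing in %s (relative jitter > %g)",
                 path, tol))
  transient_signal(vv, dt = dt, channel = channel, units = units)
}

#' Write a signal to a two-column CSV file
#'
#' Inverse of [read_signal()]; values are written with 17 significant digits
#' so a read/write round trip is stable to better than 1e-12.
#'
#' @param signal A [transient_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "transient_signal"))
  t <- (seq_along(signal$samples) - 1L) * signal$dt
  lines <- c("time_s,value",
             sprintf("%.17g,%.17g", t, signal$samples))
  writeLines(lines, path)
  invisible(path)
}

#' Anti-aliased downsampling
#'
#' Applies a zero-phase low-pass (8th-order Butterworth at 80% of the new
#' Nyquist, run forward and backward) before keeping every `factor`-th
#' sample, mirroring the acquisition chain in which 100 kHz records are
#' decimated to the 10 kHz processing rate.
#'
#' @param signal A [transient_signal()].
#' @param factor Positive integer decimation factor.
#' @return A [transient_signal()] with `dt` multiplied by `factor`.
#' @export
downsample <- function(signal, factor) {
  stopifnot(inherits(signal, "transient_signal"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(signal)
  n_out <- length(signal$samples) %/% factor
  if (n_out < 2L) stop("downsampling factor leaves fewer than 2 samples")
  bf <- signal::butter(4, 0.8 / factor, type = "low")
  y <- filtfilt_reflect(bf$b, bf$a, signal$samples)
  transient_signal(y[seq(1L, n_out * factor, by = factor)],
                   dt = signal$dt * factor,
                   channel = signal$channel, units = signal$units)
}

# Zero-phase IIR filtering: forward pass, then backward pass over the
# reversed output, with reflected-edge padding and steady-state initial
# conditions (the filter state that makes a constant input transient-free),
# so DC gain is exactly unity and edge transients are suppressed.
filtfilt_reflect <- function(b, a, x) {
  nf <- max(length(a), length(b))
  a <- c(a, numeric(nf - length(a)))
  b <- c(b, numeric(nf - length(b)))
  g <- sum(b) / sum(a)                       # DC gain
  one_pass <- function(v) {
    # history as if the signal had sat at v[1] forever (steady state)
    as.numeric(signal::filter(b, a, v,
                              init.x = rep(v[1L], nf - 1L),
                              init.y = rep(v[1L] * g, nf - 1L)))
  }
  np <- min(length(x) - 1L, 3L * (nf - 1L))
  pre <- 2 * x[1L] - x[seq(np + 1L, 2L)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - np)]
  xp <- c(pre, x, post)
  y <- rev(one_pass(rev(one_pass(xp))))
  as.numeric(y[seq(np + 1L, np + length(x))])
}

#' Pipeline configuration
#'
#' Collects every tunable of the augmentation/prediction pipeline with the
#' study defaults: depth-5 DB4 decomposition, 3000-sample signals at 10 kHz,
#' GAN trained for 1000 epochs with batch 4, one generator update per two
#' discriminator updates and learning rate 0.001; perturbation scaling
#' alpha in [0.95, 1.05] and noise ratio beta in [0.01, 0.1]; ISO 18571
#' weights (0.4, 0.2, 0.2, 0.2).
#'
#' @param wavelet_depth Decomposition depth J.
#' @param sample_length Nominal signal length N.
#' @param sample_rate Sampling rate in Hz.
#' @param epochs,batch,update_ratio,learning_rate GAN training settings;
#'   `update_ratio` is the number of discriminator updates per generator
#'   update.
#' @param alpha_range,beta Perturbation parameters.
#' @param iso_weights Length-4 weights (corridor, phase, magnitude, slope),
#'   must sum to 1.
#' @param qc_threshold Minimum ISO total score for a simulated row to enter
#'   the training set.
#' @param seed Integer seed for every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(wavelet_depth = 5L,
                            sample_length = 3000L,
                            sample_rate = 1e4,
                            epochs = 1000L,
                            batch = 4L,
                            update_ratio = 2L,
                            learning_rate = 0.001,
                            alpha_range = c(0.95, 1.05),
                            beta = 0.05,
                            iso_weights = c(0.4, 0.2, 0.2, 0.2),
                            qc_threshold = 0.5,
                            seed = 1L) {
  stopifnot(wavelet_depth >= 1L, sample_length >= 2L, sample_rate > 0,
            epochs >= 1L, batch >= 1L, update_ratio >= 1L,
            learning_rate > 0, length(alpha_range) == 2L,
            beta >= 0, length(iso_weights) == 4L)
  if (abs(sum(iso_weights) - 1) > 1e-12)
    stop("iso_weights must sum to 1")
  structure(list(wavelet_depth = as.integer(wavelet_depth),
                 sample_length = as.integer(sample_length),
                 sample_rate = sample_rate,
                 epochs = as.integer(epochs),
                 batch = as.integer(batch),
                 update_ratio = as.integer(update_ratio),
                 learning_rate = learning_rate,
                 alpha_range = as.numeric(alpha_range),
                 beta = beta,
                 iso_weights = as.numeric(iso_weights),
                 qc_threshold = qc_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Keys mirror the arguments of [pipeline_config()]; missing keys fall back
#' to the defaults.
#'
#' @param path Path to a JSON file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to JSON
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
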