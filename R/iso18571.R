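#' ISO 18571 corridor widths
#'
#' Constant-width corridors around the reference curve: inner
#' `delta_i = 0.05 * Ynorm`, outer `delta_o = 0.5 * Ynorm`, where `Ynorm`
#' is the larger of the absolute extrema of the reference.
#'
#' @param reference The reference [transient_signal()].
#' @return List with `Ynorm`, `delta_i`, `delta_o`.
#' @export
iso_corridors <- function(reference) {
  stopifnot(inherits(reference, "transient_signal"))
  Ynorm <- max(abs(min(reference$samples)), abs(max(reference$samples)))
  if (Ynorm <= 0) stop("all-zero reference curve: corridors undefined")
  list(Ynorm = Ynorm, delta_i = 0.05 * Ynorm, delta_o = 0.5 * Ynorm)
}

#' ISO 18571 corridor score
#'
#' Per-sample score: 1 inside the inner corridor, 0 outside the outer one,
#' and `((delta_o - |dev|) / (delta_o - delta_i))^2` in between; `Ec` is
#' the mean over all samples.
#'
#' @param x Reference [transient_signal()].
#' @param y Comparison signal of equal length and `dt`.
#' @return `Ec` in `[0, 1]`.
#' @export
corridor_score <- function(x, y) {
  check_pair(x, y)
  cor <- iso_corridors(x)
  dev <- abs(y$samples - x$samples)
  eci <- ifelse(dev < cor$delta_i, 1,
                ifelse(dev > cor$delta_o, 0,
                       ((cor$delta_o - dev) /
                          (cor$delta_o - cor$delta_i))^2))
  mean(eci)
}

check_pair <- function(x, y) {
  stopifnot(inherits(x, "transient_signal"),
            inherits(y, "transient_signal"))
  if (length(x$samples) != length(y$samples))
    stop("reference and comparison curves must have equal length")
  if (abs(x$dt - y$dt) > 1e-12 * x$dt)
    stop("reference and comparison curves must share dt")
  invisible(TRUE)
}

# First sample where the reference exceeds 5% of Ynorm (burst onset). If
# the remaining window would be shorter than min_tail samples, fall back
# to the start of the record.
burst_onset <- function(x, min_tail = 16L) {
  Ynorm <- max(abs(x))
  i <- which(abs(x) > 0.05 * Ynorm)[1L]
  if (is.na(i) || length(x) - i + 1L < min_tail) 1L else i
}

ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den <= 0) stop("degenerate (zero-variance) comparison window")
  sum(a * b) / den
}

#' ISO 18571 phase score
#'
#' Scans integer shifts `m = 0..floor(eps_pmax * N)` in both directions
#' with normalized cross-correlation over the evaluation window starting
#' at the burst onset; `l_eps` is the shift giving the best correlation
#' (smallest shift on ties) and `Ep = (eps_pmax*N - l_eps)/(eps_pmax*N)`.
#'
#' @param x,y Reference and comparison signals (equal length and `dt`).
#' @param eps_pmax Maximum shift as a fraction of the record length
#'   (default 0.2).
#' @return List with `Ep`, `l_eps`, `direction` (`"left"` if the
#'   comparison curve had to be advanced, `"right"` if delayed) and
#'   `tstart`.
#' @export
phase_score <- function(x, y, eps_pmax = 0.2) {
  check_pair(x, y)
  N <- length(x$samples)
  L <- max(1L, as.integer(floor(eps_pmax * N)))
  ts <- burst_onset(x$samples, min_tail = L + 8L)
  K <- (N - ts + 1L) - L
  if (K < 2L) stop("record too short for the phase evaluation window")
  xs <- x$samples; ys <- y$samples
  pl <- pr <- numeric(L + 1L)
  xb <- xs[ts:(ts + K - 1L)]
  yb <- ys[ts:(ts + K - 1L)]
  for (m in 0:L) {
    pl[m + 1L] <- ncc(xb, ys[(ts + m):(ts + m + K - 1L)])
    pr[m + 1L] <- ncc(xs[(ts + m):(ts + m + K - 1L)], yb)
  }
  best <- pmax(pl, pr)
  l_eps <- which.max(best) - 1L       # smallest shift on ties
  direction <- if (pl[l_eps + 1L] >= pr[l_eps + 1L]) "left" else "right"
  Ep <- max(0, (L - l_eps) / L)
  list(Ep = Ep, l_eps = l_eps, direction = direction, tstart = ts)
}

# Phase-aligned, truncated curve pair after removing the best shift.
align_curves <- function(x, y, phase) {
  xs <- x$samples; ys <- y$samples
  N <- length(xs); ts <- phase$tstart; l <- phase$l_eps
  if (phase$direction == "left") {
    list(xt = xs[ts:(N - l)], yts = ys[(ts + l):N])
  } else {
    list(xt = xs[(ts + l):N], yts = ys[ts:(N - l)])
  }
}

#' ISO 18571 DTW magnitude score
#'
#' Runs unconstrained dynamic time warping (squared-difference local cost,
#' steps down/right/diagonal, ties toward the diagonal) on the
#' phase-aligned curves, then computes the L1 amplitude error ratio along
#' the warping path: `eps_mag = sum|y_w - x_w| / sum|x_w|`, and
#' `Em = (0.5 - eps_mag)/0.5` clipped to `[0, 1]`.
#'
#' @param xt,yts Numeric vectors: the phase-aligned, truncated reference
#'   and comparison curves.
#' @return List with `Em`, `eps_mag`, and the warped curves `xw`, `yw`.
#' @export
magnitude_score <- function(xt, yts) {
  stopifnot(length(xt) >= 2L, length(yts) >= 2L)
  path <- dtw_path(xt, yts)
  xw <- xt[path[, 1L]]
  yw <- yts[path[, 2L]]
  den <- sum(abs(xw))
  if (den <= 0) stop("zero-norm reference after alignment")
  eps_mag <- sum(abs(yw - xw)) / den
  em_max <- 0.5
  Em <- if (eps_mag > em_max) 0 else
    min(1, max(0, (em_max - eps_mag) / em_max))
  list(Em = Em, eps_mag = eps_mag, xw = xw, yw = yw)
}

# Moving average with a 9-point window, reduced symmetrically (1, 3, 5, 7
# points) near the endpoints.
smooth9 <- function(v) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    half <- min(4L, i - 1L, n - i)
    out[i] <- mean(v[(i - half):(i + half)])
  }
  out
}

central_diff <- function(v) {
  n <- length(v)
  d <- numeric(n)
  d[1L] <- v[2L] - v[1L]
  d[n] <- v[n] - v[n - 1L]
  if (n > 2L) d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / 2
  d
}

#' ISO 18571 slope score
#'
#' Both curves are smoothed with a 9-point moving average (reduced windows
#' at the endpoints), differentiated by central differences, and compared
#' by the L1 slope-error ratio; `Es = (2 - eps_slope)/2` clipped to
#' `[0, 1]`.
#'
#' @param xt,yts Numeric vectors: aligned reference and comparison curves
#'   (length >= 9).
#' @return List with `Es` and `eps_slope`.
#' @export
slope_score <- function(xt, yts) {
  stopifnot(length(xt) == length(yts))
  if (length(xt) < 9L) stop("slope score needs at least 9 samples")
  dx <- central_diff(smooth9(xt))
  dy <- central_diff(smooth9(yts))
  den <- sum(abs(dx))
  if (den <= 0) stop("flat reference: slope error undefined")
  eps_slope <- sum(abs(dy - dx)) / den
  es_max <- 2.0
  Es <- if (eps_slope > es_max) 0 else
    min(1, max(0, (es_max - eps_slope) / es_max))
  list(Es = Es, eps_slope = eps_slope)
}

#' ISO 18571 weighted total rating
#'
#' `R = 0.4 Ec + 0.2 Ep + 0.2 Em + 0.2 Es` with the package's default
#' weights (corridor weighted highest).
#'
#' @param Ec,Ep,Em,Es Component scores in `[0, 1]`.
#' @param weights Length-4 weights summing to 1.
#' @return Total rating in `[0, 1]`.
#' @export
total_score <- function(Ec, Ep, Em, Es,
                        weights = c(0.4, 0.2, 0.2, 0.2)) {
  comp <- c(Ec, Ep, Em, Es)
  if (any(comp < 0 | comp > 1))
    stop("component scores must lie in [0, 1]")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  sum(weights * comp)
}

#' ISO 18571 objective curve rating
#'
#' Full rating of a comparison curve `y` against a reference `x`:
#' corridor score on the raw pair, phase score over the post-onset window,
#' then DTW magnitude and slope scores on the phase-aligned curves, and
#' the weighted total. The rating is asymmetric in its arguments: the
#' corridors and the onset come from the reference.
#'
#' @param x Reference [transient_signal()].
#' @param y Comparison signal (equal length and `dt`).
#' @param weights Component weights (corridor, phase, magnitude, slope).
#' @param eps_pmax Maximum phase shift fraction.
#' @return An object of class `iso_rating`: component scores `Ec`, `Ep`,
#'   `Em`, `Es`, total `R`, weights, and diagnostics (`l_eps`, `eps_mag`,
#'   `eps_slope`, `delta_i`, `delta_o`, `tstart`, `direction`).
#' @export
iso_rate <- function(x, y, weights = c(0.4, 0.2, 0.2, 0.2),
                     eps_pmax = 0.2) {
  check_pair(x, y)
  cor <- iso_corridors(x)
  Ec <- corridor_score(x, y)
  ph <- phase_score(x, y, eps_pmax = eps_pmax)
  al <- align_curves(x, y, ph)
  mg <- magnitude_score(al$xt, al$yts)
  sl <- slope_score(mg$xw, mg$yw)
  R <- total_score(Ec, ph$Ep, mg$Em, sl$Es, weights = weights)
  structure(list(Ec = Ec, Ep = ph$Ep, Em = mg$Em, Es = sl$Es, R = R,
                 weights = weights,
                 l_eps = ph$l_eps, eps_mag = mg$eps_mag,
                 eps_slope = sl$eps_slope,
                 delta_i = cor$delta_i, delta_o = cor$delta_o,
                 tstart = ph$tstart, direction = ph$direction),
            class = "iso_rating")
}

#' @export
print.iso_rating <- function(x, ...) {
  cat(sprintf("<iso_rating> R = %.3f (Ec %.3f, Ep %.3f, Em %.3f, Es %.3f)\n",
              x$R, x$Ec, x$Ep, x$Em, x$Es))
  invisible(x)
}
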