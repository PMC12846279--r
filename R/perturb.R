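#' Energy-based probability table over wavelet coefficients
#'
#' The probability of each coefficient (band j, index i) is its squared
#' value divided by the total squared sum, so high-energy coefficients are
#' selected for perturbation with proportionally higher probability while
#' near-zero coefficients are effectively never touched.
#'
#' @param decomp A [decompose()] result with positive total energy.
#' @return A data frame with columns `band` (band label in the fixed
#'   traversal order d1..dJ, aJ), `index` (position within the band) and
#'   `p`; the `p` column sums to 1.
#' @export
coefficient_pmf <- function(decomp) {
  bands <- wavelet_bands(decomp)
  sq <- unlist(lapply(bands, function(b) b^2), use.names = FALSE)
  tot <- sum(sq)
  if (tot <= 0) stop("all-zero decomposition has no coefficient distribution")
  data.frame(
    band = rep(names(bands), vapply(bands, length, 1L)),
    index = unlist(lapply(bands, seq_along), use.names = FALSE),
    p = sq / tot,
    stringsAsFactors = FALSE)
}

#' Inverse-CDF coefficient sampling
#'
#' Given a uniform draw `u`, returns the first coefficient (in the fixed
#' traversal order of [coefficient_pmf()]) whose cumulative probability
#' reaches `u`.
#'
#' @param pmf A [coefficient_pmf()] table.
#' @param u A number in (0, 1), or a vector of such numbers.
#' @return A data frame with one row per `u`: `band`, `index`, `flat`
#'   (position in traversal order).
#' @export
cdf_sample <- function(pmf, u) {
  stopifnot(all(u > 0), all(u < 1))
  cdf <- cumsum(pmf$p)
  # smallest index with cdf >= u; guard the top against rounding
  flat <- pmin(findInterval(u, cdf, left.open = TRUE) + 1L, nrow(pmf))
  data.frame(band = pmf$band[flat], index = pmf$index[flat], flat = flat,
             stringsAsFactors = FALSE)
}

#' Perturbation settings
#'
#' `alpha` is drawn uniformly from `alpha_range` per hit and scales the
#' selected coefficient; `beta` is the ratio of noise intensity to signal
#' energy from which the Gaussian noise scale sigma is derived (see
#' [noise_sigma()]).
#'
#' @param alpha_range Length-2 range for the amplitude scaling factor,
#'   default `c(0.95, 1.05)` (mild perturbation around unity).
#' @param beta Noise-to-energy ratio in `[0.01, 0.1]` by convention;
#'   `beta = 0` disables the additive noise.
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(alpha_range = c(0.95, 1.05), beta = 0.05) {
  stopifnot(length(alpha_range) == 2L, alpha_range[1] <= alpha_range[2],
            beta >= 0)
  structure(list(alpha_range = as.numeric(alpha_range), beta = beta),
            class = "perturbation_spec")
}

#' Gaussian noise scale for coefficient perturbation
#'
#' `sigma = beta * sqrt(sum(phi^2) / (J * sum(Nj)))`: beta times a
#' root-mean-square coefficient amplitude, with the mean taken over all
#' coefficients and additionally divided by the decomposition depth J so
#' deeper decompositions inject proportionally gentler noise per hit.
#'
#' @param bands List of coefficient vectors (all bands).
#' @param beta Noise-to-energy ratio.
#' @param J Decomposition depth.
#' @return Non-negative scalar sigma.
#' @export
noise_sigma <- function(bands, beta, J) {
  energy <- sum(vapply(bands, function(b) sum(b^2), 0))
  n_coef <- sum(vapply(bands, length, 1L))
  beta * sqrt(energy / (J * n_coef))
}

#' CDF-guided perturbation of wavelet coefficients
#'
#' Repeats `n_hits` times: draw `u ~ U(0,1)`, select the coefficient by
#' inverse-CDF sampling of the energy pmf, and replace it by
#' `alpha * phi + eps` with `alpha ~ U(alpha_range)` and
#' `eps ~ N(0, sigma^2)`. The pmf and sigma are computed once from the
#' decomposition as passed in; coefficients not selected are unchanged.
#'
#' @param decomp A [decompose()] result.
#' @param spec A [perturbation_spec()].
#' @param n_hits Positive integer number of perturbation draws.
#' @return The perturbed `wavelet_decomposition`, with an attribute
#'   `"hits"`: a data frame (`band`, `index`, `alpha`, `eps`) of the draws.
#' @export
perturb <- function(decomp, spec, n_hits = 1L) {
  stopifnot(inherits(decomp, "wavelet_decomposition"),
            inherits(spec, "perturbation_spec"), n_hits >= 1L)
  bands <- wavelet_bands(decomp)
  pmf <- coefficient_pmf(decomp)
  sigma <- noise_sigma(bands, spec$beta, decomp$J)
  u <- stats::runif(n_hits)
  sel <- cdf_sample(pmf, u)
  alpha <- stats::runif(n_hits, spec$alpha_range[1], spec$alpha_range[2])
  eps <- stats::rnorm(n_hits, 0, sigma)
  for (k in seq_len(n_hits)) {
    b <- sel$band[k]; i <- sel$index[k]
    bands[[b]][i] <- alpha[k] * bands[[b]][i] + eps[k]
  }
  out <- set_bands(decomp, bands)
  attr(out, "hits") <- data.frame(band = sel$band, index = sel$index,
                                  alpha = alpha, eps = eps,
                                  stringsAsFactors = FALSE)
  out
}

# Perturbation on a raw per-channel coefficient list (one batch element),
# used inside GAN training where generated coefficients are not yet wrapped
# in a decomposition. Returns the perturbed bands plus the per-coefficient
# affine scale (1 for untouched coefficients) needed to backpropagate
# exactly through the perturbation.
perturb_bands <- function(bands, alpha_range, beta, J, n_hits) {
  lens <- vapply(bands, length, 1L)
  sq <- unlist(lapply(bands, function(b) b^2), use.names = FALSE)
  tot <- sum(sq)
  scale <- rep(1, sum(lens))
  if (tot <= 0 || n_hits < 1L)
    return(list(bands = bands, scale = scale))
  sigma <- noise_sigma(bands, beta, J)
  cdf <- cumsum(sq / tot)
  flatv <- unlist(bands, use.names = FALSE)
  u <- stats::runif(n_hits)
  flat <- pmin(findInterval(u, cdf, left.open = TRUE) + 1L, length(cdf))
  alpha <- stats::runif(n_hits, alpha_range[1], alpha_range[2])
  eps <- stats::rnorm(n_hits, 0, sigma)
  for (k in seq_len(n_hits)) {
    flatv[flat[k]] <- alpha[k] * flatv[flat[k]] + eps[k]
    scale[flat[k]] <- scale[flat[k]] * alpha[k]
  }
  offsets <- c(0L, cumsum(lens))
  out <- lapply(seq_along(bands), function(m)
    flatv[(offsets[m] + 1L):offsets[m + 1L]])
  names(out) <- names(bands)
  list(bands = out, scale = scale)
}
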