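#' Log-compressed energy curve
#'
#' Elementwise `ln(1 + E)`: compresses the large dynamic range of wavelet
#' scale energies before PCA.
#'
#' @param curve Non-negative numeric vector (a [scale_energy_curve()]).
#' @return Numeric vector of the same length.
#' @export
log_energy <- function(curve) {
  if (any(curve < 0)) stop("energies must be non-negative")
  log1p(curve)
}

#' Fit a PCA basis to log-energy curves
#'
#' Mean-centers each dimension, forms the covariance matrix of the
#' centered curves (divisor `M - 1` with `M` the curve dimension), and
#' eigendecomposes it. Eigenvalues are sorted descending; each
#' eigenvector's sign is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param curves List (or matrix rows) of equal-length numeric vectors,
#'   at least 2.
#' @param n_components Number of leading components kept for projection
#'   (default 3).
#' @return An object of class `pca_basis`: `mean`, `eigenvalues`,
#'   `vectors` (columns), `n_components`.
#' @export
pca_fit <- function(curves, n_components = 3L) {
  X <- if (is.matrix(curves)) curves else do.call(rbind, curves)
  if (nrow(X) < 2L) stop("PCA needs at least 2 curves")
  M <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / (M - 1)
  eg <- eigen(C, symmetric = TRUE)
  V <- eg$vectors
  for (l in seq_len(ncol(V))) {
    k <- which.max(abs(V[, l]))
    if (V[k, l] < 0) V[, l] <- -V[, l]
  }
  structure(list(mean = mu, eigenvalues = pmax(eg$values, 0),
                 vectors = V,
                 n_components = min(as.integer(n_components), M)),
            class = "pca_basis")
}

#' Project a log-energy curve onto the leading principal components
#'
#' @param curve Numeric vector with the basis dimension.
#' @param basis A [pca_fit()] result.
#' @return Numeric vector of length `basis$n_components`.
#' @export
pca_project <- function(curve, basis) {
  stopifnot(inherits(basis, "pca_basis"))
  if (length(curve) != length(basis$mean))
    stop("curve dimension does not match the PCA basis")
  as.numeric(crossprod(curve - basis$mean,
                       basis$vectors[, seq_len(basis$n_components),
                                     drop = FALSE]))
}

#' Predictor features for one load signal
#'
#' The full feature path: DB4 decomposition, wavelet scale energy curve,
#' `ln(1+E)` compression, projection onto the first three principal
#' components, and the energy-based condition value appended as the
#' fourth feature (it is the one scalar the augmentation model explicitly
#' controls and carries the amplitude information that drives injury
#' severity).
#'
#' @param signal A load [transient_signal()].
#' @param basis A [pca_fit()] basis fitted on the corpus log-energy
#'   curves.
#' @param Emin,Emax Corpus energy range persisted from training.
#' @param J Decomposition depth (the basis dimension must be `J + 1`).
#' @return Named numeric vector `(X1, X2, X3, c)`.
#' @export
featurize <- function(signal, basis, Emin, Emax, J = length(basis$mean) - 1L) {
  d <- decompose(signal, J = J)
  e <- scale_energy_curve(d)
  proj <- pca_project(log_energy(e), basis)
  cc <- suppressWarnings(condition_value(sum(e), Emin, Emax))
  out <- c(proj, cc)
  names(out) <- c(paste0("X", seq_along(proj)), "c")
  out
}
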