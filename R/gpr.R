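#' Assemble the hybrid training set
#'
#' Physical test rows come first, then augmented-simulation rows. A
#' simulation row is excluded when its ISO 18571 total quality score is
#' below `qc_threshold` (default 0.5) or when its load peak exceeds
#' `peak_limit` (600 g for pedal loads, 400 g for seat loads: the regime
#' in which the response model is considered distorted).
#'
#' @param test_X Matrix (or list) of physical-test feature vectors.
#' @param test_y Physical-test injury indices.
#' @param sim_X,sim_y Simulation features and indices (may be empty).
#' @param sim_qc Optional ISO total score per simulation row.
#' @param sim_peaks Optional load peak per simulation row (same units as
#'   `peak_limit`).
#' @param qc_threshold Minimum acceptable ISO total score.
#' @param peak_limit Maximum acceptable load peak, or `NULL` to skip.
#' @return A list of class `training_set`: `X`, `y`, `provenance`
#'   (`"TST"`/`"SIM"`), `n1`, `n2`, `kept` (logical over sim rows).
#' @export
gpr_assemble <- function(test_X, test_y, sim_X = NULL, sim_y = NULL,
                         sim_qc = NULL, sim_peaks = NULL,
                         qc_threshold = 0.5, peak_limit = NULL) {
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  test_X <- as_mat(test_X)
  stopifnot(nrow(test_X) == length(test_y))
  if (!is.null(sim_X) && NROW(sim_X) > 0L) {
    sim_X <- as_mat(sim_X)
    stopifnot(nrow(sim_X) == length(sim_y),
              ncol(sim_X) == ncol(test_X))
    keep <- rep(TRUE, nrow(sim_X))
    if (!is.null(sim_qc)) keep <- keep & (sim_qc >= qc_threshold)
    if (!is.null(sim_peaks) && !is.null(peak_limit))
      keep <- keep & (sim_peaks <= peak_limit)
    sim_X <- sim_X[keep, , drop = FALSE]
    sim_y <- sim_y[keep]
  } else {
    sim_X <- matrix(numeric(), 0L, ncol(test_X))
    sim_y <- numeric()
    keep <- logical()
  }
  X <- rbind(test_X, sim_X)
  y <- c(test_y, sim_y)
  if (!nrow(X)) stop("empty training set after exclusions")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite entries in the training set")
  structure(list(X = X, y = y,
                 provenance = c(rep("TST", nrow(test_X)),
                                rep("SIM", nrow(sim_X))),
                 n1 = nrow(test_X), n2 = nrow(sim_X), kept = keep),
            class = "training_set")
}

#' ARD-RBF kernel
#'
#' `k(x1, x2) = sigma_f^2 * exp(-0.5 * sum(((x1 - x2)/l)^2))` with one
#' length scale per input dimension.
#'
#' @param x1,x2 Feature vectors of equal length.
#' @param theta List with `sigma_f`, `sigma_n`, `l` (length-scale vector).
#' @return Kernel value.
#' @export
gpr_kernel <- function(x1, x2, theta) {
  check_theta(theta, length(x1))
  theta$sigma_f^2 * exp(-0.5 * sum(((x1 - x2) / theta$l)^2))
}

check_theta <- function(theta, d = NULL) {
  if (theta$sigma_f <= 0 || theta$sigma_n <= 0 || any(theta$l <= 0))
    stop("GPR hyperparameters must be strictly positive")
  if (!is.null(d) && length(theta$l) != d)
    stop("length-scale count does not match the feature dimension")
  invisible(TRUE)
}

kernel_matrix <- function(X1, X2, theta) {
  S1 <- sweep(X1, 2L, theta$l, "/")
  S2 <- sweep(X2, 2L, theta$l, "/")
  d2 <- outer(rowSums(S1^2), rowSums(S2^2), "+") - 2 * tcrossprod(S1, S2)
  theta$sigma_f^2 * exp(-0.5 * pmax(d2, 0))
}

# Cholesky of K + sigma_n^2 I with a relative jitter for conditioning.
gpr_chol <- function(X, theta, jitter_rel = 1e-8) {
  K <- kernel_matrix(X, X, theta)
  Kp <- K + (theta$sigma_n^2 + jitter_rel * mean(diag(K))) * diag(nrow(K))
  L <- tryCatch(chol(Kp), error = function(e)
    stop("kernel matrix not positive definite after jitter; ",
         "conditioning failure"))
  list(K = K, L = L)
}

#' Log marginal likelihood of a GP regression model
#'
#' `-0.5 y' (K + sigma_n^2 I)^-1 y - 0.5 log|K + sigma_n^2 I|
#'  - (n/2) log(2 pi)`, evaluated via a Cholesky factorization.
#'
#' @param X Feature matrix (rows = observations).
#' @param y Response vector.
#' @param theta Hyperparameters, see [gpr_kernel()].
#' @return Scalar log marginal likelihood.
#' @export
gpr_lml <- function(X, y, theta) {
  check_theta(theta, ncol(X))
  ch <- gpr_chol(X, theta)
  a <- backsolve(ch$L, forwardsolve(t(ch$L), y))
  -0.5 * sum(y * a) - sum(log(diag(ch$L))) -
    0.5 * length(y) * log(2 * pi)
}

# LML and its gradient w.r.t. log(sigma_f), log(sigma_n), log(l).
lml_and_grad <- function(X, y, ltheta) {
  d <- ncol(X)
  theta <- list(sigma_f = exp(ltheta[1L]), sigma_n = exp(ltheta[2L]),
                l = exp(ltheta[2L + seq_len(d)]))
  ch <- gpr_chol(X, theta)
  n <- length(y)
  Linv <- backsolve(ch$L, diag(n))
  Kinv <- tcrossprod(Linv)
  alpha <- Kinv %*% y
  lml <- -0.5 * sum(y * alpha) - sum(log(diag(ch$L))) -
    0.5 * n * log(2 * pi)
  W <- tcrossprod(alpha) - Kinv        # dL/dK = 0.5 * W (sym)
  grad <- numeric(2L + d)
  grad[1L] <- 0.5 * sum(W * (2 * ch$K))                 # d/dlog sigma_f
  grad[2L] <- 0.5 * sum(diag(W)) * 2 * theta$sigma_n^2  # d/dlog sigma_n
  S <- sweep(X, 2L, theta$l, "/")
  for (k in seq_len(d)) {
    Dk <- outer(S[, k], S[, k], "-")^2
    grad[2L + k] <- 0.5 * sum(W * (ch$K * Dk))          # d/dlog l_k
  }
  list(lml = lml, grad = grad, theta = theta)
}

#' Fit an ARD-RBF Gaussian process regressor
#'
#' Features are standardized internally (zero mean, unit variance per
#' dimension; constant dimensions are left unscaled). Hyperparameters are
#' found by multi-start gradient-based maximization of the log marginal
#' likelihood in log-hyperparameter space (L-BFGS-B with analytic
#' gradients); the start with the best final likelihood wins. Fully
#' deterministic under `seed`.
#'
#' @param X Feature matrix or `training_set`.
#' @param y Response vector (ignored when `X` is a `training_set`).
#' @param restarts Number of optimizer starts (default 5).
#' @param seed Integer seed for the start points.
#' @return An object of class `gpr_fit`: `theta` (standardized scale),
#'   `center`/`scale`, standardized `X`, `y`, the Cholesky factor and
#'   `alpha` for prediction, and `lml`.
#' @export
gpr_fit <- function(X, y = NULL, restarts = 5L, seed = 1L) {
  if (inherits(X, "training_set")) { y <- X$y; X <- X$X }
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2L, nrow(X) == length(y))
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale <= 0] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  d <- ncol(Xs)
  sy <- stats::sd(y); if (!is.finite(sy) || sy <= 0) sy <- 1
  base <- c(log(sy), log(0.1 * sy), rep(0, d))
  set.seed(seed)
  starts <- lapply(seq_len(restarts), function(r) {
    if (r == 1L) base else base + stats::rnorm(length(base), sd = 0.7)
  })
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st,
                   fn = function(p) -lml_and_grad(Xs, y, p)$lml,
                   gr = function(p) -lml_and_grad(Xs, y, p)$grad,
                   method = "L-BFGS-B",
                   lower = rep(log(1e-6), length(st)),
                   upper = rep(log(1e6), length(st)),
                   control = list(maxit = 200L)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer restarts failed")
  theta <- list(sigma_f = exp(best$par[1L]), sigma_n = exp(best$par[2L]),
                l = exp(best$par[2L + seq_len(d)]))
  ch <- gpr_chol(Xs, theta)
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), y))
  structure(list(theta = theta, center = center, scale = scale,
                 X = Xs, y = y, L = ch$L, alpha = alpha,
                 lml = -best$value),
            class = "gpr_fit")
}

#' @export
print.gpr_fit <- function(x, ...) {
  cat(sprintf("<gpr_fit> n = %d, d = %d; sigma_f = %.3g, sigma_n = %.3g, l = (%s); lml = %.3f\n",
              nrow(x$X), ncol(x$X), x$theta$sigma_f, x$theta$sigma_n,
              paste(signif(x$theta$l, 3), collapse = ", "), x$lml))
  invisible(x)
}

#' GP posterior prediction with 95% intervals
#'
#' Posterior mean and latent-function variance (observation noise
#' excluded) at new inputs; the interval is `mean +/- 1.96 * sqrt(var)`.
#'
#' @param object A [gpr_fit()].
#' @param newdata Matrix of feature vectors (raw scale), or a single
#'   vector.
#' @param ... Unused.
#' @return Data frame with columns `mean`, `variance`, `ci95_low`,
#'   `ci95_high`.
#' @export
predict.gpr_fit <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  Xs <- sweep(sweep(as.matrix(newdata), 2L, object$center), 2L,
              object$scale, "/")
  Ks <- kernel_matrix(Xs, object$X, object$theta)
  mu <- as.numeric(Ks %*% object$alpha)
  V <- forwardsolve(t(object$L), t(Ks))
  var <- pmax(object$theta$sigma_f^2 - colSums(V^2), 0)
  data.frame(mean = mu, variance = var,
             ci95_low = mu - 1.96 * sqrt(var),
             ci95_high = mu + 1.96 * sqrt(var))
}

#' Relative error in percent
#'
#' `|pred - truth| / |truth| * 100`; errors on a zero truth rather than
#' returning infinity.
#'
#' @param pred,truth Numeric scalars or vectors.
#' @return Percentage error(s).
#' @export
relative_error <- function(pred, truth) {
  if (any(truth == 0)) stop("relative error undefined for zero truth")
  abs(pred - truth) / abs(truth) * 100
}

#' Leave-one-out cross-validation of a GPR model
#'
#' Performs `n` fits, each holding out one row; reports the held-out
#' relative error per row and, per cycle, the maximum training-set
#' relative error.
#'
#' @param X Feature matrix or `training_set`.
#' @param y Responses (ignored for a `training_set`).
#' @param restarts,seed Passed to [gpr_fit()]; each fold uses the same
#'   seed so the procedure is deterministic.
#' @return A list of class `loocv_result`: `per_row` data frame
#'   (`test_re`, `train_max_re`, `provenance`), and `max_train_re`.
#' @export
gpr_loocv <- function(X, y = NULL, restarts = 5L, seed = 1L) {
  prov <- NULL
  if (inherits(X, "training_set")) { prov <- X$provenance; y <- X$y; X <- X$X }
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3L)
  if (is.null(prov)) prov <- rep("TST", n)
  test_re <- train_max_re <- numeric(n)
  for (i in seq_len(n)) {
    fit <- gpr_fit(X[-i, , drop = FALSE], y[-i], restarts = restarts,
                   seed = seed)
    pr_tr <- predict(fit, X[-i, , drop = FALSE])$mean
    train_max_re[i] <- max(relative_error(pr_tr, y[-i]))
    test_re[i] <- relative_error(predict(fit, X[i, ])$mean, y[i])
  }
  structure(list(per_row = data.frame(row = seq_len(n),
                                      provenance = prov,
                                      test_re = test_re,
                                      train_max_re = train_max_re),
                 max_train_re = max(train_max_re)),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> n = %d; median held-out RE = %.2f%%; max training RE = %.2f%%\n",
              nrow(x$per_row), stats::median(x$per_row$test_re),
              x$max_train_re))
  invisible(x)
}
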