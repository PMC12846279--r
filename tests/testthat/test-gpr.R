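test_that("the hybrid training set applies the QC and load-peak exclusions", {
  test_X <- matrix(rnorm(12), 3, 4)
  test_y <- c(5, 6, 7)
  sim_X <- matrix(rnorm(24), 6, 4)
  sim_y <- 1:6
  ts <- gpr_assemble(test_X, test_y, sim_X, sim_y,
                     sim_qc = c(0.44, 0.54, 0.9, 0.5, 0.49, 0.8),
                     sim_peaks = c(100, 100, 700, 100, 100, 100),
                     peak_limit = 600)
  # rows 1 and 5 fail QC (< 0.5), row 3 fails the peak rule
  expect_equal(ts$n1, 3)
  expect_equal(ts$n2, 3)
  expect_equal(ts$y, c(5, 6, 7, 2, 4, 6))
  expect_equal(ts$provenance, c(rep("TST", 3), rep("SIM", 3)))

  only <- gpr_assemble(test_X, test_y)
  expect_equal(only$n2, 0)
  expect_equal(nrow(only$X), 3)

  ts2 <- gpr_assemble(test_X, test_y, sim_X[1:5, ], sim_y[1:5])
  expect_equal(c(ts2$n1, ts2$n2, nrow(ts2$X)), c(3, 5, 8))
})

test_that("the ARD-RBF kernel takes its closed-form values", {
  th <- list(sigma_f = 2, sigma_n = 0.1, l = c(1, 1, 1, 1))
  x <- c(0, 0, 0, 0); y <- c(1, 1, 0, 0)        # squared distance 2
  expect_equal(gpr_kernel(x, y, th), 4 * exp(-1))
  expect_equal(gpr_kernel(x, x, th), 4)
  set.seed(2)
  a <- rnorm(4); b <- rnorm(4)
  th2 <- list(sigma_f = 1.4, sigma_n = 0.1, l = c(0.5, 1, 2, 3))
  expect_equal(gpr_kernel(a, b, th2), gpr_kernel(b, a, th2))
  expect_error(gpr_kernel(a, b, list(sigma_f = -1, sigma_n = 1,
                                     l = rep(1, 4))), "positive")
})

test_that("the log marginal likelihood matches direct dense evaluation", {
  th <- list(sigma_f = 1.5, sigma_n = 0.3, l = c(1, 2, 0.7, 1.3))
  # n = 1, y = 0 closed form (the implementation adds a tiny relative
  # jitter for conditioning, hence the loose-but-tight tolerance)
  expect_equal(gpr_lml(matrix(0, 1, 4), 0, th),
               -0.5 * log(2 * pi * (th$sigma_f^2 + th$sigma_n^2)),
               tolerance = 1e-7)

  set.seed(21)
  X <- matrix(rnorm(20), 5, 4); y <- rnorm(5)
  K <- outer(1:5, 1:5, Vectorize(function(i, j)
    gpr_kernel(X[i, ], X[j, ], th)))
  Kp <- K + (th$sigma_n^2 + 1e-8 * mean(diag(K))) * diag(5)
  direct <- -0.5 * drop(t(y) %*% solve(Kp) %*% y) -
    0.5 * as.numeric(determinant(Kp)$modulus) - 2.5 * log(2 * pi)
  expect_equal(gpr_lml(X, y, th), direct, tolerance = 1e-10)

  # invariant to row permutation
  p <- c(4, 2, 5, 1, 3)
  expect_equal(gpr_lml(X[p, ], y[p], th), gpr_lml(X, y, th),
               tolerance = 1e-10)
})

test_that("fitting maximizes the likelihood, is seeded, and recovers known hyperparameters", {
  # a design dense relative to the length scales, so the noise level is
  # statistically identifiable
  set.seed(31)
  th_star <- list(sigma_f = 2, sigma_n = 0.2, l = c(1, 1.5, 0.8, 2))
  n <- 60
  X <- matrix(runif(n * 4, -1, 1), n, 4)
  K <- outer(1:n, 1:n, Vectorize(function(i, j)
    gpr_kernel(X[i, ], X[j, ], th_star)))
  y <- drop(t(chol(K + 1e-10 * diag(n))) %*% rnorm(n)) +
    th_star$sigma_n * rnorm(n)

  fit <- gpr_fit(X, y, restarts = 4, seed = 5)
  fit2 <- gpr_fit(X, y, restarts = 4, seed = 5)
  expect_identical(fit$theta, fit2$theta)

  # the optimum beats every documented start point
  d <- ncol(X)
  sy <- sd(y)
  base <- c(log(sy), log(0.1 * sy), rep(0, d))
  Xs <- scale(X)
  attr(Xs, "scaled:center") <- attr(Xs, "scaled:scale") <- NULL
  lml_at <- function(p) gpr_lml(Xs, y, list(sigma_f = exp(p[1]),
                                            sigma_n = exp(p[2]),
                                            l = exp(p[3:6])))
  expect_gte(fit$lml + 1e-6, lml_at(base))

  # parameter recovery (inputs were generated near unit scale, so the
  # standardized-scale estimates are comparable to th_star)
  expect_lt(abs(log(fit$theta$sigma_f / th_star$sigma_f)), log(2))
  expect_lt(abs(log(fit$theta$sigma_n / th_star$sigma_n)), log(3))
  sd_x <- apply(X, 2, sd)
  expect_true(all(abs(log(fit$theta$l * sd_x / th_star$l)) < log(2)))
})

test_that("posterior limits: interpolation at data, prior reversion far away", {
  set.seed(41)
  X <- matrix(rnorm(24), 6, 4)
  y <- rowSums(X) + 0.01 * rnorm(6)
  fit <- gpr_fit(X, y, restarts = 3, seed = 2)
  pr <- predict(fit, X)
  expect_lt(max(abs(pr$mean - y)), 0.05 * diff(range(y)))
  expect_true(all(pr$variance >= 0))
  expect_true(all(pr$variance <= fit$theta$sigma_f^2 +
                    fit$theta$sigma_n^2 + 1e-9))

  far <- predict(fit, rep(500, 4))
  expect_equal(far$mean, 0, tolerance = 1e-6)
  expect_equal(far$variance, fit$theta$sigma_f^2, tolerance = 1e-6)
  expect_true(far$ci95_low <= far$mean && far$mean <= far$ci95_high)
  expect_equal(far$ci95_high - far$mean, 1.96 * sqrt(far$variance),
               tolerance = 1e-10)
})

test_that("a two-point posterior matches hand linear algebra", {
  th <- list(sigma_f = 1.2, sigma_n = 0.2, l = c(1, 1))
  X <- rbind(c(0, 0), c(1, 0))
  y <- c(1, 2)
  # hand calculation (no jitter)
  k12 <- th$sigma_f^2 * exp(-0.5)
  K <- matrix(c(th$sigma_f^2, k12, k12, th$sigma_f^2), 2) +
    th$sigma_n^2 * diag(2)
  xs <- c(0.5, 0)
  ks <- th$sigma_f^2 * exp(-0.5 * c(0.25, 0.25))
  mu_hand <- drop(ks %*% solve(K, y))
  var_hand <- th$sigma_f^2 - drop(ks %*% solve(K, ks))
  # package route with the same (fixed) hyperparameters
  ch <- blastinjury:::gpr_chol(X, th, jitter_rel = 0)
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), y))
  fit <- structure(list(theta = th, center = c(0, 0), scale = c(1, 1),
                        X = X, y = y, L = ch$L, alpha = alpha, lml = 0),
                   class = "gpr_fit")
  pr <- predict(fit, xs)
  expect_equal(pr$mean, mu_hand, tolerance = 1e-10)
  expect_equal(pr$variance, var_hand, tolerance = 1e-10)
})

test_that("adding a training point never raises posterior variance", {
  set.seed(51)
  th <- list(sigma_f = 1.5, sigma_n = 0.3, l = rep(1, 3))
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  grid <- matrix(rnorm(15), 5, 3)
  post_var <- function(Xt, yt) {
    ch <- blastinjury:::gpr_chol(Xt, th)
    fit <- structure(list(theta = th, center = rep(0, 3),
                          scale = rep(1, 3), X = Xt, y = yt, L = ch$L,
                          alpha = backsolve(ch$L,
                                            forwardsolve(t(ch$L), yt)),
                          lml = 0),
                     class = "gpr_fit")
    predict(fit, grid)$variance
  }
  v9 <- post_var(X[1:9, ], y[1:9])
  v10 <- post_var(X, y)
  expect_true(all(v10 <= v9 + 1e-9))
})

test_that("relative error is the absolute percentage formula", {
  expect_equal(relative_error(10, 10), 0)
  expect_equal(relative_error(11, 10), 10)
  expect_equal(relative_error(9.3 * 1.086, 9.3 * 1.086 / 1.086) ,
               abs(9.3 * 1.086 - 9.3) / 9.3 * 100)
  expect_equal(relative_error(-11, -10), 10)
  expect_error(relative_error(1, 0), "zero truth")
})

test_that("LOOCV performs n fits and is accurate on smooth noiseless data", {
  set.seed(61)
  n <- 30
  X <- matrix(runif(n * 4, -1, 1), n, 4)
  y <- 5 + exp(rowMeans(X)) + sin(X[, 1])
  r <- gpr_loocv(X, y, restarts = 2, seed = 3)
  expect_equal(nrow(r$per_row), n)
  expect_lt(median(r$per_row$test_re), 15)
  r2 <- gpr_loocv(X, y, restarts = 2, seed = 3)
  expect_identical(r$per_row, r2$per_row)
  expect_error(gpr_loocv(X[1:2, ], y[1:2]), "n >= 3")
})
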