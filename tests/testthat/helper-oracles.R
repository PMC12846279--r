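# Shared fixtures and independent oracles, all built in code.

# A short blast-like test signal (deterministic).
toy_signal <- function(n = 256, dt = 1e-4, channel = "pedal_load",
                       seed = 1) {
  set.seed(seed)
  t <- (seq_len(n) - 1) * dt
  x <- exp(-20 * t) * sin(2 * pi * 30 * t) +
    0.3 * exp(-300 * t) * sin(2 * pi * 1800 * t) +
    0.01 * rnorm(n)
  transient_signal(x, dt = dt, channel = channel)
}

# Independent statement of the orthonormal DB4 analysis filters.
oracle_db4_lo <- c(0.23037781330889651, 0.71484657055291567,
                   0.63088076792985892, -0.027983769416859854,
                   -0.18703481171909309, 0.030841381835560764,
                   0.032883011666885197, -0.010597401785069032)
oracle_db4_hi <- rev(oracle_db4_lo) * rep(c(1, -1), 4)

# Brute-force single-level periodized filter bank: explicit double loop
# over output index and filter tap (correlation + dyadic decimation,
# circular indexing).
oracle_dwt_level <- function(x) {
  L <- length(x)
  half <- L %/% 2
  a <- d <- numeric(half)
  for (k in seq_len(half)) {
    for (n in 0:7) {
      i <- ((2 * (k - 1) + n) %% L) + 1
      a[k] <- a[k] + oracle_db4_lo[n + 1] * x[i]
      d[k] <- d[k] + oracle_db4_hi[n + 1] * x[i]
    }
  }
  list(a = a, d = d)
}

# Brute-force DTW minimum cumulative cost (squared local cost, steps
# down/right/diagonal) by plain dynamic programming in R.
oracle_dtw_cost <- function(x, y) {
  n <- length(x); m <- length(y)
  D <- matrix(Inf, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      c0 <- (x[i] - y[j])^2
      if (i == 1 && j == 1) D[i, j] <- c0
      else D[i, j] <- c0 + min(
        if (i > 1 && j > 1) D[i - 1, j - 1] else Inf,
        if (i > 1) D[i - 1, j] else Inf,
        if (j > 1) D[i, j - 1] else Inf)
    }
  }
  D[n, m]
}

# Central finite-difference gradient of a scalar function of one network's
# flattened parameter vector, at selected indices.
fd_gradient <- function(model, which, loss_fun, idx, h = 1e-5) {
  p0 <- model$params[[which]]
  flat <- unlist(p0)
  vapply(idx, function(k) {
    up <- flat; up[k] <- up[k] + h
    dn <- flat; dn[k] <- dn[k] - h
    m_up <- model; m_up$params[[which]] <- utils::relist(up, p0)
    m_dn <- model; m_dn$params[[which]] <- utils::relist(dn, p0)
    (loss_fun(m_up) - loss_fun(m_dn)) / (2 * h)
  }, 0)
}

# Largest relative disagreement between analytic and FD gradients.
grad_rel_err <- function(analytic_flat, fd, idx) {
  a <- analytic_flat[idx]
  max(abs(a - fd) / pmax(abs(a), abs(fd), 1e-8))
}
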