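ramp_pair <- function(n = 40, slope = 1, offset = 0, scale = 1) {
  x <- transient_signal(slope * seq_len(n), channel = "tibial_force")
  y <- transient_signal(scale * slope * seq_len(n) + offset,
                        channel = "tibial_force")
  list(x = x, y = y)
}

test_that("corridors follow the 5%/50% rule and scale with the reference", {
  x <- transient_signal(c(-2, 0, 1, 0.5), channel = "tibial_force")
  cor <- iso_corridors(x)
  expect_equal(cor$Ynorm, 2)
  expect_equal(cor$delta_i, 0.1)
  expect_equal(cor$delta_o, 1.0)
  xk <- x; xk$samples <- 7 * x$samples
  cork <- iso_corridors(xk)
  expect_equal(cork$delta_i, 7 * cor$delta_i)
  expect_equal(cork$delta_o / cork$delta_i, 10)
  expect_error(iso_corridors(transient_signal(numeric(5),
                                              channel = "tibial_force")),
               "all-zero")
})

test_that("corridor score takes its closed-form values", {
  x <- transient_signal(sin((1:200) / 10), channel = "pelvis_accel")
  expect_equal(corridor_score(x, x), 1)

  cor <- iso_corridors(x)
  beyond <- x; beyond$samples <- x$samples + 2 * cor$delta_o
  expect_equal(corridor_score(x, beyond), 0)

  mid <- x; mid$samples <- x$samples + (cor$delta_i + cor$delta_o) / 2
  expect_equal(corridor_score(x, mid), 0.25)
})

test_that("phase score recovers a constructed delay", {
  # distinct pulse, delayed by a known number of samples
  n <- 500
  t <- (seq_len(n) - 1) * 1e-4
  pulse <- function(m0) exp(-((t - 0.01 - m0 * 1e-4) / 0.002)^2)
  x <- transient_signal(pulse(0), channel = "pedal_load")
  for (m0 in c(0, 7, 30)) {
    y <- transient_signal(pulse(m0), channel = "pedal_load")
    ph <- phase_score(x, y, eps_pmax = 0.2)
    L <- floor(0.2 * n)
    expect_equal(ph$l_eps, m0)
    expect_equal(ph$Ep, (L - m0) / L)
  }
  expect_equal(phase_score(x, x)$l_eps, 0)
  expect_equal(phase_score(x, x)$Ep, 1)
})

test_that("DTW magnitude agrees with the brute-force dynamic program", {
  set.seed(6)
  for (rep in 1:5) {
    xt <- cumsum(rnorm(18)); yts <- cumsum(rnorm(15))
    path <- blastinjury:::dtw_path(xt, yts)
    cost <- sum((xt[path[, 1]] - yts[path[, 2]])^2)
    expect_equal(cost, oracle_dtw_cost(xt, yts), tolerance = 1e-12)
    # path is monotone and uses only the allowed steps
    steps <- diff(path)
    expect_true(all(steps >= 0 & steps <= 1))
    expect_true(all(rowSums(steps) >= 1))
  }

  mg <- magnitude_score(1:20, (1:20) * 1.0)
  expect_equal(mg$eps_mag, 0)
  expect_equal(mg$Em, 1)

  # amplitude scaling that warping cannot remove
  mg2 <- magnitude_score(seq(0, 1, length.out = 25),
                         1.5 * seq(0, 1, length.out = 25))
  expect_gt(mg2$eps_mag, 0)
  expect_equal(mg2$Em, max(0, (0.5 - mg2$eps_mag) / 0.5))

  big <- magnitude_score(rep(c(0.1, 0.2), 10), rep(c(2, -2), 10))
  expect_equal(big$Em, 0)
})

test_that("slope score matches a direct evaluation of smoothing plus differencing", {
  # hand case: independent evaluation of the 9-point average and central
  # differences on a 20-sample curve
  set.seed(12)
  xt <- cumsum(rnorm(20)); yts <- cumsum(rnorm(20))
  sm <- function(v) {
    n <- length(v)
    vapply(seq_len(n), function(i) {
      half <- min(4, i - 1, n - i)
      mean(v[(i - half):(i + half)])
    }, 0)
  }
  cd <- function(v) {
    n <- length(v)
    c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1])
  }
  ex <- sum(abs(cd(sm(yts)) - cd(sm(xt)))) / sum(abs(cd(sm(xt))))
  sl <- slope_score(xt, yts)
  expect_equal(sl$eps_slope, ex, tolerance = 1e-12)

  expect_equal(slope_score(xt, xt)$Es, 1)

  # derivative ratio 3 on a ramp: eps_slope = 2 exactly, Es = 0
  rp <- ramp_pair(n = 30, scale = 3, offset = 5)
  sl3 <- slope_score(rp$x$samples, rp$y$samples)
  expect_equal(sl3$eps_slope, 2, tolerance = 1e-12)
  expect_equal(sl3$Es, 0)
})

test_that("the weighted total reproduces printed component combinations", {
  expect_equal(total_score(1, 1, 1, 1), 1)
  expect_equal(total_score(0, 0, 0, 0), 0)
  expect_equal(round(total_score(0.49, 0.43, 0.71, 0.79), 2), 0.58)
  expect_error(total_score(1.2, 0, 0, 0), "\\[0, 1\\]")
  expect_error(total_score(1, 1, 1, 1, weights = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
})

test_that("a full rating of a curve against itself is perfect", {
  s <- toy_signal(600, seed = 3)
  r <- iso_rate(s, s)
  expect_identical(c(r$Ec, r$Ep, r$Em, r$Es, r$R), rep(1, 5))
  expect_equal(r$l_eps, 0L)
})

test_that("the rating is asymmetric in reference and comparison", {
  s <- toy_signal(600, seed = 3)
  y <- s; y$samples <- 0.4 * s$samples + 0.05
  r_xy <- iso_rate(s, y)
  r_yx <- iso_rate(y, s)
  expect_false(isTRUE(all.equal(r_xy$R, r_yx$R)))
})

test_that("component scores stay in [0, 1] and degrade with growing noise", {
  set.seed(44)
  for (rep in 1:40) {
    x <- transient_signal(cumsum(rnorm(120)), channel = "pedal_load")
    y <- transient_signal(cumsum(rnorm(120)), channel = "pedal_load")
    r <- iso_rate(x, y)
    expect_true(all(c(r$Ec, r$Ep, r$Em, r$Es, r$R) >= 0))
    expect_true(all(c(r$Ec, r$Ep, r$Em, r$Es, r$R) <= 1))
  }

  s <- toy_signal(400, seed = 19)
  mean_R <- vapply(c(0.02, 0.1, 0.4), function(sd0) {
    mean(vapply(1:15, function(i) {
      set.seed(1000 + i)
      y <- s
      y$samples <- s$samples + rnorm(length(s$samples), sd = sd0)
      iso_rate(s, y)$R
    }, 0))
  }, 0)
  expect_true(all(diff(mean_R) < 0))
})
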