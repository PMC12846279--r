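test_that("CFC filtering has unity DC gain and zero phase lag", {
  dc <- transient_signal(rep(3, 2000), dt = 1e-4, channel = "tibial_force",
                         units = "kN")
  out <- cfc_filter(dc, "CFC600")
  expect_lt(max(abs(out$samples - 3)), 1e-6 * 3)

  t <- (0:4999) * 1e-4
  s <- transient_signal(sin(2 * pi * 50 * t), dt = 1e-4,
                        channel = "pelvis_accel")
  y <- cfc_filter(s, "CFC600")
  cc <- ccf(y$samples, s$samples, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("CFC magnitude response matches the analytic two-pass Butterworth", {
  # FFT of a centered impulse response vs |H(z)|^2 from the filter
  # coefficients
  fs <- 1e4
  for (cls in c("CFC600", "CFC1000")) {
    cutoff <- if (cls == "CFC600") 1000 else 1650
    bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
    imp <- transient_signal(replace(numeric(4096), 2048, 1), dt = 1 / fs,
                            channel = "pelvis_accel")
    h <- cfc_filter(imp, cls)$samples
    H <- abs(fft(h))[1:2048]
    w <- 2 * pi * (0:2047) / 4096
    Han <- vapply(w, function(ww) {
      z <- exp(-1i * ww)
      Mod((bf$b[1] + bf$b[2] * z + bf$b[3] * z^2) /
            (1 + bf$a[2] * z + bf$a[3] * z^2))^2
    }, 0)
    sel <- Han > 1e-3          # probe frequencies with non-negligible gain
    expect_lt(max(abs(H[sel] - Han[sel]) / Han[sel]), 0.02)
  }
})

test_that("CFC filtering rejects too-low sample rates and is linear", {
  slow <- transient_signal(rnorm(100), dt = 1e-3, channel = "tibial_force")
  expect_error(cfc_filter(slow, "CFC600"), "too low")

  set.seed(9)
  a <- rnorm(500); b <- rnorm(500)
  f <- function(v) cfc_filter(transient_signal(v, channel = "pelvis_accel"),
                              "CFC1000")$samples
  expect_equal(f(2 * a + 3 * b), 2 * f(a) + 3 * f(b), tolerance = 1e-10)
})

test_that("tibial assessment takes the compressive peak and the strict threshold", {
  z <- transient_signal(numeric(100), channel = "tibial_force")
  expect_warning(r0 <- tibial_assessment(z, filtered = TRUE),
                 "no compressive")
  expect_equal(r0$Fzp, 0)
  expect_true(r0$pass)

  mk <- function(peak) {
    t <- (0:999) * 1e-4
    transient_signal(peak * exp(-((t - 0.02) / 0.01)^2),
                     channel = "tibial_force")
  }
  expect_true(tibial_assessment(mk(5.39), filtered = TRUE)$pass)
  fail <- tibial_assessment(mk(5.40), filtered = TRUE)
  expect_false(fail$pass)
  expect_equal(fail$Fzp, 5.40)

  mixed <- transient_signal(c(numeric(10), 6.9, numeric(10), -8.0,
                              numeric(10)),
                            channel = "tibial_force")
  expect_equal(tibial_assessment(mixed, filtered = TRUE)$Fzp, 6.9)
})

test_that("DRIz matches the closed-form step overshoot and is homogeneous", {
  p <- dri_params()
  # constant compressive acceleration of A g, long enough to reach the
  # first oscillation peak
  A <- 5
  step <- transient_signal(rep(A, 20000), dt = 1e-4,
                           channel = "pelvis_accel")
  d <- dri_z(step, filtered = TRUE)
  closed <- A * (1 + exp(-p$zeta * pi / sqrt(1 - p$zeta^2)))
  expect_equal(d, closed, tolerance = 1e-3)

  expect_equal(dri_z(transient_signal(numeric(100),
                                      channel = "pelvis_accel")), 0)

  set.seed(4)
  a <- toy_signal(2000, channel = "pelvis_accel", seed = 6)
  for (k in c(0.5, 2, 7)) {
    ka <- a; ka$samples <- k * a$samples
    expect_equal(dri_z(ka), k * dri_z(a), tolerance = 1e-9)
  }
})

test_that("halving the integration step leaves DRIz essentially unchanged", {
  # same continuous step input sampled at dt and dt/2
  A <- 3
  coarse <- transient_signal(rep(A, 2000), dt = 1e-4,
                             channel = "pelvis_accel")
  fine <- transient_signal(rep(A, 4000), dt = 5e-5,
                           channel = "pelvis_accel")
  d1 <- dri_z(coarse, filtered = TRUE)
  d2 <- dri_z(fine, filtered = TRUE)
  expect_lt(abs(d1 - d2) / d2, 1e-4)
})

test_that("combined injury report applies both tolerances at their boundaries", {
  t <- (0:999) * 1e-4
  force <- transient_signal(6 * exp(-((t - 0.02) / 0.01)^2),
                            channel = "tibial_force")
  acc <- transient_signal(2 * exp(-20 * t) * sin(2 * pi * 10 * t),
                          channel = "pelvis_accel")
  r <- injury_indices(force, acc, filtered = TRUE)
  expect_false(r$Fz_pass)          # 6 kN >= 5.4 kN
  expect_true(r$DRIz_pass)
  expect_equal(r$Fzc, 5.4)
  expect_equal(r$DRIz_c, 17.7)
})
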