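toy_model <- function(seed = 7) gan_init(c(8, 6), seed = seed)

test_that("zero-parameter networks behave as the linear algebra dictates", {
  m <- toy_model()
  zero <- function(p) rapply(p, function(v) v * 0, how = "replace")
  m$params <- zero(m$params)
  lat <- list(rnorm(8), rnorm(6))
  out <- generator_forward(lat, 0.3, m)
  expect_true(all(unlist(out) == 0))
  expect_equal(discriminator_forward(lat, 0.7, m), 0.5)
})

test_that("the condition gate halves the hidden layer when its parameters are zero", {
  m <- toy_model()
  m$params$gen$Wg <- m$params$gen$Wg * 0
  m$params$gen$bg <- m$params$gen$bg * 0
  lat <- list(rnorm(8), rnorm(6))
  for (cv in c(0, 0.4, 1)) {
    cache <- blastinjury:::gen_forward_cache(m, lat, cv)
    expect_true(all(cache$G == 0.5))
    expect_equal(cache$Hg, cache$Hcat * 0.5)
  }
})

test_that("a one-channel toy generator matches hand matrix arithmetic", {
  m <- gan_init(4L, seed = 1, nh_g = 2L, nfc = 2L)
  p <- m$params$gen
  lat <- c(0.5, -1, 2, 0.25)
  cv <- 0.6
  out <- generator_forward(list(lat), cv, m)[[1]]
  h <- tanh(as.numeric(lat %*% p$W1[[1]]) + p$b1[[1]])
  g <- 1 / (1 + exp(-(p$Wg * cv + p$bg)))
  f <- tanh(as.numeric((h * g) %*% p$W2) + p$b2)
  y <- as.numeric(f %*% p$W3[[1]]) + p$b3[[1]]
  expect_equal(out, y, tolerance = 1e-12)
})

test_that("a one-channel toy discriminator matches hand matrix arithmetic", {
  m <- gan_init(4L, seed = 2, nh_d = 2L, nfc = 2L)
  p <- m$params$disc
  x <- c(1, -0.5, 0.25, 2)
  cv <- 0.3
  P <- discriminator_forward(list(x), cv, m)
  h <- tanh(as.numeric(x %*% p$W1[[1]]) + p$b1[[1]])
  f <- tanh(as.numeric(c(h, cv) %*% p$W2) + p$b2)
  yd <- sum(f * p$W3) + p$b3
  expect_equal(P, 1 / (1 + exp(-yd)), tolerance = 1e-12)
})

test_that("raising the discriminator output bias raises its probability", {
  m <- toy_model()
  x <- list(rnorm(8), rnorm(6))
  ps <- vapply(c(-1, 0, 1, 2), function(b) {
    m$params$disc$b3 <- b
    discriminator_forward(x, 0.5, m)
  }, 0)
  expect_true(all(diff(ps) > 0))
})

test_that("adversarial losses take their closed-form values", {
  l <- gan_losses(0.5, 0.5)
  expect_equal(l$L_D, 2 * log(2))
  expect_equal(l$L_G, log(2))
  expect_lt(gan_losses(1 - 1e-13, 1e-13)$L_D, 1e-10)
  expect_lt(gan_losses(0.5, 1 - 1e-13)$L_G, 1e-10)
})

test_that("SGD updates subtract eta times the gradient and reject NaN", {
  m <- toy_model()
  zero_g <- rapply(m$params$gen, function(v) v * 0, how = "replace")
  expect_equal(sgd_step(m, zero_g, which = "gen")$params$gen,
               m$params$gen)
  # scalar case: W = 1, grad = 2, eta = 0.001 -> 0.998
  m$params$disc$b3 <- 1
  g <- rapply(m$params$disc, function(v) v * 0, how = "replace")
  g$b3 <- 2
  expect_equal(sgd_step(m, g, eta = 0.001, which = "disc")$params$disc$b3,
               0.998)
  g$b3 <- NaN
  expect_error(sgd_step(m, g, which = "disc"), "non-finite")
})

test_that("analytic backprop equals central finite differences on toy nets", {
  set.seed(21)
  m <- toy_model(seed = 9)
  lat <- list(rnorm(8), rnorm(6))
  real <- list(rnorm(8) / 3, rnorm(6) / 3)
  fake <- list(rnorm(8) / 4, rnorm(6) / 4)
  cv <- 0.45

  gl <- blastinjury:::gen_loss_grads(m, lat, cv)
  gen_flat <- unlist(gl$grads)
  idx <- sort(sample(length(gen_flat), 60))
  fd <- fd_gradient(m, "gen", function(mm)
    blastinjury:::gen_loss_grads(mm, lat, cv)$loss, idx)
  expect_lt(grad_rel_err(gen_flat, fd, idx), 1e-4)

  dl <- blastinjury:::disc_loss_grads(m, real, cv, fake, cv)
  disc_flat <- unlist(dl$grads)
  idx <- sort(sample(length(disc_flat), min(60, length(disc_flat))))
  fd <- fd_gradient(m, "disc", function(mm)
    blastinjury:::disc_loss_grads(mm, real, cv, fake, cv)$loss, idx)
  expect_lt(grad_rel_err(disc_flat, fd, idx), 1e-4)
})

toy_corpus <- function(n = 4, len = 256, seed = 13) {
  set.seed(seed)
  t <- (seq_len(len) - 1) * 1e-4
  lapply(seq_len(n), function(i) {
    amp <- 0.5 + i
    transient_signal(amp * exp(-30 * t) * sin(2 * pi * (40 + 5 * i) * t) +
                       0.01 * rnorm(len),
                     channel = "pedal_load")
  })
}

test_that("training honors the 1:2 generator:discriminator update ratio", {
  cfg <- pipeline_config(wavelet_depth = 3, sample_length = 256,
                         epochs = 10, seed = 5)
  model <- train_gan(toy_corpus(), cfg)
  expect_equal(unname(model$updates["gen"]), 10L)
  expect_equal(unname(model$updates["disc"]), 20L)
})

test_that("training is bit-reproducible under a fixed seed and stays finite", {
  cfg <- pipeline_config(wavelet_depth = 3, sample_length = 256,
                         epochs = 30, seed = 17)
  m1 <- train_gan(toy_corpus(), cfg)
  m2 <- train_gan(toy_corpus(), cfg)
  expect_identical(m1$params, m2$params)
  expect_true(all(is.finite(m1$losses$L_D)))
  expect_true(all(is.finite(m1$losses$L_G)))
})

test_that("synthesized signals have the nominal length, are seeded, and hit the target condition", {
  cfg <- pipeline_config(wavelet_depth = 3, sample_length = 256,
                         epochs = 40, seed = 23)
  model <- train_gan(toy_corpus(), cfg)
  s1 <- synthesize(model, 0.6, n = 3, seed = 99)
  s2 <- synthesize(model, 0.6, n = 3, seed = 99)
  expect_identical(lapply(s1, `[[`, "samples"), lapply(s2, `[[`, "samples"))
  for (s in s1) {
    expect_length(s$samples, 256)
    d <- decompose(s, 3)
    realized <- (total_energy(d) - model$Emin) / (model$Emax - model$Emin)
    expect_equal(realized, 0.6, tolerance = 0.02)
  }
})

test_that("generated band-energy profiles resemble the training corpus", {
  # smoke-level distributional fidelity: after adversarial training the
  # mean per-band energy fractions of 50 generated signals must lie
  # within 20 percentage points of the corpus means
  cfg <- pipeline_config(wavelet_depth = 3, sample_length = 128,
                         epochs = 10000, seed = 31)
  corpus <- toy_corpus(len = 128)
  model <- train_gan(corpus, cfg)
  frac <- function(sig) {
    ec <- scale_energy_curve(decompose(sig, 3))
    ec / sum(ec)
  }
  real_mean <- rowMeans(vapply(corpus, frac, numeric(4)))
  gen <- synthesize(model, 0.5, n = 50, seed = 7)
  gen_mean <- rowMeans(vapply(gen, frac, numeric(4)))
  expect_true(all(abs(gen_mean - real_mean) < 0.20))
})
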