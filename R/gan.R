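#' Multi-channel gated conditional GAN in the wavelet domain
#'
#' Each wavelet band of a decomposed load signal is one network channel.
#' The generator maps a per-channel standard-normal latent vector (length
#' `Nj`) through a per-channel hidden layer (width `Nj/5`), a gate driven by
#' the energy condition `c`, a shared fully connected layer (width `Nj/10`
#' per channel) and per-channel linear output layers back to length `Nj`.
#' The discriminator mirrors this with hidden width `Nj/4`, receives `c` as
#' one extra unit appended to its flattened hidden vector, and ends in a
#' sigmoid. Hidden and FC layers use tanh; the generator output is linear
#' (it regresses normalized coefficients).
#'
#' @param nj Integer vector of band lengths (channels), finest detail first
#'   then the approximation band.
#' @param seed Integer seed for weight initialization.
#' @param learning_rate SGD learning rate (default 0.001).
#' @param nh_g,nh_d,nfc Optional width overrides (defaults `Nj/5`, `Nj/4`,
#'   `Nj/10`, rounded, minimum 1).
#' @return An object of class `gan_model`.
#' @export
gan_init <- function(nj, seed = 1L, learning_rate = 0.001,
                     nh_g = NULL, nh_d = NULL, nfc = NULL) {
  nj <- as.integer(nj)
  M <- length(nj)
  if (is.null(nh_g)) nh_g <- pmax(1L, as.integer(round(nj / 5)))
  if (is.null(nh_d)) nh_d <- pmax(1L, as.integer(round(nj / 4)))
  if (is.null(nfc)) nfc <- pmax(1L, as.integer(round(nj / 10)))
  set.seed(seed)
  rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)),
                                  nr, nc)
  gen <- list(
    W1 = lapply(seq_len(M), function(m) rmat(nj[m], nh_g[m])),
    b1 = lapply(seq_len(M), function(m) numeric(nh_g[m])),
    Wg = stats::rnorm(sum(nh_g), sd = 0.5),
    bg = numeric(sum(nh_g)),
    W2 = rmat(sum(nh_g), sum(nfc)),
    b2 = numeric(sum(nfc)),
    W3 = lapply(seq_len(M), function(m) rmat(nfc[m], nj[m])),
    b3 = lapply(seq_len(M), function(m) numeric(nj[m])))
  disc <- list(
    W1 = lapply(seq_len(M), function(m) rmat(nj[m], nh_d[m])),
    b1 = lapply(seq_len(M), function(m) numeric(nh_d[m])),
    W2 = rmat(sum(nh_d) + 1L, sum(nfc)),
    b2 = numeric(sum(nfc)),
    W3 = matrix(stats::rnorm(sum(nfc), sd = 1 / sqrt(sum(nfc)))),
    b3 = 0)
  structure(list(nj = nj, M = M, nh_g = nh_g, nh_d = nh_d, nfc = nfc,
                 learning_rate = learning_rate,
                 params = list(gen = gen, disc = disc)),
            class = "gan_model")
}

#' @export
print.gan_model <- function(x, ...) {
  cat(sprintf("<gan_model> %d channels, band lengths %s\n", x$M,
              paste(x$nj, collapse = "/")))
  if (!is.null(x$updates))
    cat(sprintf("  trained: %d generator / %d discriminator updates\n",
                x$updates["gen"], x$updates["disc"]))
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Coerce per-channel input (list of vectors or of B x Nj matrices) to a
# list of matrices, checking shapes.
as_channel_batch <- function(x, nj) {
  if (!is.list(x) || length(x) != length(nj))
    stop("expected a list with one element per channel")
  out <- lapply(seq_along(x), function(m) {
    v <- x[[m]]
    if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
    if (ncol(v) != nj[m])
      stop(sprintf("channel %d has length %d, expected %d", m, ncol(v),
                   nj[m]))
    v
  })
  out
}

# Split a B x sum(widths) matrix back into per-channel blocks.
split_channels <- function(mat, widths) {
  offs <- c(0L, cumsum(widths))
  lapply(seq_along(widths), function(m)
    mat[, (offs[m] + 1L):offs[m + 1L], drop = FALSE])
}

gen_forward_cache <- function(model, latent, cvals) {
  p <- model$params$gen
  X <- as_channel_batch(latent, model$nj)
  B <- nrow(X[[1L]])
  stopifnot(length(cvals) == B)
  H <- lapply(seq_len(model$M), function(m)
    tanh(sweep(X[[m]] %*% p$W1[[m]], 2L, p$b1[[m]], "+")))
  Hcat <- do.call(cbind, H)
  G <- sigmoid(outer(cvals, p$Wg) +
                 matrix(p$bg, B, length(p$bg), byrow = TRUE))
  Hg <- Hcat * G
  Fc <- tanh(sweep(Hg %*% p$W2, 2L, p$b2, "+"))
  Fch <- split_channels(Fc, model$nfc)
  Y <- lapply(seq_len(model$M), function(m)
    sweep(Fch[[m]] %*% p$W3[[m]], 2L, p$b3[[m]], "+"))
  list(X = X, Hcat = Hcat, G = G, Hg = Hg, Fc = Fc, Y = Y, c = cvals, B = B)
}

disc_forward_cache <- function(model, coeffs, cvals) {
  p <- model$params$disc
  X <- as_channel_batch(coeffs, model$nj)
  B <- nrow(X[[1L]])
  stopifnot(length(cvals) == B)
  H <- lapply(seq_len(model$M), function(m)
    tanh(sweep(X[[m]] %*% p$W1[[m]], 2L, p$b1[[m]], "+")))
  Hcat <- cbind(do.call(cbind, H), cvals)
  Fd <- tanh(sweep(Hcat %*% p$W2, 2L, p$b2, "+"))
  Yd <- as.numeric(Fd %*% p$W3) + p$b3
  list(X = X, Hcat = Hcat, Fd = Fd, Yd = Yd, P = sigmoid(Yd), B = B)
}

#' Generator forward pass
#'
#' @param latent List of per-channel latent vectors (or `B x Nj` matrices
#'   for a batch).
#' @param c Condition value(s) in `[0, 1]`, one per batch element.
#' @param model A [gan_init()] model.
#' @return List of per-channel outputs with the same shapes as `latent`
#'   (normalized wavelet coefficients).
#' @export
generator_forward <- function(latent, c, model) {
  stopifnot(inherits(model, "gan_model"))
  cache <- gen_forward_cache(model, latent, c)
  if (is.null(dim(latent[[1L]]))) lapply(cache$Y, as.numeric) else cache$Y
}

#' Discriminator forward pass
#'
#' The condition is appended as one extra unit to the flattened hidden
#' vector before the FC layer.
#'
#' @param coeffs List of per-channel coefficient vectors (or batch
#'   matrices).
#' @param c Condition value(s).
#' @param model A [gan_init()] model.
#' @return Probability (vector for batches) in (0, 1).
#' @export
discriminator_forward <- function(coeffs, c, model) {
  stopifnot(inherits(model, "gan_model"))
  disc_forward_cache(model, coeffs, c)$P
}

#' Adversarial losses
#'
#' `L_D = -log P_real - log(1 - P_fake)`, `L_G = -log P_fake`, averaged
#' over the batch. Probabilities are clamped to `[1e-12, 1 - 1e-12]` before
#' taking logs.
#'
#' @param P_real,P_fake Discriminator outputs on real and generated
#'   samples.
#' @return List with elements `L_D` and `L_G`.
#' @export
gan_losses <- function(P_real, P_fake) {
  pr <- pmin(pmax(P_real, 1e-12), 1 - 1e-12)
  pf <- pmin(pmax(P_fake, 1e-12), 1 - 1e-12)
  list(L_D = mean(-log(pr)) + mean(-log(1 - pf)), L_G = mean(-log(pf)))
}

# Backward pass through the discriminator given dL/dYd (vector over the
# batch). Returns parameter gradients and the gradient w.r.t. the input
# channels (needed when the generator loss is backpropagated).
disc_backward <- function(model, cache, dYd) {
  p <- model$params$disc
  dYd <- matrix(dYd, ncol = 1L)
  gW3 <- t(cache$Fd) %*% dYd
  gb3 <- sum(dYd)
  dFd <- (dYd %*% t(p$W3)) * (1 - cache$Fd^2)
  gW2 <- t(cache$Hcat) %*% dFd
  gb2 <- colSums(dFd)
  dHcat <- dFd %*% t(p$W2)
  nh_tot <- sum(model$nh_d)
  dH <- split_channels(dHcat[, seq_len(nh_tot), drop = FALSE], model$nh_d)
  Hch <- split_channels(cache$Hcat[, seq_len(nh_tot), drop = FALSE],
                        model$nh_d)
  gW1 <- vector("list", model$M); gb1 <- vector("list", model$M)
  dX <- vector("list", model$M)
  for (m in seq_len(model$M)) {
    dZ1 <- dH[[m]] * (1 - Hch[[m]]^2)
    gW1[[m]] <- t(cache$X[[m]]) %*% dZ1
    gb1[[m]] <- colSums(dZ1)
    dX[[m]] <- dZ1 %*% t(p$W1[[m]])
  }
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3),
       dX = dX)
}

# Backward pass through the generator given dL/dY per channel.
gen_backward <- function(model, cache, dY) {
  p <- model$params$gen
  Fch <- split_channels(cache$Fc, model$nfc)
  gW3 <- vector("list", model$M); gb3 <- vector("list", model$M)
  dF <- vector("list", model$M)
  for (m in seq_len(model$M)) {
    gW3[[m]] <- t(Fch[[m]]) %*% dY[[m]]
    gb3[[m]] <- colSums(dY[[m]])
    dF[[m]] <- dY[[m]] %*% t(p$W3[[m]])
  }
  dFc <- do.call(cbind, dF) * (1 - cache$Fc^2)
  gW2 <- t(cache$Hg) %*% dFc
  gb2 <- colSums(dFc)
  dHg <- dFc %*% t(p$W2)
  dG <- dHg * cache$Hcat
  dHcat <- dHg * cache$G
  dPre <- dG * cache$G * (1 - cache$G)          # gate pre-activation grad
  gWg <- colSums(dPre * cache$c)
  gbg <- colSums(dPre)
  dH <- split_channels(dHcat, model$nh_g)
  Hch <- split_channels(cache$Hcat, model$nh_g)
  gW1 <- vector("list", model$M); gb1 <- vector("list", model$M)
  for (m in seq_len(model$M)) {
    dZ1 <- dH[[m]] * (1 - Hch[[m]]^2)
    gW1[[m]] <- t(cache$X[[m]]) %*% dZ1
    gb1[[m]] <- colSums(dZ1)
  }
  list(W1 = gW1, b1 = gb1, Wg = gWg, bg = gbg, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3)
}

# Discriminator loss and its gradients on a batch of real and fake
# coefficient sets (fakes treated as fixed inputs).
disc_loss_grads <- function(model, real, c_real, fake, c_fake) {
  cr <- disc_forward_cache(model, real, c_real)
  cf <- disc_forward_cache(model, fake, c_fake)
  loss <- gan_losses(cr$P, cf$P)$L_D
  # d/dYd of mean(-log sigmoid(Yd)) = -(1 - P)/B ; of mean(-log(1-P)) = P/B
  br <- disc_backward(model, cr, -(1 - cr$P) / cr$B)
  bf <- disc_backward(model, cf, cf$P / cf$B)
  grads <- add_params(br$grads, bf$grads)
  list(loss = loss, grads = grads, P_real = cr$P, P_fake = cf$P)
}

# Generator loss and gradients; the generated batch may be perturbed by
# the caller (pass the perturbed coefficients plus the per-coefficient
# affine scale so the gradient is exact through the perturbation).
gen_loss_grads <- function(model, latent, cvals, perturbed = NULL) {
  gc <- gen_forward_cache(model, latent, cvals)
  Y <- if (is.null(perturbed)) gc$Y else perturbed$Y
  dc <- disc_forward_cache(model, Y, cvals)
  loss <- gan_losses(1, dc$P)$L_G
  db <- disc_backward(model, dc, -(1 - dc$P) / dc$B)
  dY <- db$dX
  if (!is.null(perturbed)) {
    scl <- split_channels(perturbed$scale, model$nj)
    dY <- lapply(seq_len(model$M), function(m) dY[[m]] * scl[[m]])
  }
  list(loss = loss, grads = gen_backward(model, gc, dY), P_fake = dc$P)
}

# Elementwise combination of two same-shaped parameter trees.
add_params <- function(a, b) {
  if (is.list(a)) return(mapply(add_params, a, b, SIMPLIFY = FALSE))
  a + b
}

#' One stochastic-gradient step
#'
#' Subtracts `eta` times each gradient from the matching parameter of the
#' selected network.
#'
#' @param model A [gan_init()] model.
#' @param grads Gradient tree with the same shape as
#'   `model$params[[which]]`.
#' @param eta Learning rate; defaults to the model's.
#' @param which `"gen"` or `"disc"`.
#' @return The updated model.
#' @export
sgd_step <- function(model, grads, eta = model$learning_rate,
                     which = c("gen", "disc")) {
  which <- match.arg(which)
  ok <- all(rapply(grads, function(g) all(is.finite(g)), how = "unlist"))
  if (!ok) stop("non-finite gradients; aborting update")
  step <- function(p, g) {
    if (is.list(p)) return(mapply(step, p, g, SIMPLIFY = FALSE))
    p - eta * g
  }
  model$params[[which]] <- step(model$params[[which]], grads)
  model
}

#' Train the wavelet-domain conditional GAN
#'
#' Decomposes each real signal (depth `config$wavelet_depth`), computes the
#' corpus energy range and per-signal condition values, then runs
#' adversarial SGD: per generator update the discriminator is updated
#' `config$update_ratio` times (default 2, the 1:2 generator:discriminator
#' ratio), each step on a batch of `config$batch` real signals (drawn with
#' replacement when the corpus is smaller than the batch) and an equal
#' number of generated ones. Generated batches receive a real-time
#' CDF-guided perturbation (1% of coefficients per batch element) before
#' the discriminator sees them; the gradient is taken exactly through the
#' perturbation's affine map. Training is fully determined by
#' `config$seed`.
#'
#' @param real_signals List of at least 2 [transient_signal()]s of equal
#'   length.
#' @param config A [pipeline_config()].
#' @param spec A [perturbation_spec()] for the real-time perturbation.
#' @return A trained `gan_model` with extra fields: `Emin`, `Emax`,
#'   `norm_scale`, `template` (decomposition structure used for
#'   reconstruction), `losses` (per-epoch mean `L_D`, `L_G`) and `updates`
#'   (generator/discriminator update counts).
#' @export
train_gan <- function(real_signals, config = pipeline_config(),
                      spec = perturbation_spec(config$alpha_range,
                                               config$beta)) {
  stopifnot(length(real_signals) >= 2L)
  lens <- vapply(real_signals, length, 1L)
  if (length(unique(lens)) != 1L)
    stop("all real signals must have the same length")
  J <- config$wavelet_depth
  decomps <- lapply(real_signals, decompose, J = J)
  energies <- vapply(decomps, total_energy, 0)
  Emin <- min(energies); Emax <- max(energies)
  if (!(Emax > Emin))
    stop("degenerate corpus: all signals have identical energy")
  cvals <- (energies - Emin) / (Emax - Emin)
  real_bands <- lapply(decomps, function(d) {
    lapply(normalized_bands(d), function(b) matrix(b, nrow = 1L))
  })
  nj <- vapply(wavelet_bands(decomps[[1L]]), length, 1L)
  n_real <- length(real_signals)
  n_coef <- sum(nj)
  n_hits <- max(1L, as.integer(round(0.01 * n_coef)))

  set.seed(config$seed)
  model <- gan_init(nj, seed = sample.int(.Machine$integer.max, 1L),
                    learning_rate = config$learning_rate)
  n_gen <- 0L; n_disc <- 0L
  iters_per_epoch <- max(1L, ceiling(n_real / config$batch))
  loss_d <- numeric(config$epochs); loss_g <- numeric(config$epochs)

  stack_real <- function(idx) {
    lapply(seq_along(nj), function(m)
      do.call(rbind, lapply(idx, function(i) real_bands[[i]][[m]])))
  }
  draw_latent <- function(B) {
    lapply(nj, function(n) matrix(stats::rnorm(B * n), B, n))
  }
  make_fake <- function(B, cv) {
    gc <- gen_forward_cache(model, draw_latent(B), cv)
    Yflat <- do.call(cbind, gc$Y)
    scale <- matrix(1, B, n_coef)
    for (b in seq_len(B)) {
      pb <- perturb_bands(split_channels(Yflat[b, , drop = FALSE], nj),
                          spec$alpha_range, spec$beta, J, n_hits)
      Yflat[b, ] <- unlist(pb$bands, use.names = FALSE)
      scale[b, ] <- pb$scale
    }
    list(Y = split_channels(Yflat, nj), cvals = cv)
  }

  for (ep in seq_len(config$epochs)) {
    ld <- 0; lg <- 0
    for (it in seq_len(iters_per_epoch)) {
      for (r in seq_len(config$update_ratio)) {
        idx <- sample.int(n_real, config$batch,
                          replace = n_real < config$batch)
        fk <- make_fake(config$batch, cvals[idx])
        dl <- disc_loss_grads(model, stack_real(idx), cvals[idx],
                              fk$Y, fk$cvals)
        model <- sgd_step(model, dl$grads, which = "disc")
        n_disc <- n_disc + 1L
        ld <- ld + dl$loss
      }
      idx <- sample.int(n_real, config$batch,
                        replace = n_real < config$batch)
      lat <- draw_latent(config$batch)
      gc <- gen_forward_cache(model, lat, cvals[idx])
      Yflat <- do.call(cbind, gc$Y)
      scale <- matrix(1, config$batch, n_coef)
      for (b in seq_len(config$batch)) {
        pb <- perturb_bands(split_channels(Yflat[b, , drop = FALSE], nj),
                            spec$alpha_range, spec$beta, J, n_hits)
        Yflat[b, ] <- unlist(pb$bands, use.names = FALSE)
        scale[b, ] <- pb$scale
      }
      gl <- gen_loss_grads(model, lat, cvals[idx],
                           perturbed = list(Y = split_channels(Yflat, nj),
                                            scale = scale))
      model <- sgd_step(model, gl$grads, which = "gen")
      n_gen <- n_gen + 1L
      lg <- lg + gl$loss
    }
    loss_d[ep] <- ld / (iters_per_epoch * config$update_ratio)
    loss_g[ep] <- lg / iters_per_epoch
    if (!is.finite(loss_d[ep]) || !is.finite(loss_g[ep]))
      stop("training diverged (non-finite loss) at epoch ", ep)
  }

  model$Emin <- Emin
  model$Emax <- Emax
  model$norm_scale <- mean(vapply(decomps, function(d) d$norm_scale, 0))
  model$template <- set_bands(decomps[[1L]],
                              lapply(wavelet_bands(decomps[[1L]]),
                                     function(b) 0 * b))
  model$spec <- spec
  model$config <- config
  model$losses <- data.frame(epoch = seq_len(config$epochs),
                             L_D = loss_d, L_G = loss_g)
  model$updates <- c(gen = n_gen, disc = n_disc)
  model
}

#' Generate augmented load signals
#'
#' Draws per-channel latents, runs the generator at the target condition,
#' optionally applies the CDF-guided perturbation, reconstructs the time
#' signal from the generated wavelet coefficients, and rescales the
#' amplitude so the realized energy-based condition value equals
#' `c_target`.
#'
#' @param model A trained [train_gan()] model.
#' @param c_target Condition value in `[0, 1]`.
#' @param n Number of signals to generate.
#' @param seed Integer seed.
#' @param apply_perturbation Apply the real-time perturbation to the
#'   generated coefficients (default `TRUE`).
#' @return A list of `n` [transient_signal()]s of length `model$template$n`.
#' @export
synthesize <- function(model, c_target, n = 1L, seed = 1L,
                       apply_perturbation = TRUE) {
  stopifnot(inherits(model, "gan_model"), !is.null(model$template),
            c_target >= 0, c_target <= 1, n >= 1L)
  if (!all(rapply(model$params, function(p) all(is.finite(p)),
                  how = "unlist")))
    stop("model parameters are not finite; was training aborted?")
  set.seed(seed)
  nj <- model$nj
  J <- model$template$J
  n_hits <- max(1L, as.integer(round(0.01 * sum(nj))))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    lat <- lapply(nj, function(len) stats::rnorm(len))
    Y <- generator_forward(lat, c_target, model)
    if (apply_perturbation)
      Y <- perturb_bands(Y, model$spec$alpha_range, model$spec$beta, J,
                         n_hits)$bands
    d <- set_bands(model$template,
                   lapply(Y, function(b) b * model$norm_scale))
    sig <- reconstruct(d)
    Et <- sum(sig$samples^2)
    Et_target <- model$Emin + c_target * (model$Emax - model$Emin)
    if (Et <= 0) stop("generated signal has zero energy")
    sig$samples <- sig$samples * sqrt(Et_target / Et)
    out[[k]] <- sig
  }
  out
}
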