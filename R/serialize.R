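# JSON (de)serialization of model bundles: every array is stored as
# {dim, data} so matrices survive the round trip exactly.

pack_tree <- function(x) {
  if (is.list(x) && !is.data.frame(x)) return(lapply(x, pack_tree))
  if (is.matrix(x)) return(list(.dim = dim(x), .data = as.numeric(x)))
  x
}

unpack_tree <- function(x) {
  if (is.list(x) && !is.null(x$.dim))
    return(matrix(unlist(x$.data), x$.dim[[1L]], x$.dim[[2L]]))
  if (is.list(x)) return(lapply(x, unpack_tree))
  x
}

#' Save a trained GAN model to a JSON bundle
#'
#' Stores all weights, the wavelet template structure, the corpus energy
#' range and the training configuration; [load_gan_model()] restores an
#' equivalent model.
#'
#' @param model A trained [train_gan()] model.
#' @param path Output path (.json).
#' @return `path`, invisibly.
#' @export
save_gan_model <- function(model, path) {
  stopifnot(inherits(model, "gan_model"))
  tpl <- model$template
  bundle <- list(
    kind = "blastinjury_gan", nj = model$nj, M = model$M,
    nh_g = model$nh_g, nh_d = model$nh_d, nfc = model$nfc,
    learning_rate = model$learning_rate,
    params = pack_tree(model$params),
    Emin = model$Emin, Emax = model$Emax, norm_scale = model$norm_scale,
    spec = unclass(model$spec), config = unclass(model$config),
    updates = as.list(model$updates),
    template = list(n = tpl$n, J = tpl$J, padded = tpl$padded,
                    dt = tpl$dt, channel = tpl$channel, units = tpl$units,
                    band_lengths = vapply(wavelet_bands(tpl), length, 1L)))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a GAN model saved by [save_gan_model()]
#'
#' @param path Path to the JSON bundle.
#' @return A `gan_model`.
#' @export
load_gan_model <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (!identical(b$kind, "blastinjury_gan"))
    stop("not a blastinjury GAN bundle: ", path)
  tpl_bands <- lapply(b$template$band_lengths, numeric)
  tpl <- structure(list(details = tpl_bands[seq_len(b$template$J)],
                        approx = tpl_bands[[b$template$J + 1L]],
                        n = b$template$n, J = b$template$J,
                        padded = as.logical(b$template$padded),
                        norm_scale = 1, dt = b$template$dt,
                        channel = b$template$channel,
                        units = b$template$units),
                   class = "wavelet_decomposition")
  model <- structure(
    list(nj = as.integer(b$nj), M = as.integer(b$M),
         nh_g = as.integer(b$nh_g), nh_d = as.integer(b$nh_d),
         nfc = as.integer(b$nfc), learning_rate = b$learning_rate,
         params = unpack_tree(b$params),
         Emin = b$Emin, Emax = b$Emax, norm_scale = b$norm_scale,
         spec = structure(list(alpha_range = as.numeric(b$spec$alpha_range),
                               beta = b$spec$beta),
                          class = "perturbation_spec"),
         config = do.call(pipeline_config, b$config),
         updates = unlist(b$updates), template = tpl),
    class = "gan_model")
  # bias vectors come back as length-1 lists of vectors in some layouts;
  # normalize numeric leaves
  model$params <- rapply(model$params, function(v)
    if (is.matrix(v)) v else as.numeric(unlist(v)), how = "replace")
  model
}

#' Save a fitted injury predictor bundle
#'
#' Bundles the PCA basis, the energy range, the standardizer and
#' hyperparameters of the GPR, and the training set with provenance.
#'
#' @param fit A [gpr_fit()].
#' @param basis The [pca_fit()] basis used for the features.
#' @param Emin,Emax Corpus energy range used for the condition feature.
#' @param training Optional `training_set` (for provenance bookkeeping).
#' @param path Output path (.json).
#' @return `path`, invisibly.
#' @export
save_predictor <- function(fit, basis, Emin, Emax, path, training = NULL) {
  stopifnot(inherits(fit, "gpr_fit"), inherits(basis, "pca_basis"))
  bundle <- list(
    kind = "blastinjury_predictor",
    theta = fit$theta, center = fit$center, scale = fit$scale,
    X = pack_tree(fit$X), y = fit$y, lml = fit$lml,
    basis = list(mean = basis$mean, eigenvalues = basis$eigenvalues,
                 vectors = pack_tree(basis$vectors),
                 n_components = basis$n_components),
    Emin = Emin, Emax = Emax,
    provenance = if (!is.null(training)) training$provenance)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an injury predictor bundle saved by [save_predictor()]
#'
#' @param path Path to the JSON bundle.
#' @return A list with elements `fit` (`gpr_fit`), `basis` (`pca_basis`),
#'   `Emin`, `Emax`, `provenance`.
#' @export
load_predictor <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (!identical(b$kind, "blastinjury_predictor"))
    stop("not a blastinjury predictor bundle: ", path)
  Xs <- unpack_tree(b$X)
  theta <- list(sigma_f = b$theta$sigma_f, sigma_n = b$theta$sigma_n,
                l = as.numeric(unlist(b$theta$l)))
  ch <- gpr_chol(Xs, theta)
  alpha <- backsolve(ch$L, forwardsolve(t(ch$L), as.numeric(b$y)))
  fit <- structure(list(theta = theta, center = as.numeric(b$center),
                        scale = as.numeric(b$scale), X = Xs,
                        y = as.numeric(b$y), L = ch$L, alpha = alpha,
                        lml = b$lml),
                   class = "gpr_fit")
  basis <- structure(list(mean = as.numeric(b$basis$mean),
                          eigenvalues = as.numeric(b$basis$eigenvalues),
                          vectors = unpack_tree(b$basis$vectors),
                          n_components = b$basis$n_components),
                     class = "pca_basis")
  list(fit = fit, basis = basis, Emin = b$Emin, Emax = b$Emax,
       provenance = b$provenance)
}
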