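#' Dual-loss autoencoder configuration
#'
#' Training hyperparameters for the phase-1 model. The defaults follow the
#' two-stage Adam recipe (batch 32; 10 epochs at learning rate 1e-4, then 10
#' refinement epochs at 1e-5). `latent_dim` defaults to 128 for desk-scale
#' images; 8192 mirrors the full-resolution feature count.
#'
#' @param latent_dim bottleneck width.
#' @param loss_weight_ce weight of the classification loss in the total loss
#'   (1 = plain sum of the two losses; 0 = reconstruction-only ablation).
#' @param batch_size minibatch size.
#' @param epochs_phase_a,lr_phase_a epochs and learning rate of the first
#'   Adam stage.
#' @param epochs_phase_b,lr_phase_b epochs and learning rate of the second
#'   (refinement) stage.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return an `ae_config` list.
#' @export
ae_config <- function(latent_dim = 128L, loss_weight_ce = 1,
                      batch_size = 32L,
                      epochs_phase_a = 10L, lr_phase_a = 1e-4,
                      epochs_phase_b = 10L, lr_phase_b = 1e-5,
                      seed = 1L) {
  stopifnot(latent_dim >= 1, loss_weight_ce >= 0, batch_size >= 1,
            epochs_phase_a >= 0, epochs_phase_b >= 0,
            lr_phase_a > 0, lr_phase_b > 0)
  structure(list(latent_dim = as.integer(latent_dim),
                 loss_weight_ce = loss_weight_ce,
                 batch_size = as.integer(batch_size),
                 epochs_phase_a = as.integer(epochs_phase_a),
                 lr_phase_a = lr_phase_a,
                 epochs_phase_b = as.integer(epochs_phase_b),
                 lr_phase_b = lr_phase_b,
                 seed = as.integer(seed)),
            class = "ae_config")
}

#' Reconstruction loss
#'
#' Mean over samples of the mean squared pixel error between inputs and
#' reconstructions.
#'
#' @param images,reconstructions numeric arrays/matrices of identical shape.
#' @return a scalar `>= 0`.
#' @export
mse_loss <- function(images, reconstructions) {
  if (!identical(dim(images), dim(reconstructions)) ||
      length(images) != length(reconstructions))
    stop("shape mismatch between images and reconstructions")
  mean((images - reconstructions)^2)
}

#' Classification loss
#'
#' Mean negative log-likelihood of the true class under predicted
#' probabilities, with probabilities clipped to `[eps, 1 - eps]`.
#'
#' @param true_labels 0/1 vector.
#' @param predicted_probs probabilities in `(0, 1)`.
#' @param eps clipping constant (default 1e-7).
#' @return a scalar `>= 0`.
#' @export
ce_loss <- function(true_labels, predicted_probs, eps = 1e-7) {
  if (any(!true_labels %in% c(0, 1))) stop("labels must be 0 or 1")
  if (length(true_labels) != length(predicted_probs)) stop("length mismatch")
  p <- pmin(pmax(predicted_probs, eps), 1 - eps)
  -mean(true_labels * log(p) + (1 - true_labels) * log(1 - p))
}

#' Total dual loss
#'
#' The training objective of the autoencoder: reconstruction loss plus the
#' (optionally weighted) classification loss. Weight 1 is the plain sum;
#' weight 0 gives the reconstruction-only ablation.
#'
#' @param l_mse,l_ce the two loss components.
#' @param weight_ce weight on the classification term (default 1).
#' @return `l_mse + weight_ce * l_ce`.
#' @export
total_loss <- function(l_mse, l_ce, weight_ce = 1) {
  stopifnot(is.finite(l_mse), is.finite(l_ce), is.finite(weight_ce))
  l_mse + weight_ce * l_ce
}

# images argument: H x W x n array or (H*W) x n matrix -> (H*W) x n matrix
as_image_matrix <- function(images, image_size = NULL) {
  if (is.matrix(images) && !is.null(image_size)) {
    if (nrow(images) != prod(image_size)) stop("image size mismatch")
    return(images)
  }
  d <- dim(images)
  if (length(d) == 3) {
    m <- images
    dim(m) <- c(d[1] * d[2], d[3])
    return(m)
  }
  if (length(d) == 2 && !is.null(image_size) && all(d == image_size))
    return(matrix(as.vector(images), ncol = 1))
  if (is.matrix(images)) return(images)
  stop("images must be an H x W x n array or a (H*W) x n matrix")
}

#' Build an (untrained) dual-loss autoencoder
#'
#' Encoder: three stride-2 3x3 convolution blocks (8, 16, 32 channels, ReLU)
#' followed by a dense map from the flattened bottleneck to the latent vector.
#' Decoder: the mirror image (dense, then three 2x upsample + convolution
#' blocks), ending in a sigmoid so reconstructions live in `[0, 1]`. Severity
#' head: three dense layers with Leaky-ReLU activations (negative slope 0.01)
#' ending in a single logit. Initialization is deterministic given the seed.
#'
#' @param config an [ae_config()].
#' @param image_size `c(H, W)`; both divisible by 8 (three halvings).
#' @return a `perifusion_ae` (untrained).
#' @export
build_ae <- function(config = ae_config(), image_size = c(32L, 32L)) {
  image_size <- as.integer(image_size)
  H <- image_size[1]; W <- image_size[2]
  if (H %% 8 != 0 || W %% 8 != 0)
    stop("image_size must be divisible by 2^3 = 8, got ", H, "x", W)
  set.seed(config$seed)
  ld <- config$latent_dim
  bott <- (H / 8) * (W / 8) * 32
  enc <- list(layer_conv(H, W, 1L, 8L, stride = 2L, act = "relu"),
              layer_conv(H / 2, W / 2, 8L, 16L, stride = 2L, act = "relu"),
              layer_conv(H / 4, W / 4, 16L, 32L, stride = 2L, act = "relu"),
              layer_dense(bott, ld, act = "linear"))
  dec <- list(layer_dense(ld, bott, act = "relu"),
              layer_upsample(H / 8, W / 8, 32L),
              layer_conv(H / 4, W / 4, 32L, 16L, stride = 1L, act = "relu"),
              layer_upsample(H / 4, W / 4, 16L),
              layer_conv(H / 2, W / 2, 16L, 8L, stride = 1L, act = "relu"),
              layer_upsample(H / 2, W / 2, 8L),
              layer_conv(H, W, 8L, 1L, stride = 1L, act = "sigmoid"))
  head <- list(layer_dense(ld, 64L, act = "leaky"),
               layer_dense(64L, 32L, act = "leaky"),
               layer_dense(32L, 1L, act = "linear"))  # logit; sigmoid applied at loss
  structure(list(enc = enc, dec = dec, head = head, config = config,
                 image_size = as.integer(image_size),
                 last_conv = 3L, history = NULL, trained = FALSE),
            class = "perifusion_ae")
}

#' @export
print.perifusion_ae <- function(x, ...) {
  cat("Dual-loss autoencoder:", paste(x$image_size, collapse = "x"),
      "input, latent", x$config$latent_dim,
      if (x$trained) "(trained)\n" else "(untrained)\n")
  invisible(x)
}

ae_forward <- function(ae, X, want_caches = FALSE) {
  fe <- net_forward(ae$enc, X)
  fd <- net_forward(ae$dec, fe$out)
  fh <- net_forward(ae$head, fe$out)
  out <- list(latent = fe$out, xhat = fd$out, logit = fh$out,
              prob = plogis(as.vector(fh$out)))
  if (want_caches) out[c("cache_enc", "cache_dec", "cache_head")] <-
    list(fe$caches, fd$caches, fh$caches)
  out
}

ae_losses <- function(ae, X, y) {
  fw <- ae_forward(ae, X)
  l_mse <- mse_loss(X, fw$xhat)
  l_ce <- ce_loss(y, fw$prob)
  c(mse = l_mse, ce = l_ce,
    total = total_loss(l_mse, l_ce, ae$config$loss_weight_ce))
}

#' Train the dual-loss autoencoder
#'
#' Joint training: per minibatch, the reconstruction gradient flows through
#' decoder and encoder while the classification gradient flows through the
#' severity head and encoder, and both update the shared encoder. Two
#' sequential Adam stages run at the configured learning rates with seeded
#' shuffling. The per-epoch loss trajectory (evaluated on the full training
#' set, including a pre-training epoch-0 row) is recorded.
#'
#' @param images H x W x n array or (H*W) x n matrix of training images.
#' @param severity_labels 0/1 vector (both classes required, >= 2 each).
#' @param config an [ae_config()].
#' @return a trained `perifusion_ae` with a `history` data.frame
#'   (`epoch`, `phase`, `lr`, `mse`, `ce`, `total`).
#' @export
train_ae <- function(images, severity_labels, config = ae_config()) {
  X <- as_image_matrix(images)
  d <- dim(images)
  image_size <- if (length(d) == 3) d[1:2] else c(as.integer(sqrt(nrow(X))),
                                                  as.integer(sqrt(nrow(X))))
  y <- as.numeric(severity_labels)
  if (length(y) != ncol(X)) stop("label/image count mismatch")
  if (min(table(factor(y, levels = c(0, 1)))) < 2)
    stop("need at least 2 subjects per severity class to train the dual loss")
  ae <- build_ae(config, image_size)
  n <- ncol(X); npix <- nrow(X)
  st_enc <- adam_init(ae$enc); st_dec <- adam_init(ae$dec); st_head <- adam_init(ae$head)
  w_ce <- config$loss_weight_ce
  hist <- list()
  l0 <- ae_losses(ae, X, y)
  hist[[1]] <- data.frame(epoch = 0L, phase = "init", lr = NA_real_,
                          mse = l0[["mse"]], ce = l0[["ce"]], total = l0[["total"]])
  t_step <- 0L; epoch_no <- 0L
  for (phase in list(list(name = "a", epochs = config$epochs_phase_a, lr = config$lr_phase_a),
                     list(name = "b", epochs = config$epochs_phase_b, lr = config$lr_phase_b))) {
    for (e in seq_len(phase$epochs)) {
      for (idx in minibatches(n, config$batch_size)) {
        Xb <- X[, idx, drop = FALSE]; yb <- y[idx]; B <- length(idx)
        fw <- ae_forward(ae, Xb, want_caches = TRUE)
        # reconstruction gradient (mean over batch and pixels)
        d_xhat <- 2 * (fw$xhat - Xb) / (npix * B)
        bw_dec <- net_backward(ae$dec, fw$cache_dec, d_xhat)
        # classification gradient on the logit (sigmoid + BCE combined)
        d_logit <- matrix(w_ce * (fw$prob - yb) / B, 1L, B)
        bw_head <- net_backward(ae$head, fw$cache_head, d_logit)
        d_latent <- bw_dec$dX + bw_head$dX
        bw_enc <- net_backward(ae$enc, fw$cache_enc, d_latent)
        t_step <- t_step + 1L
        up <- adam_step(ae$enc, bw_enc$grads, st_enc, phase$lr, t_step)
        ae$enc <- up$layers; st_enc <- up$state
        up <- adam_step(ae$dec, bw_dec$grads, st_dec, phase$lr, t_step)
        ae$dec <- up$layers; st_dec <- up$state
        up <- adam_step(ae$head, bw_head$grads, st_head, phase$lr, t_step)
        ae$head <- up$layers; st_head <- up$state
      }
      epoch_no <- epoch_no + 1L
      le <- ae_losses(ae, X, y)
      hist[[length(hist) + 1]] <- data.frame(epoch = epoch_no, phase = phase$name,
                                             lr = phase$lr, mse = le[["mse"]],
                                             ce = le[["ce"]], total = le[["total"]])
    }
  }
  ae$history <- do.call(rbind, hist)
  ae$trained <- epoch_no > 0
  ae
}

#' Encode images to latent features
#'
#' Deterministic forward pass through the trained encoder.
#'
#' @param ae a `perifusion_ae`.
#' @param images H x W x n array or (H*W) x n matrix at the training size.
#' @return n x latent_dim numeric matrix.
#' @export
encode <- function(ae, images) {
  stopifnot(inherits(ae, "perifusion_ae"))
  X <- as_image_matrix(images, ae$image_size)
  if (nrow(X) != prod(ae$image_size))
    stop("images do not match the model's input size ",
         paste(ae$image_size, collapse = "x"))
  t(net_forward(ae$enc, X)$out)
}

#' Severity probability from the autoencoder head
#'
#' @param ae a `perifusion_ae`.
#' @param images images at the training size.
#' @return vector of probabilities in `(0, 1)`.
#' @export
ae_severity_prob <- function(ae, images) {
  X <- as_image_matrix(images, ae$image_size)
  fw <- ae_forward(ae, X)
  fw$prob
}

#' Save / load an autoencoder checkpoint
#'
#' A single archive file with the configuration embedded.
#' @param ae a `perifusion_ae`.
#' @param path checkpoint path.
#' @export
save_ae <- function(ae, path) { saveRDS(ae, path); invisible(path) }

#' @rdname save_ae
#' @export
load_ae <- function(path) {
  ae <- readRDS(path)
  if (!inherits(ae, "perifusion_ae")) stop("not an autoencoder checkpoint: ", path)
  ae
}

#' Linear-probe AUC of a feature set
#'
#' Measures the class-discriminative content of frozen features: standardizes
#' them with training-half statistics, fits a closed-form ridge regression of
#' the labels on the training half, and reports the held-out AUC of the fitted
#' linear score. Used to compare dual-loss latents against the
#' reconstruction-only ablation.
#'
#' @param features n x d matrix.
#' @param labels 0/1 vector.
#' @param train_frac fraction used to fit the probe (default 0.7).
#' @param lambda ridge penalty (default 1).
#' @param seed split seed.
#' @return held-out AUC (scalar).
#' @export
linear_probe_auc <- function(features, labels, train_frac = 0.7,
                             lambda = 1, seed = 1L) {
  n <- nrow(features)
  set.seed(seed)
  perm <- sample.int(n)
  n_tr <- round(train_frac * n)
  tr <- perm[seq_len(n_tr)]; te <- perm[-seq_len(n_tr)]
  sc <- fit_scaler(features[tr, , drop = FALSE])
  Xtr <- apply_scaler(features[tr, , drop = FALSE], sc)
  Xte <- apply_scaler(features[te, , drop = FALSE], sc)
  yc <- labels[tr] - mean(labels[tr])
  w <- solve(crossprod(Xtr) + lambda * diag(ncol(Xtr)), crossprod(Xtr, yc))
  roc_auc(labels[te], as.vector(Xte %*% w))$auc
}
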