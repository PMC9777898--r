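#' Rectified linear unit
#'
#' `relu(x) = x` for `x >= 0`, else 0.
#' @param x numeric vector/matrix (finite).
#' @return same shape as `x`.
#' @export
relu <- function(x) {
  if (any(!is.finite(x))) stop("relu requires finite input")
  pmax(x, 0)
}

#' Dense layer map
#'
#' One fully connected layer: affine map followed by elementwise [relu()],
#' `u = relu(W %*% u_prev + b)`.
#'
#' @param u_prev input vector (or matrix with one column per sample).
#' @param W weight matrix (`n_out x n_in`).
#' @param b bias vector (`n_out`).
#' @return activated output.
#' @export
dense_layer <- function(u_prev, W, b) {
  u_prev <- as.matrix(u_prev)
  if (ncol(W) != nrow(u_prev)) stop("dimension mismatch: W has ", ncol(W),
                                    " columns but input has ", nrow(u_prev), " rows")
  if (length(b) != nrow(W)) stop("dimension mismatch: bias length ", length(b),
                                 " vs ", nrow(W), " output units")
  relu(W %*% u_prev + b)
}

#' Fusion classifier configuration
#'
#' Hyperparameters of the phase-2 per-chapter classifier. Defaults follow the
#' stated recipe (Adam, learning rate 1e-4, batch size 50, 300 epochs) with
#' equal branch widths so neither modality dominates the concatenation.
#'
#' @param n1_out image-branch output width.
#' @param n2_out tabular-branch output width (must be within a factor of 4 of
#'   `n1_out`).
#' @param n3_hidden hidden widths of the joint trunk.
#' @param dropout_rate dropout between the trunk's dense layers, in `[0, 1)`.
#' @param lr,batch_size,epochs Adam training recipe.
#' @param seed integer seed.
#' @return a `fusion_config` list.
#' @export
fusion_config <- function(n1_out = 32L, n2_out = 32L, n3_hidden = c(64L, 32L),
                          dropout_rate = 0.5, lr = 1e-4, batch_size = 50L,
                          epochs = 300L, seed = 1L) {
  stopifnot(n1_out >= 1, n2_out >= 1, all(n3_hidden >= 1),
            dropout_rate >= 0, dropout_rate < 1, lr > 0,
            batch_size >= 1, epochs >= 0)
  if (max(n1_out, n2_out) > 4 * min(n1_out, n2_out))
    stop("branch widths must be within a factor of 4 of each other (n1_out = ",
         n1_out, ", n2_out = ", n2_out, ")")
  structure(list(n1_out = as.integer(n1_out), n2_out = as.integer(n2_out),
                 n3_hidden = as.integer(n3_hidden), dropout_rate = dropout_rate,
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "fusion_config")
}

#' Build an (untrained) fusion classifier
#'
#' Three-branch architecture: the image branch `N1` compresses the latent
#' features, the tabular branch `N2` lifts the eight clinical features to a
#' comparable width, their outputs are concatenated, and the joint trunk `N3`
#' (dense + ReLU with dropout between dense layers) produces the chapter
#' logit. The unimodal variants drop the excluded branch; the trunk then
#' consumes the surviving branch alone.
#'
#' @param latent_dim width of the image-feature input.
#' @param n_tabular number of tabular features (default 8).
#' @param config a [fusion_config()].
#' @param mode `"fused"`, `"image"` (image-only) or `"tabular"` (tabular-only).
#' @return a `perifusion_fusion` (untrained).
#' @export
build_fusion <- function(latent_dim, n_tabular = 8L, config = fusion_config(),
                         mode = c("fused", "image", "tabular")) {
  mode <- match.arg(mode)
  stopifnot(latent_dim >= 1, n_tabular >= 1)
  set.seed(config$seed)
  n1 <- if (mode != "tabular") list(layer_dense(latent_dim, config$n1_out, "relu")) else NULL
  n2 <- if (mode != "image") list(layer_dense(n_tabular, config$n2_out, "relu")) else NULL
  concat_width <- (if (mode != "tabular") config$n1_out else 0L) +
                  (if (mode != "image") config$n2_out else 0L)
  n3 <- list()
  prev <- concat_width
  for (h in config$n3_hidden) {
    n3[[length(n3) + 1]] <- layer_dense(prev, h, "relu")
    n3[[length(n3) + 1]] <- layer_dropout(config$dropout_rate)
    prev <- h
  }
  n3[[length(n3) + 1]] <- layer_dense(prev, 1L, "linear")  # chapter logit
  structure(list(n1 = n1, n2 = n2, n3 = n3, config = config, mode = mode,
                 latent_dim = as.integer(latent_dim),
                 n_tabular = as.integer(n_tabular),
                 chapter = NULL, history = NULL, trained = FALSE),
            class = "perifusion_fusion")
}

#' @export
print.perifusion_fusion <- function(x, ...) {
  cat("Fusion classifier (", x$mode, " mode", sep = "")
  if (!is.null(x$chapter)) cat(", chapter ", x$chapter, sep = "")
  cat("):", x$latent_dim, "image +", x$n_tabular, "tabular features",
      if (x$trained) "(trained)\n" else "(untrained)\n")
  invisible(x)
}

fusion_forward <- function(model, Ximg, Xtab, train = FALSE, want_caches = FALSE) {
  parts <- list(); caches <- list(n1 = NULL, n2 = NULL)
  if (!is.null(model$n1)) {
    f1 <- net_forward(model$n1, Ximg, train = train)
    parts$img <- f1$out; caches$n1 <- f1$caches
  }
  if (!is.null(model$n2)) {
    f2 <- net_forward(model$n2, Xtab, train = train)
    parts$tab <- f2$out; caches$n2 <- f2$caches
  }
  Z <- do.call(rbind, parts)
  f3 <- net_forward(model$n3, Z, train = train)
  out <- list(prob = plogis(as.vector(f3$out)), logit = f3$out)
  if (want_caches) {
    caches$n3 <- f3$caches
    out$caches <- caches
    out$split <- vapply(parts, nrow, 0L)
  }
  out
}

check_fusion_inputs <- function(model, features_img, features_tab) {
  if (!is.null(model$n1)) {
    if (is.null(features_img)) stop("image features required in ", model$mode, " mode")
    if (ncol(features_img) != model$latent_dim)
      stop("image feature width ", ncol(features_img), " != latent_dim ", model$latent_dim)
  }
  if (!is.null(model$n2)) {
    if (is.null(features_tab)) stop("tabular features required in ", model$mode, " mode")
    if (ncol(features_tab) != model$n_tabular)
      stop("tabular feature width ", ncol(features_tab), " != ", model$n_tabular)
  }
}

#' Train a per-chapter fusion classifier
#'
#' Adam on the binary cross-entropy objective with dropout active during
#' training only. Feature matrices have one row per subject; training data
#' should already be class-balanced (see [downsample_balance()]).
#'
#' @param features_img n x latent_dim matrix (ignored in tabular mode).
#' @param features_tab n x 8 matrix (ignored in image mode).
#' @param labels 0/1 chapter labels.
#' @param config a [fusion_config()].
#' @param mode `"fused"`, `"image"` or `"tabular"`.
#' @param chapter optional chapter id stored in the model.
#' @return a trained `perifusion_fusion` with per-epoch `history`.
#' @export
train_fusion <- function(features_img, features_tab, labels,
                         config = fusion_config(),
                         mode = c("fused", "image", "tabular"),
                         chapter = NULL) {
  mode <- match.arg(mode)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("both classes must be present to train")
  latent_dim <- if (!is.null(features_img)) ncol(features_img) else 1L
  n_tabular <- if (!is.null(features_tab)) ncol(features_tab) else 1L
  model <- build_fusion(latent_dim, n_tabular, config, mode)
  model$chapter <- chapter
  check_fusion_inputs(model, features_img, features_tab)
  n <- length(y)
  Ximg <- if (!is.null(model$n1)) t(features_img) else NULL
  Xtab <- if (!is.null(model$n2)) t(features_tab) else NULL
  st1 <- if (!is.null(model$n1)) adam_init(model$n1)
  st2 <- if (!is.null(model$n2)) adam_init(model$n2)
  st3 <- adam_init(model$n3)
  hist <- numeric(config$epochs + 1)
  eval_loss <- function() {
    fw <- fusion_forward(model, Ximg, Xtab, train = FALSE)
    ce_loss(y, fw$prob)
  }
  hist[1] <- eval_loss()
  t_step <- 0L
  for (e in seq_len(config$epochs)) {
    for (idx in minibatches(n, config$batch_size)) {
      B <- length(idx)
      Xi <- if (!is.null(Ximg)) Ximg[, idx, drop = FALSE]
      Xt <- if (!is.null(Xtab)) Xtab[, idx, drop = FALSE]
      fw <- fusion_forward(model, Xi, Xt, train = TRUE, want_caches = TRUE)
      d_logit <- matrix((fw$prob - y[idx]) / B, 1L, B)
      bw3 <- net_backward(model$n3, fw$caches$n3, d_logit)
      t_step <- t_step + 1L
      # split the concatenation gradient back to the branches
      ofs <- 0L
      if (!is.null(model$n1)) {
        d1 <- bw3$dX[ofs + seq_len(fw$split[["img"]]), , drop = FALSE]
        ofs <- ofs + fw$split[["img"]]
        bw1 <- net_backward(model$n1, fw$caches$n1, d1)
        up <- adam_step(model$n1, bw1$grads, st1, config$lr, t_step)
        model$n1 <- up$layers; st1 <- up$state
      }
      if (!is.null(model$n2)) {
        d2 <- bw3$dX[ofs + seq_len(fw$split[["tab"]]), , drop = FALSE]
        bw2 <- net_backward(model$n2, fw$caches$n2, d2)
        up <- adam_step(model$n2, bw2$grads, st2, config$lr, t_step)
        model$n2 <- up$layers; st2 <- up$state
      }
      up <- adam_step(model$n3, bw3$grads, st3, config$lr, t_step)
      model$n3 <- up$layers; st3 <- up$state
    }
    hist[e + 1] <- eval_loss()
  }
  model$history <- data.frame(epoch = 0:config$epochs, ce = hist)
  model$trained <- config$epochs > 0
  model
}

#' Train a unimodal variant
#'
#' Convenience wrapper over [train_fusion()] with the excluded branch removed;
#' everything else (architecture, recipe, seed) is identical.
#'
#' @param mode `"image"` or `"tabular"`.
#' @inheritParams train_fusion
#' @return a trained `perifusion_fusion`.
#' @export
unimodal_variant <- function(mode = c("image", "tabular"), features_img = NULL,
                             features_tab = NULL, labels = NULL,
                             config = fusion_config(), chapter = NULL) {
  mode <- match.arg(mode)
  train_fusion(features_img, features_tab, labels, config, mode = mode,
               chapter = chapter)
}

#' Predict chapter probabilities
#'
#' Pure function of the trained parameters and inputs: dropout is disabled, so
#' predictions are deterministic and invariant to `dropout_rate`.
#'
#' @param object a trained `perifusion_fusion`.
#' @param features_img n x latent_dim matrix (or `NULL` in tabular mode).
#' @param features_tab n x 8 matrix (or `NULL` in image mode).
#' @param ... unused.
#' @return vector of probabilities in `(0, 1)`.
#' @export
predict.perifusion_fusion <- function(object, features_img = NULL,
                                      features_tab = NULL, ...) {
  check_fusion_inputs(object, features_img, features_tab)
  Ximg <- if (!is.null(object$n1)) t(features_img) else NULL
  Xtab <- if (!is.null(object$n2)) t(features_tab) else NULL
  fusion_forward(object, Ximg, Xtab, train = FALSE)$prob
}
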