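# Bilinear resize with corner-aligned sampling; used to lift the coarse
# class-activation grid back to input resolution.
resize_bilinear <- function(mat, out_h, out_w) {
  H <- nrow(mat); W <- ncol(mat)
  ry <- if (out_h == 1) rep(1, out_h) else seq(1, H, length.out = out_h)
  rx <- if (out_w == 1) rep(1, out_w) else seq(1, W, length.out = out_w)
  y0 <- pmin(floor(ry), H - 1L); y0[H == 1] <- 1
  x0 <- pmin(floor(rx), W - 1L); x0[W == 1] <- 1
  if (H == 1) { y0 <- rep(1, out_h); wy <- rep(0, out_h) } else wy <- ry - y0
  if (W == 1) { x0 <- rep(1, out_w); wx <- rep(0, out_w) } else wx <- rx - x0
  y1 <- pmin(y0 + 1L, H); x1 <- pmin(x0 + 1L, W)
  a <- mat[y0, x0, drop = FALSE]; b <- mat[y0, x1, drop = FALSE]
  c_ <- mat[y1, x0, drop = FALSE]; d <- mat[y1, x1, drop = FALSE]
  WY <- matrix(wy, out_h, out_w); WX <- matrix(wx, out_h, out_w, byrow = TRUE)
  a * (1 - WY) * (1 - WX) + b * (1 - WY) * WX + c_ * WY * (1 - WX) + d * WY * WX
}

#' Grad-CAM saliency for the severity classification path
#'
#' Gradient-weighted class activation mapping against the encoder's last
#' convolutional layer, with the severity head's logit as the class score:
#' channel weights are the spatial means of the score's gradient on the
#' activation map, the map is the ReLU of the weighted activation sum,
#' bilinearly upsampled to input size and min-max normalized to `[0, 1]`.
#' If every gradient is zero the map is all-zero and a warning is raised.
#'
#' @param ae a trained `perifusion_ae`.
#' @param image H x W matrix at the model's input size.
#' @param subject_id optional id stored in the result.
#' @return a `saliency_map`: list with `heat` (H x W in `[0, 1]`),
#'   `subject_id`, `layer`.
#' @export
grad_cam <- function(ae, image, subject_id = NULL) {
  stopifnot(inherits(ae, "perifusion_ae"))
  H <- ae$image_size[1]; W <- ae$image_size[2]
  X <- matrix(as.vector(image), ncol = 1)
  if (nrow(X) != H * W) stop("image does not match model input size ",
                             H, "x", W)
  li <- ae$last_conv
  fe <- net_forward(ae$enc, X)
  fh <- net_forward(ae$head, fe$out)
  # gradient of the severity logit w.r.t. the latent, then back through the
  # encoder layers above the target convolution
  bw_head <- net_backward(ae$head, fh$caches, matrix(1, 1, 1))
  d <- bw_head$dX
  for (i in rev(seq(li + 1L, length(ae$enc)))) {
    d <- layer_backward(ae$enc[[i]], fe$caches[[i]], d)$dX
  }
  A <- fe$caches[[li]]$A                       # (ho*wo*C) x 1 activations
  Cout <- ae$enc[[li]]$Cout
  g <- ae$enc[[li]]$geom
  sp <- g$Ho * g$Wo
  Amat <- matrix(A, sp, Cout)
  Gmat <- matrix(d, sp, Cout)
  wts <- colMeans(Gmat)                        # spatially averaged gradients
  cam <- pmax(Amat %*% wts, 0)
  heat <- resize_bilinear(matrix(cam, g$Ho, g$Wo), H, W)
  mx <- max(heat)
  if (mx <= 0) {
    warning("all-zero Grad-CAM map (no positive gradient contribution)")
    heat <- matrix(0, H, W)
  } else heat <- (heat - min(heat)) / (mx - min(heat))
  structure(list(heat = heat, subject_id = subject_id,
                 layer = paste0("enc_conv", li)),
            class = "saliency_map")
}

#' Lesion localization score
#'
#' Fraction of total saliency mass falling inside a binary mask. Under a
#' spatially uniform map this equals the mask's area fraction, which is the
#' chance baseline a lesion-focused model must exceed.
#'
#' @param map a `saliency_map` or an H x W heat matrix.
#' @param mask logical H x W matrix (same shape).
#' @return scalar in `[0, 1]`; `NA` (with a warning) for an empty mask or an
#'   all-zero map.
#' @export
localization_score <- function(map, mask) {
  heat <- if (inherits(map, "saliency_map")) map$heat else map
  if (!all(dim(heat) == dim(mask))) stop("map and mask shapes differ")
  if (!any(mask)) {
    warning("empty mask: localization score undefined")
    return(NA_real_)
  }
  tot <- sum(heat)
  if (tot <= 0) {
    warning("all-zero saliency map: localization score undefined")
    return(NA_real_)
  }
  sum(heat[mask]) / tot
}

#' PCA projection of the latent space
#'
#' Mean-centered projection onto the top two principal components. Component
#' signs are fixed by making each component's largest-magnitude loading
#' positive, so the projection is fully deterministic.
#'
#' @param latents n x d matrix (n >= 3, d >= 2).
#' @param labels optional vector stored alongside the coordinates.
#' @return a `latent_projection`: `coords` (n x 2), `explained` (variance
#'   fractions of the two components, nonincreasing), `labels`.
#' @export
pca_project <- function(latents, labels = NULL) {
  if (nrow(latents) < 3) stop("need at least 3 samples")
  if (ncol(latents) < 2) stop("need at least 2 latent dimensions")
  if (all(apply(latents, 2, stats::sd) < 1e-12))
    stop("zero-variance latents: PCA undefined")
  pc <- stats::prcomp(latents, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) { rot[, j] <- -rot[, j]; pc$x[, j] <- -pc$x[, j] }
  }
  ev <- pc$sdev^2
  structure(list(coords = pc$x[, 1:2, drop = FALSE],
                 explained = ev[1:2] / sum(ev),
                 labels = labels),
            class = "latent_projection")
}

#' Mean silhouette width of a 2-D projection by label
#'
#' Quantitative surrogate for "two separate clusters in the latent
#' projection": positive values mean samples sit closer to their own label
#' group than to the other.
#'
#' @param coords n x 2 coordinate matrix.
#' @param labels grouping vector with >= 2 groups.
#' @return mean silhouette width in `[-1, 1]`.
#' @export
silhouette_by_label <- function(coords, labels) {
  f <- as.integer(factor(labels))
  if (length(unique(f)) < 2) stop("need at least two label groups")
  sil <- cluster::silhouette(f, stats::dist(coords))
  mean(sil[, "sil_width"])
}

#' Write a saliency map as a grayscale PNG
#'
#' @param map a `saliency_map`.
#' @param path output path.
#' @export
write_saliency_png <- function(map, path) {
  png::writePNG(map$heat, path)
  invisible(path)
}
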