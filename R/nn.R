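# Minimal feed-forward / convolutional network engine.
#
# Everything operates on column-major design matrices: one column per sample.
# An image batch is a (H*W*C) x B matrix where each column stacks the C
# channels, each channel vectorized column-major (rows fastest).  All layers
# are plain lists; forward passes return caches that the matching backward
# pass consumes.  Randomness (init, shuffling, dropout) uses the caller's RNG
# stream so a single set.seed() makes a whole training run reproducible.

# ---- activations -----------------------------------------------------------

act_forward <- function(z, kind) {
  switch(kind,
    linear  = z,
    relu    = pmax(z, 0),
    leaky   = pmax(z, 0) + 0.01 * pmin(z, 0),
    sigmoid = plogis(z),
    stop("unknown activation: ", kind)
  )
}

# `a` is the forward output (post-activation); relu/leaky slopes are
# recoverable from its sign, sigmoid from its value.
act_backward <- function(da, a, kind) {
  switch(kind,
    linear  = da,
    relu    = da * (a > 0),
    leaky   = da * ifelse(a > 0, 1, 0.01),
    sigmoid = da * a * (1 - a),
    stop("unknown activation: ", kind)
  )
}

# ---- layer constructors ----------------------------------------------------

# He-style init scaled by fan-in; draws from the current RNG stream.
init_weights <- function(n_out, n_in) {
  matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)), n_out, n_in)
}

layer_dense <- function(n_in, n_out, act = "relu") {
  list(kind = "dense", n_in = n_in, n_out = n_out, act = act,
       W = init_weights(n_out, n_in), b = numeric(n_out))
}

# 3x3 convolution, pad 1, stride 1 or 2.  Precomputes the im2col gather
# index and its scatter inverse for the given input geometry.
conv_geom <- function(H, W, Cin, stride) {
  Hp <- H + 2L; Wp <- W + 2L
  Ho <- (H - 1L) %/% stride + 1L
  Wo <- (W - 1L) %/% stride + 1L
  tap <- as.vector(outer(0:2, 0:2, function(dr, dc) dr + dc * Hp))
  tl  <- as.vector(outer(seq_len(Ho), seq_len(Wo),
                         function(i, j) (i - 1L) * stride + 1L + (j - 1L) * stride * Hp))
  colidx <- outer(tap, tl, `+`)                       # 9 x (Ho*Wo)
  idx <- do.call(rbind, lapply(seq_len(Cin), function(ch) colidx + (ch - 1L) * Hp * Wp))
  inner1 <- as.vector(outer(2:(H + 1L), seq(2L, W + 1L),
                            function(r, cc) r + (cc - 1L) * Hp))
  inner <- as.vector(outer(inner1, (seq_len(Cin) - 1L) * Hp * Wp, `+`))
  idxvec <- as.vector(idx)
  list(H = H, W = W, Cin = Cin, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
       idxvec = idxvec, uniq = sort(unique(idxvec)), inner = inner)
}

layer_conv <- function(H, W, Cin, Cout, stride = 1L, act = "relu") {
  g <- conv_geom(H, W, Cin, stride)
  list(kind = "conv", act = act, Cout = Cout, geom = g,
       W = init_weights(Cout, 9L * Cin), b = numeric(Cout))
}

# Nearest-neighbour 2x upsampling (no parameters).
layer_upsample <- function(H, W, C) {
  Ho <- 2L * H; Wo <- 2L * W
  m1 <- as.vector(outer(seq_len(Ho), seq_len(Wo),
                        function(r, cc) ((r + 1L) %/% 2L) + (((cc + 1L) %/% 2L) - 1L) * H))
  idx <- as.vector(outer(m1, (seq_len(C) - 1L) * H * W, `+`))
  list(kind = "upsample", act = "linear", idx = idx, n_in = H * W * C)
}

layer_dropout <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  list(kind = "dropout", act = "linear", rate = rate)
}

# ---- forward / backward ----------------------------------------------------

layer_forward <- function(layer, X, train = FALSE) {
  if (layer$kind == "dense") {
    Z <- layer$W %*% X + layer$b
    A <- act_forward(Z, layer$act)
    return(list(out = A, cache = list(X = X, A = A)))
  }
  if (layer$kind == "conv") {
    g <- layer$geom; B <- ncol(X)
    Xp <- matrix(0, g$Hp * g$Wp * g$Cin, B)
    Xp[g$inner, ] <- X
    Xcol <- Xp[g$idxvec, , drop = FALSE]
    dim(Xcol) <- c(9L * g$Cin, g$Ho * g$Wo * B)
    Z <- layer$W %*% Xcol + layer$b
    dim(Z) <- c(layer$Cout, g$Ho * g$Wo, B)
    Z <- aperm(Z, c(2, 1, 3))
    dim(Z) <- c(g$Ho * g$Wo * layer$Cout, B)
    A <- act_forward(Z, layer$act)
    return(list(out = A, cache = list(Xcol = Xcol, A = A, B = B)))
  }
  if (layer$kind == "upsample") {
    return(list(out = X[layer$idx, , drop = FALSE], cache = NULL))
  }
  if (layer$kind == "dropout") {
    if (!train || layer$rate == 0) return(list(out = X, cache = list(mask = NULL)))
    keep <- 1 - layer$rate
    mask <- matrix((stats::runif(length(X)) < keep) / keep, nrow(X), ncol(X))
    return(list(out = X * mask, cache = list(mask = mask)))
  }
  stop("unknown layer kind: ", layer$kind)
}

layer_backward <- function(layer, cache, dOut) {
  if (layer$kind == "dense") {
    dZ <- act_backward(dOut, cache$A, layer$act)
    list(dX = crossprod(layer$W, dZ),
         grads = list(W = tcrossprod(dZ, cache$X), b = rowSums(dZ)))
  } else if (layer$kind == "conv") {
    g <- layer$geom; B <- cache$B
    dA <- act_backward(dOut, cache$A, layer$act)
    dim(dA) <- c(g$Ho * g$Wo, layer$Cout, B)
    dZ <- aperm(dA, c(2, 1, 3))
    dim(dZ) <- c(layer$Cout, g$Ho * g$Wo * B)
    gW <- tcrossprod(dZ, cache$Xcol)
    gb <- rowSums(dZ)
    dXcol <- crossprod(layer$W, dZ)
    dim(dXcol) <- c(length(g$idxvec), B)
    sc <- rowsum(dXcol, group = g$idxvec)
    dXp <- matrix(0, g$Hp * g$Wp * g$Cin, B)
    dXp[g$uniq, ] <- sc
    list(dX = dXp[g$inner, , drop = FALSE], grads = list(W = gW, b = gb))
  } else if (layer$kind == "upsample") {
    list(dX = rowsum(dOut, group = layer$idx), grads = NULL)
  } else if (layer$kind == "dropout") {
    if (is.null(cache$mask)) list(dX = dOut, grads = NULL)
    else list(dX = dOut * cache$mask, grads = NULL)
  } else stop("unknown layer kind: ", layer$kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

net_forward <- function(layers, X, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], X, train = train)
    X <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = X, caches = caches)
}

net_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], caches[[i]], dOut)
    dOut <- bw$dX
    grads[i] <- list(bw$grads)  # keep NULL slots for parameter-free layers
  }
  list(dX = dOut, grads = grads)
}

# ---- Adam optimizer --------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$W)) NULL
    else list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# Accumulate grads over sub-nets sharing one Adam state: sum two grad lists.
grads_add <- function(g1, g2) {
  for (i in seq_along(g1)) {
    if (is.null(g1[[i]])) next
    g1[[i]]$W <- g1[[i]]$W + g2[[i]]$W
    g1[[i]]$b <- g1[[i]]$b + g2[[i]]$b
  }
  g1
}

# Seeded minibatch index generator: list of index vectors covering a
# permutation of 1..n in chunks of batch_size.
minibatches <- function(n, batch_size) {
  perm <- sample.int(n)
  split(perm, ceiling(seq_along(perm) / batch_size))
}
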