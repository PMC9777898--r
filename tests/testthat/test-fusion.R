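test_that("relu and dense_layer follow their piecewise/affine definitions", {
  expect_equal(relu(-1), 0)
  expect_equal(relu(2), 2)
  expect_equal(relu(0), 0)
  expect_error(relu(NaN), "finite")
  u <- c(0.3, 1.2)
  expect_equal(as.vector(dense_layer(u, diag(2), c(0, 0))), u)
  expect_equal(as.vector(dense_layer(u, matrix(0, 2, 2), c(-1, -1))), c(0, 0))
  W <- matrix(c(1, -2, 0.5, 3), 2, 2); b <- c(0.1, -0.2)
  by_hand <- pmax(c(W[1, 1] * u[1] + W[1, 2] * u[2] + b[1],
                    W[2, 1] * u[1] + W[2, 2] * u[2] + b[2]), 0)
  expect_equal(as.vector(dense_layer(u, W, b)), by_hand)
  expect_error(dense_layer(u, matrix(0, 2, 3), b), "dimension mismatch")
  expect_error(dense_layer(u, W, c(1, 2, 3)), "dimension mismatch")
})

test_that("the fusion architecture concatenates equal-width branches", {
  cfg <- fusion_config(seed = 2)
  m <- build_fusion(128, 8, cfg)
  expect_equal(m$n3[[1]]$n_in, 64)                  # 32 + 32 concatenation
  expect_equal(m$n2[[1]]$n_in, 8)                   # eight clinical features
  m2 <- build_fusion(128, 8, cfg)
  expect_identical(m$n1, m2$n1)
  expect_identical(m$n3, m2$n3)
  expect_error(fusion_config(n1_out = 64, n2_out = 8), "factor of 4")
  # unimodal variants drop a branch and shrink the trunk input
  mi <- build_fusion(128, 8, cfg, mode = "image")
  expect_null(mi$n2)
  expect_equal(mi$n3[[1]]$n_in, 32)
  mt <- build_fusion(128, 8, cfg, mode = "tabular")
  expect_null(mt$n1)
  expect_equal(mt$n3[[1]]$n_in, 32)
})

test_that("training reduces the loss on separable data and is seed-deterministic", {
  set.seed(20)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  img <- matrix(rnorm(n * 16), n, 16) + y * 1.5
  tab <- matrix(rnorm(n * 8), n, 8) + y * 1.0
  cfg <- fast_fusion(seed = 20)
  m <- train_fusion(img, tab, y, cfg)
  expect_lt(m$history$ce[nrow(m$history)], m$history$ce[1])
  # zero dropout + same seed: identical histories run to run
  cfg0 <- fast_fusion(seed = 21, dropout_rate = 0)
  h1 <- train_fusion(img, tab, y, cfg0)$history
  h2 <- train_fusion(img, tab, y, cfg0)$history
  expect_identical(h1, h2)
  expect_error(train_fusion(img, tab, rep(1, n), cfg), "both classes")
})

test_that("prediction is pure, in (0,1), and invariant to dropout at eval time", {
  set.seed(21)
  n <- 80
  y <- rep(c(0, 1), n / 2)
  img <- matrix(rnorm(n * 16), n, 16) + y
  tab <- matrix(rnorm(n * 8), n, 8)
  for (rate in c(0, 0.7)) {
    m <- train_fusion(img, tab, y, fast_fusion(seed = 3, dropout_rate = rate))
    p1 <- predict(m, img, tab)
    p2 <- predict(m, img, tab)
    expect_identical(p1, p2)
    expect_true(all(p1 > 0 & p1 < 1))
  }
  m <- train_fusion(img, tab, y, fast_fusion(seed = 3))
  expect_error(predict(m, img[, 1:5], tab), "width")
})

test_that("models trained on pure noise sit near chance", {
  set.seed(22)
  n <- 200
  y <- rep(c(0, 1), n / 2)
  img <- matrix(rnorm(n * 16), n, 16)
  tab <- matrix(rnorm(n * 8), n, 8)
  tr <- 1:120; te <- 121:200
  m <- train_fusion(img[tr, ], tab[tr, ], y[tr], fast_fusion(seed = 5))
  auc <- roc_auc(y[te], predict(m, img[te, ], tab[te, ]))$auc
  expect_lt(abs(auc - 0.5), 0.17)  # Monte-Carlo band for 40/40 test subjects
})

test_that("unimodal variants see only their own modality's signal", {
  set.seed(23)
  n <- 160
  y <- rep(c(0, 1), n / 2)
  img <- matrix(rnorm(n * 16), n, 16)            # image carries no signal
  tab <- matrix(rnorm(n * 8), n, 8) + y * 1.5    # tabular carries all of it
  tr <- 1:100; te <- 101:160
  mi <- unimodal_variant("image", features_img = img[tr, ], labels = y[tr],
                         config = fast_fusion(seed = 6))
  mt <- unimodal_variant("tabular", features_tab = tab[tr, ], labels = y[tr],
                         config = fast_fusion(seed = 6))
  auc_i <- roc_auc(y[te], predict(mi, features_img = img[te, ]))$auc
  auc_t <- roc_auc(y[te], predict(mt, features_tab = tab[te, ]))$auc
  expect_lt(abs(auc_i - 0.5), 0.2)
  expect_gt(auc_t, 0.75)
})
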