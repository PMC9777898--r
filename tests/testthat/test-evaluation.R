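test_that("AUC equals the pairwise Mann-Whitney count with tie credit", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.8, 0.7, 0.3, 0.2))$auc, 0.75)
  set.seed(30)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), sample(0:2, 1))   # coarse rounding induces ties
    expect_equal(roc_auc(y, s)$auc, auc_bruteforce(y, s))
  }
  expect_error(roc_auc(rep(1, 4), runif(4)), "both classes")
})

test_that("ROC curves run from (0,0) to (1,1) and are monotone", {
  set.seed(31)
  r <- roc_auc(rbinom(40, 1, 0.5), round(rnorm(40), 1))
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$thresholds) <= 0))
})

test_that("DeLong intervals contain the point AUC and shrink with n", {
  set.seed(32)
  width_at <- function(n) {
    mean(replicate(30, {
      y <- rep(c(0, 1), each = n / 2)
      ci <- auc_ci(y, rnorm(n) + y * 0.8)
      ci$hi - ci$lo
    }))
  }
  y <- rep(c(0, 1), each = 30)
  s <- rnorm(60) + y
  ci <- auc_ci(y, s)
  expect_true(ci$lo <= ci$auc && ci$auc <= ci$hi)
  expect_false(ci$degenerate)
  expect_gt(width_at(40), width_at(160))
  # symmetric null case
  ci0 <- auc_ci(rep(c(0, 1), 50), rep(c(0.4, 0.6, 0.5, 0.5), 25))
  expect_lt(abs((ci0$hi - ci0$auc) - (ci0$auc - ci0$lo)), 0.02)
  # perfect separation at tiny n degenerates and is widened + flagged
  expect_warning(ci1 <- auc_ci(c(0, 0, 1, 1), c(1, 2, 3, 4)), "degenerate")
  expect_true(ci1$degenerate)
  expect_lt(ci1$lo, 1)
})

test_that("the paired DeLong test is symmetric and exact for identical models", {
  set.seed(33)
  y <- rep(c(0, 1), each = 25)
  a <- rnorm(50) + y * 0.8
  b <- rnorm(50) + y * 0.4
  d0 <- delong_test(y, a, a)
  expect_equal(d0$z, 0)
  expect_equal(d0$p_two_sided, 1)
  d1 <- delong_test(y, a, b)
  d2 <- delong_test(y, b, a)
  expect_equal(d1$p_two_sided, d2$p_two_sided)
  expect_equal(d1$z, -d2$z)
  expect_error(delong_test(y, a, b[1:10]), "aligned")
})

test_that("DeLong machinery agrees with the pROC reference implementation", {
  set.seed(34)
  y <- rep(c(0, 1), each = 40)
  a <- rnorm(80) + y * 0.9
  b <- rnorm(80) + y * 0.5
  ci <- auc_ci(y, a)
  ref_ci <- as.numeric(pROC::ci.auc(pROC::roc(y, a, quiet = TRUE), method = "delong"))
  expect_equal(c(ci$lo, ci$auc, ci$hi), ref_ci, tolerance = 1e-10)
  p_ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                          pROC::roc(y, b, quiet = TRUE),
                          method = "delong")$p.value
  expect_equal(delong_test(y, a, b)$p_two_sided, p_ref, tolerance = 1e-10)
})

test_that("the single-AUC DeLong variance tracks the bootstrap at n = 200", {
  set.seed(35)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  s <- rnorm(n) + y
  v <- auc_ci(y, s)$var
  bs <- replicate(1500, {
    idx <- c(sample(which(y == 0), n / 2, TRUE), sample(which(y == 1), n / 2, TRUE))
    roc_auc(y[idx], s[idx])$auc
  })
  expect_lt(abs(v - var(bs)) / var(bs), 0.15)
})

test_that("cross-validation scores each fold once on held-out subjects", {
  set.seed(36)
  ids <- sprintf("s%03d", 1:100)
  y <- rep(c(0, 1), 50); names(y) <- ids
  X <- matrix(rnorm(300), 100, 3,
              dimnames = list(ids, NULL))
  X[, 1] <- X[, 1] + 3 * y                      # strong signal
  plan <- make_split(ids, y, seed = 1)
  ridge_trainer <- function(Xtr, ytr, fold) {
    w <- solve(crossprod(Xtr) + diag(3), crossprod(Xtr, ytr - mean(ytr)))
    function(Xv) as.vector(Xv %*% w)
  }
  cv <- cross_validate(X, y, plan, ridge_trainer)
  expect_length(cv$fold_aucs, 10)
  expect_gt(cv$mean, 0.9)
  # label permutation destroys the signal
  yp <- sample(y); names(yp) <- ids
  cvp <- cross_validate(X, yp, plan, ridge_trainer)
  expect_lt(abs(cvp$mean - 0.5), 0.2)
})

test_that("threshold metrics reproduce the F1 identity and confusion layout", {
  # harmonic-mean identity at the printed precisions of typical reports
  expect_equal(round(2 * 0.85 * 0.93 / (0.85 + 0.93), 2), 0.89)
  expect_equal(round(2 * 0.71 * 0.77 / (0.71 + 0.77), 2), 0.74)
  y <- c(1, 1, 1, 0, 0, 0, 1, 0)
  s <- c(0.9, 0.8, 0.4, 0.3, 0.6, 0.1, 0.7, 0.2)
  tm <- threshold_metrics(y, s)
  expect_equal(tm$counts[["tp"]], 3)
  expect_equal(tm$counts[["fn"]], 1)
  expect_equal(tm$counts[["fp"]], 1)
  expect_equal(tm$f1, 2 * tm$precision * tm$sensitivity /
                 (tm$precision + tm$sensitivity))
  expect_equal(rowSums(tm$confusion), c(`0` = 1, `1` = 1))
  # sensitivity + FNR = 1 and specificity + FPR = 1 by construction
  expect_equal(tm$sensitivity + tm$confusion["1", "0"], 1)
  expect_equal(tm$specificity + tm$confusion["0", "1"], 1)
  perfect <- threshold_metrics(y, y)
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                "precision", "f1")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 precision = 1, f1 = 1))
  expect_equal(perfect$confusion, diag(2), ignore_attr = TRUE)
  none <- threshold_metrics(y, rep(0.1, 8), threshold = 0.5)
  expect_true(is.na(none$precision))
  expect_true(is.na(none$f1))
})

test_that("chapter evaluation refuses leakage and reports refit spread", {
  set.seed(37)
  co <- generate_cohort(tiny_spec(n = 120, seed = 12))
  ids <- co$tabular$subject_id
  z <- matrix(rnorm(120 * 16), 120, 16, dimnames = list(ids, NULL))
  z[, 1] <- z[, 1] + 2 * co$chapters$ch_IX
  ftab <- tabular_features(mean_impute(co$tabular))
  y <- co$chapters$ch_IX; names(y) <- ids
  plan <- make_split(ids, co$severity, seed = 12)
  rep1 <- evaluate_chapter("ch_IX", z, ftab, y, plan, fast_fusion(seed = 12),
                           n_refits = 2, run_cv = FALSE)
  expect_length(rep1$test$sd, 6)
  expect_true(all(is.finite(rep1$test$mean[c("auc", "accuracy")])))
  expect_equal(rep1$test$mean[["f1"]],
               mean(apply(rep1$refit_scores, 2, function(s) {
                 tm <- threshold_metrics(y[plan$test_ids], s)
                 2 * tm$precision * tm$sensitivity / (tm$precision + tm$sensitivity)
               })))
  # determinism: identical call, identical report
  rep2 <- evaluate_chapter("ch_IX", z, ftab, y, plan, fast_fusion(seed = 12),
                           n_refits = 2, run_cv = FALSE)
  expect_identical(rep1$refit_scores, rep2$refit_scores)
  bad_plan <- plan; bad_plan$test_ids[1] <- plan$train_ids[1]
  expect_error(evaluate_chapter("ch_IX", z, ftab, y, bad_plan,
                                fast_fusion(), run_cv = FALSE), "leakage")
})
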