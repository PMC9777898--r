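#' ROC curve and AUC
#'
#' Builds the ROC curve over all distinct score thresholds (descending) and
#' computes the AUC as the Mann-Whitney statistic: the proportion of
#' (positive, negative) pairs ranked correctly, with half credit for ties
#' (midrank convention).
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores finite numeric scores, higher = more positive.
#' @return a `roc_curve`: list with `thresholds`, `fpr`, `tpr` (curve points
#'   from (0,0) to (1,1)), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(labels, scores) {
  y <- as.numeric(labels)
  if (length(y) != length(scores)) stop("length mismatch")
  if (any(!is.finite(scores))) stop("scores must be finite")
  m <- sum(y == 1); n <- sum(y == 0)
  if (m == 0 || n == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)                       # midranks
  auc <- (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  last <- !duplicated(ss, fromLast = TRUE)  # last occurrence of each threshold
  tp <- cumsum(ys)[last]; fp <- cumsum(1 - ys)[last]
  structure(list(thresholds = c(Inf, ss[last]),
                 fpr = c(0, fp / n), tpr = c(0, tp / m),
                 auc = auc, n_pos = m, n_neg = n),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (%d positives, %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

# DeLong placement values (structural components), midrank convention:
#   V10[i] = P-hat(score_pos_i > score_neg) ; V01[j] = P-hat(score_pos > score_neg_j)
delong_placements <- function(labels, scores) {
  y <- as.numeric(labels)
  m <- sum(y == 1); n <- sum(y == 0)
  r_all <- rank(scores)
  r_pos <- rank(scores[y == 1]); r_neg <- rank(scores[y == 0])
  V10 <- (r_all[y == 1] - r_pos) / n
  V01 <- 1 - (r_all[y == 0] - r_neg) / m
  auc <- mean(V10)
  list(V10 = V10, V01 = V01, auc = auc, m = m, n = n)
}

#' DeLong confidence interval for a single AUC
#'
#' Normal-approximation interval using the DeLong structural-components
#' variance estimator, clipped to `[0, 1]`. When the empirical variance
#' degenerates to zero (e.g. AUC exactly 1 at small n), a continuity rule
#' shrinks the AUC toward 1/2 by half a pair before computing a fallback
#' variance, and the interval is flagged.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @param alpha two-sided error rate (default 0.05 for a 95% interval).
#' @return list with `auc`, `lo`, `hi`, `var`, `alpha`, `degenerate`.
#' @export
auc_ci <- function(labels, scores, alpha = 0.05) {
  pl <- delong_placements(labels, scores)
  v <- stats::var(pl$V10) / pl$m + stats::var(pl$V01) / pl$n
  degenerate <- !is.finite(v) || v <= 0
  if (degenerate) {
    ac <- (pl$m * pl$n * pl$auc + 0.5 * sign(0.5 - pl$auc)) / (pl$m * pl$n)
    if (pl$auc == 0.5) ac <- 0.5
    v <- max(ac * (1 - ac) / min(pl$m, pl$n), 1 / (pl$m * pl$n)^2)
    warning("degenerate DeLong variance; interval widened by continuity rule")
  }
  z <- stats::qnorm(1 - alpha / 2)
  list(auc = pl$auc,
       lo = max(0, pl$auc - z * sqrt(v)),
       hi = min(1, pl$auc + z * sqrt(v)),
       var = v, alpha = alpha, degenerate = degenerate)
}

#' DeLong paired AUC comparison test
#'
#' Two-sided nonparametric comparison of two correlated AUCs computed from
#' the same subjects, using the covariance of the models' placement values.
#' The null hypothesis is no difference in AUC.
#'
#' @param labels 0/1 vector (same subjects under both models).
#' @param scores_a,scores_b scores of the two models, aligned with `labels`.
#' @return a `delong_result`: `auc_a`, `auc_b`, `var_diff`, `z`,
#'   `p_two_sided`, `degenerate`.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels))
    stop("scores must be aligned with labels (same subjects under both models)")
  pa <- delong_placements(labels, scores_a)
  pb <- delong_placements(labels, scores_b)
  s10 <- stats::cov(cbind(pa$V10, pb$V10))
  s01 <- stats::cov(cbind(pa$V01, pb$V01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  diff <- pa$auc - pb$auc
  degenerate <- FALSE
  if (v <= 0) {
    if (abs(diff) < 1e-12) { z <- 0; p <- 1 }
    else {
      degenerate <- TRUE
      warning("zero paired variance with nonzero AUC difference")
      z <- sign(diff) * Inf; p <- 0
    }
  } else {
    z <- diff / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = max(v, 0),
                 z = z, p_two_sided = p, degenerate = degenerate),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong paired test: AUC %.4f vs %.4f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$z, x$p_two_sided))
  invisible(x)
}

#' K-fold cross-validation of a scoring model
#'
#' Runs the trainer on each fold's complement and scores the held-out fold;
#' validation sets never overlap. Folds whose validation set lacks a class
#' are skipped with a warning and reported as `NA`.
#'
#' @param features n x d matrix with rownames = subject ids.
#' @param labels 0/1 vector aligned with the rows.
#' @param split_plan a [make_split()] plan; only its training ids and fold
#'   assignments are used.
#' @param trainer `function(X_train, y_train, fold)` returning a scorer
#'   `function(X) -> numeric scores`.
#' @return list with `fold_aucs` (length k, `NA` for skipped folds), `mean`,
#'   `sd`, `ci` (normal interval over folds).
#' @export
cross_validate <- function(features, labels, split_plan, trainer) {
  stopifnot(inherits(split_plan, "split_plan"))
  ids <- rownames(features)
  if (is.null(ids)) stop("features must carry subject ids as rownames")
  names(labels) <- ids
  k <- split_plan$k
  folds <- split_plan$fold_assignments
  aucs <- rep(NA_real_, k)
  for (f in 0:(k - 1)) {
    val_ids <- names(folds)[folds == f]
    tr_ids <- setdiff(split_plan$train_ids, val_ids)
    yv <- labels[val_ids]
    if (length(unique(yv)) < 2) {
      warning("fold ", f, " skipped: single-class validation set")
      next
    }
    scorer <- trainer(features[tr_ids, , drop = FALSE], labels[tr_ids], f)
    aucs[f + 1] <- roc_auc(yv, scorer(features[val_ids, , drop = FALSE]))$auc
  }
  ok <- aucs[!is.na(aucs)]
  se <- stats::sd(ok) / sqrt(length(ok))
  list(fold_aucs = aucs, mean = mean(ok), sd = stats::sd(ok),
       ci = c(lo = max(0, mean(ok) - 1.96 * se),
              hi = min(1, mean(ok) + 1.96 * se)))
}

#' Threshold classification metrics
#'
#' Standard 2x2 metrics at a hard threshold: accuracy, sensitivity (recall),
#' specificity, precision, F1 (harmonic mean of precision and sensitivity),
#' and the row-normalized confusion matrix (rows = true class, so each row
#' sums to 1). With no predicted positives, precision (and hence F1) is
#' undefined and reported as `NA`.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores probabilities or scores.
#' @param threshold hard-label cut (default 0.5).
#' @return list of metrics plus `confusion` (normalized), `counts`
#'   (tp, fp, tn, fn) and `threshold`.
#' @export
threshold_metrics <- function(labels, scores, threshold = 0.5) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  f1 <- if (is.na(prec) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  confusion <- rbind(`0` = c(`0` = tn, `1` = fp) / (tn + fp),
                     `1` = c(`0` = fn, `1` = tp) / (fn + tp))
  list(accuracy = (tp + tn) / length(y), sensitivity = sens,
       specificity = spec, precision = prec, f1 = f1,
       confusion = confusion,
       counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
       threshold = threshold)
}

#' Evaluate one chapter on the unseen test set
#'
#' The per-chapter evaluation bundle: ten-fold cross-validated AUC on the
#' training portion, then `n_refits` independent refits (fresh balancing,
#' scaling and initialization seeds) evaluated on the untouched test set,
#' reported as mean +/- sd per metric with the mean normalized confusion
#' matrix. Training-set balancing and feature scaling never see test rows;
#' any id appearing in both partitions raises a hard error.
#'
#' @param chapter chapter id (for the report).
#' @param features_img n x latent_dim matrix, rownames = subject ids.
#' @param features_tab n x 8 matrix, rownames = subject ids (raw scale; the
#'   refits standardize with train statistics).
#' @param labels named 0/1 vector of chapter membership.
#' @param split_plan a [make_split()] plan.
#' @param config a [fusion_config()].
#' @param mode model variant passed to [train_fusion()].
#' @param n_refits number of refit seeds (default 3).
#' @param threshold hard-label threshold (default 0.5).
#' @param run_cv compute the ten-fold CV summary (default TRUE).
#' @return a `chapter_report`: chapter id, `cv` (per-fold AUCs, mean, CI),
#'   `test` (mean/sd of each metric, mean confusion matrix, per-refit AUCs
#'   and DeLong CI of the first refit), `refit_scores` (matrix of test-set
#'   scores per refit), and the test AUC `auc_mean`/`auc_sd`.
#' @export
evaluate_chapter <- function(chapter, features_img, features_tab, labels,
                             split_plan, config = fusion_config(),
                             mode = "fused", n_refits = 3L, threshold = 0.5,
                             run_cv = TRUE) {
  leak <- intersect(split_plan$train_ids, split_plan$test_ids)
  if (length(leak)) stop("data leakage: id(s) in both train and test: ",
                         paste(utils::head(leak, 3), collapse = ", "))
  ids_tr <- split_plan$train_ids; ids_te <- split_plan$test_ids
  y <- labels
  fit_once <- function(tr_img, tr_tab, tr_y, seed) {
    cfg <- config; cfg$seed <- as.integer(seed)
    sc_img <- if (mode != "tabular") fit_scaler(tr_img)
    sc_tab <- if (mode != "image") fit_scaler(tr_tab)
    model <- train_fusion(
      if (mode != "tabular") apply_scaler(tr_img, sc_img),
      if (mode != "image") apply_scaler(tr_tab, sc_tab),
      tr_y, cfg, mode = mode, chapter = chapter)
    function(Ximg, Xtab) {
      predict(model,
              if (mode != "tabular") apply_scaler(Ximg, sc_img),
              if (mode != "image") apply_scaler(Xtab, sc_tab))
    }
  }

  cv <- NULL
  if (run_cv) {
    feats <- cbind(features_img, features_tab)
    d_img <- ncol(features_img)
    trainer <- function(X, yy, fold) {
      bal_ids <- downsample_balance(rownames(X), yy, seed = config$seed + fold)
      scorer <- fit_once(X[bal_ids, seq_len(d_img), drop = FALSE],
                         X[bal_ids, -seq_len(d_img), drop = FALSE],
                         yy[bal_ids], seed = config$seed + 100 + fold)
      function(Xv) scorer(Xv[, seq_len(d_img), drop = FALSE],
                          Xv[, -seq_len(d_img), drop = FALSE])
    }
    cv <- cross_validate(feats[ids_tr, , drop = FALSE], y[ids_tr],
                         split_plan, trainer)
  }

  metrics <- list(); refit_scores <- matrix(NA_real_, length(ids_te), n_refits,
                                            dimnames = list(ids_te, NULL))
  conf_sum <- matrix(0, 2, 2)
  for (r in seq_len(n_refits)) {
    seed_r <- config$seed + 1000L * r
    bal <- downsample_balance(ids_tr, y[ids_tr], seed = seed_r)
    scorer <- fit_once(features_img[bal, , drop = FALSE],
                       features_tab[bal, , drop = FALSE], y[bal], seed_r)
    sc <- scorer(features_img[ids_te, , drop = FALSE],
                 features_tab[ids_te, , drop = FALSE])
    refit_scores[, r] <- sc
    tm <- threshold_metrics(y[ids_te], sc, threshold)
    metrics[[r]] <- c(auc = roc_auc(y[ids_te], sc)$auc,
                      accuracy = tm$accuracy, sensitivity = tm$sensitivity,
                      specificity = tm$specificity, precision = tm$precision,
                      f1 = tm$f1)
    conf_sum <- conf_sum + tm$confusion
  }
  M <- do.call(rbind, metrics)
  ci1 <- auc_ci(y[ids_te], refit_scores[, 1])
  structure(list(chapter = chapter, mode = mode, n_refits = n_refits,
                 cv = cv,
                 test = list(mean = colMeans(M), sd = apply(M, 2, stats::sd),
                             confusion = conf_sum / n_refits,
                             auc_ci_first_refit = ci1),
                 auc_mean = mean(M[, "auc"]), auc_sd = stats::sd(M[, "auc"]),
                 refit_scores = refit_scores,
                 test_labels = y[ids_te],
                 threshold = threshold),
            class = "chapter_report")
}

#' @export
print.chapter_report <- function(x, ...) {
  cat(sprintf("Chapter %s [%s]: test AUC %.3f +/- %.3f", x$chapter, x$mode,
              x$auc_mean, x$auc_sd))
  if (!is.null(x$cv)) cat(sprintf("; CV AUC %.3f (%.3f-%.3f)",
                                  x$cv$mean, x$cv$ci["lo"], x$cv$ci["hi"]))
  cat("\n")
  m <- x$test$mean
  cat(sprintf("  acc %.2f sens %.2f spec %.2f prec %.2f F1 %.2f\n",
              m["accuracy"], m["sensitivity"], m["specificity"],
              m["precision"], m["f1"]))
  invisible(x)
}
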