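#' Assemble a run configuration
#'
#' Single configuration object for an end-to-end run; every source of
#' randomness is derived from the master `seed` so a run is reproducible
#' from its configuration alone.
#'
#' @param seed master integer seed.
#' @param cohort a [cohort_spec()] (for synthetic runs), or `NULL` when
#'   reading a cohort from disk.
#' @param ae an [ae_config()].
#' @param fusion a [fusion_config()].
#' @param chapters chapter ids to evaluate.
#' @param n_refits refit seeds per chapter report.
#' @param train_frac,k_folds split geometry.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       cohort = cohort_spec(seed = seed),
                       ae = ae_config(seed = seed),
                       fusion = fusion_config(seed = seed),
                       chapters = c("ch_III", "ch_VI", "ch_IX"),
                       n_refits = 2L, train_frac = 0.70, k_folds = 10L) {
  structure(list(seed = as.integer(seed), cohort = cohort, ae = ae,
                 fusion = fusion, chapters = chapters,
                 n_refits = as.integer(n_refits), train_frac = train_frac,
                 k_folds = as.integer(k_folds)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Any omitted field falls back to the [run_config()] default; nested
#' sections `cohort`, `ae` and `fusion` override the corresponding
#' constructor arguments.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  co <- do.call(cohort_spec, c(y$cohort %||% list(),
                               if (is.null(y$cohort$seed)) list(seed = seed)))
  if (!is.null(y$cohort$chapter_prevalences))
    co$chapter_prevalences <- unlist(y$cohort$chapter_prevalences)
  validate_cohort_spec(co)
  ae <- do.call(ae_config, c(y$ae %||% list(),
                             if (is.null(y$ae$seed)) list(seed = seed)))
  fu <- do.call(fusion_config, c(y$fusion %||% list(),
                                 if (is.null(y$fusion$seed)) list(seed = seed)))
  run_config(seed = seed, cohort = co, ae = ae, fusion = fu,
             chapters = y$chapters %||% c("ch_III", "ch_VI", "ch_IX"),
             n_refits = as.integer(y$n_refits %||% 2L),
             train_frac = y$train_frac %||% 0.70,
             k_folds = as.integer(y$k_folds %||% 10L))
}

write_resolved_config <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, file.path(out_dir, "config_resolved.yaml"))
  writeLines(paste0("perifusion ", as.character(utils::packageVersion("perifusion"))),
             file.path(out_dir, "VERSION"))
}

#' Run phase 1: train the dual-loss autoencoder and cache latent features
#'
#' Trains on the training subjects only (no test image influences the learned
#' representation), then encodes every subject. Writes the latent feature
#' cache, the loss trajectory, a model checkpoint and the resolved
#' configuration to `out_dir`.
#'
#' @param cohort a `perifusion_cohort` or the list returned by
#'   [read_cohort()].
#' @param config a `run_config`.
#' @param out_dir output directory.
#' @param train_ids ids used for training; default: the plan implied by the
#'   config seed and severity labels.
#' @return list with `ae` (trained model), `latents` (n x latent_dim matrix,
#'   rownames = subject ids), `severity` (named vector), `split_plan`.
#' @export
run_phase1 <- function(cohort, config = run_config(), out_dir = NULL,
                       train_ids = NULL) {
  ids <- cohort$tabular$subject_id
  severity <- binarize_severity(cohort$tabular$stage_group)
  names(severity) <- ids
  plan <- make_split(ids, severity, train_frac = config$train_frac,
                     k = config$k_folds, seed = config$seed)
  if (is.null(train_ids)) train_ids <- plan$train_ids
  tr_idx <- match(train_ids, ids)
  if (anyNA(tr_idx)) stop("unknown training id: ", train_ids[which(is.na(tr_idx))[1]])
  ae <- train_ae(cohort$images[, , tr_idx, drop = FALSE], severity[train_ids],
                 config$ae)
  latents <- encode(ae, cohort$images)
  rownames(latents) <- ids
  colnames(latents) <- paste0("l", seq_len(ncol(latents)))
  if (!is.null(out_dir)) {
    write_resolved_config(config, out_dir)
    utils::write.csv(data.frame(subject_id = ids, latents, check.names = FALSE),
                     file.path(out_dir, "latents.csv"), row.names = FALSE)
    utils::write.csv(ae$history, file.path(out_dir, "loss_history.csv"),
                     row.names = FALSE)
    save_ae(ae, file.path(out_dir, "ae_checkpoint.rds"))
    write_split_plan(plan, file.path(out_dir, "split_plan.json"))
  }
  list(ae = ae, latents = latents, severity = severity, split_plan = plan)
}

chapter_report_json <- function(report) {
  list(chapter = report$chapter, mode = report$mode,
       n_refits = report$n_refits,
       cv = if (!is.null(report$cv))
         list(fold_aucs = report$cv$fold_aucs, mean = report$cv$mean,
              sd = report$cv$sd, ci = as.list(report$cv$ci)),
       test = list(mean = as.list(report$test$mean),
                   sd = as.list(report$test$sd),
                   confusion = unname(apply(report$test$confusion, 1, as.list)),
                   auc_ci_first_refit = report$test$auc_ci_first_refit[
                     c("auc", "lo", "hi", "degenerate")]),
       threshold = report$threshold)
}

#' Run phase 2: per-chapter fusion classifiers and their evaluation
#'
#' For each requested chapter: balance the training ids, cross-validate on
#' the training portion, refit and evaluate on the unseen test set; then fit
#' both unimodal variants on the same seeds and compare them to the fused
#' model with the paired DeLong test on the shared test subjects. One JSON
#' report per chapter is written to `out_dir`.
#'
#' @param phase1 the list returned by [run_phase1()].
#' @param cohort the cohort used in phase 1.
#' @param config a `run_config`.
#' @param out_dir output directory (`NULL` to skip writing).
#' @param include_unimodal fit image-only and tabular-only variants and the
#'   DeLong comparisons (default TRUE).
#' @param run_cv run ten-fold CV per chapter (default TRUE).
#' @return named list of per-chapter results: `fused`, `image`, `tabular`
#'   (chapter reports) and `delong` (fused vs each unimodal).
#' @export
run_phase2 <- function(phase1, cohort, config = run_config(), out_dir = NULL,
                       include_unimodal = TRUE, run_cv = TRUE) {
  tab_imp <- mean_impute(cohort$tabular)
  feats_tab <- as.matrix(tab_imp[, FEATURE_COLS])
  rownames(feats_tab) <- tab_imp$subject_id
  latents <- phase1$latents
  plan <- phase1$split_plan
  missing_ch <- setdiff(config$chapters, names(cohort$chapters))
  if (length(missing_ch)) stop("chapter(s) not in cohort: ",
                               paste(missing_ch, collapse = ", "))
  if (!is.null(out_dir)) write_resolved_config(config, out_dir)
  out <- list()
  for (ch in config$chapters) {
    y <- cohort$chapters[[ch]]
    names(y) <- tab_imp$subject_id
    fused <- evaluate_chapter(ch, latents, feats_tab, y, plan, config$fusion,
                              mode = "fused", n_refits = config$n_refits,
                              run_cv = run_cv)
    res <- list(fused = fused)
    if (include_unimodal) {
      img <- evaluate_chapter(ch, latents, feats_tab, y, plan, config$fusion,
                              mode = "image", n_refits = config$n_refits,
                              run_cv = FALSE)
      tabm <- evaluate_chapter(ch, latents, feats_tab, y, plan, config$fusion,
                               mode = "tabular", n_refits = config$n_refits,
                               run_cv = FALSE)
      yte <- fused$test_labels
      res$image <- img
      res$tabular <- tabm
      res$delong <- list(
        fused_vs_image = delong_test(yte, fused$refit_scores[, 1],
                                     img$refit_scores[, 1]),
        fused_vs_tabular = delong_test(yte, fused$refit_scores[, 1],
                                       tabm$refit_scores[, 1]))
    }
    if (!is.null(out_dir)) {
      j <- list(fused = chapter_report_json(fused))
      if (include_unimodal) {
        j$image <- chapter_report_json(res$image)
        j$tabular <- chapter_report_json(res$tabular)
        j$delong <- lapply(res$delong, function(d)
          d[c("auc_a", "auc_b", "z", "p_two_sided")])
      }
      jsonlite::write_json(j, file.path(out_dir, paste0("report_", ch, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    out[[ch]] <- res
  }
  out
}

#' Run a full synthetic demonstration
#'
#' Generates a synthetic cohort, runs both phases, evaluates the configured
#' chapters (fused + unimodal + DeLong), writes interpretability artifacts
#' (Grad-CAM saliency PNGs for a few severe test subjects, the PCA latent
#' projection CSV) and a summary JSON. Internal consistency checks
#' (train/test disjointness, deterministic prediction, probability ranges)
#' raise an error on failure.
#'
#' @param seed master seed.
#' @param out_dir output directory (required for artifact writing).
#' @param config optional `run_config`; default derives everything from
#'   `seed`.
#' @return summary list (invisible): per-chapter AUCs, DeLong p-values,
#'   localization scores, silhouette.
#' @export
run_demo <- function(seed = 1L, out_dir = tempfile("perifusion_demo"),
                     config = NULL) {
  if (is.null(config)) config <- run_config(seed = seed)
  cohort <- generate_cohort(config$cohort)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- run_phase1(cohort, config, out_dir = out_dir)
  p2 <- run_phase2(p1, cohort, config, out_dir = out_dir)

  # interpretability artifacts
  proj <- pca_project(p1$latents, labels = p1$severity)
  utils::write.csv(data.frame(subject_id = rownames(p1$latents),
                              pc1 = proj$coords[, 1], pc2 = proj$coords[, 2],
                              severity = p1$severity),
                   file.path(out_dir, "latent_projection.csv"),
                   row.names = FALSE)
  sil <- silhouette_by_label(proj$coords, p1$severity)
  ids <- cohort$tabular$subject_id
  te_sev <- intersect(p1$split_plan$test_ids, ids[p1$severity == 1])
  loc <- c()
  for (id in utils::head(te_sev, 5)) {
    i <- match(id, ids)
    sm <- grad_cam(p1$ae, cohort$images[, , i], subject_id = id)
    write_saliency_png(sm, file.path(out_dir, paste0("gradcam_", id, ".png")))
    if (any(cohort$lesion_masks[, , i]))  # no planted lesion, no score
      loc <- c(loc, localization_score(sm, cohort$lesion_masks[, , i]))
  }

  # consistency checks
  if (length(intersect(p1$split_plan$train_ids, p1$split_plan$test_ids)))
    stop("invariant violated: train/test overlap")
  z1 <- encode(p1$ae, cohort$images[, , 1:2])
  z2 <- encode(p1$ae, cohort$images[, , 1:2])
  if (!identical(z1, z2)) stop("invariant violated: encoding not deterministic")
  for (ch in names(p2)) {
    sc <- p2[[ch]]$fused$refit_scores
    if (any(sc <= 0 | sc >= 1)) stop("invariant violated: probabilities out of range")
  }

  summary <- list(
    seed = config$seed,
    severe_fraction = mean(p1$severity),
    chapters = lapply(p2, function(r) list(
      fused_auc = r$fused$auc_mean,
      image_auc = if (!is.null(r$image)) r$image$auc_mean,
      tabular_auc = if (!is.null(r$tabular)) r$tabular$auc_mean,
      delong_p_fused_vs_image = if (!is.null(r$delong)) r$delong$fused_vs_image$p_two_sided,
      delong_p_fused_vs_tabular = if (!is.null(r$delong)) r$delong$fused_vs_tabular$p_two_sided)),
    gradcam_localization_mean = if (length(loc)) mean(loc, na.rm = TRUE) else NA,
    lesion_area_fraction = mean(image_template(config$cohort$image_size[1],
                                               config$cohort$image_size[2])$lesion),
    pca_silhouette = sil)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
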