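FEATURE_COLS <- c("age", "gender", "income", "n_teeth", "perio_stage",
                  "extent_bone_loss", "bone_loss_max", "age_adj_bone_loss")

STAGE_LEVELS <- c("health", "gingivitis", "Stage I", "Stage II",
                  "Stage III localized", "Stage III generalized", "Stage IV")
SEVERE_STAGES <- c("Stage III generalized", "Stage IV")

#' Read a subject table
#'
#' Parses the subject CSV (see [write_cohort()] for the column layout):
#' `subject_id`, the eight demographic/clinical features, `stage_group`, and
#' one 0/1 column per chapter id (columns starting with `ch_`). Empty strings
#' are missing values; they are kept as `NA`, never silently zeroed.
#'
#' @param path CSV path.
#' @return list with `tabular` (data.frame of id, features, stage_group) and
#'   `chapters` (data.frame of 0/1 labels).
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path)) stop("subject table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("subject_id", FEATURE_COLS, "stage_group")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("subject table missing column(s): ", paste(miss, collapse = ", "))
  ch_cols <- grep("^ch_", names(raw), value = TRUE)
  unknown <- setdiff(names(raw), c(need, ch_cols))
  if (length(unknown)) stop("unknown column(s) in subject table: ",
                            paste(unknown, collapse = ", "))
  dup <- raw$subject_id[duplicated(raw$subject_id)]
  if (length(dup)) stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "))

  parse_num <- function(col) {
    x <- raw[[col]]
    x[!nzchar(x)] <- NA_character_
    bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
    if (any(bad)) stop("non-numeric value '", x[which(bad)[1]], "' in column '",
                       col, "' (subject ", raw$subject_id[which(bad)[1]], ")")
    as.numeric(x)
  }
  tab <- data.frame(subject_id = raw$subject_id, stringsAsFactors = FALSE)
  for (col in FEATURE_COLS) tab[[col]] <- parse_num(col)
  tab$stage_group <- raw$stage_group
  chapters <- data.frame(row.names = seq_len(nrow(raw)))
  for (col in ch_cols) {
    v <- parse_num(col)
    if (any(!is.na(v) & !v %in% c(0, 1)))
      stop("chapter column '", col, "' must be 0/1")
    chapters[[col]] <- as.integer(v)
  }
  list(tabular = tab, chapters = chapters)
}

#' Mean-impute missing feature values
#'
#' Replaces each missing numeric cell by the arithmetic mean of the observed
#' values in its column. Observed cells are untouched, so each column's mean
#' is invariant under imputation.
#'
#' @param df data.frame with the feature columns.
#' @param cols columns to impute (default: the eight feature columns present).
#' @return data.frame with no missing values in `cols`.
#' @export
mean_impute <- function(df, cols = intersect(FEATURE_COLS, names(df))) {
  for (col in cols) {
    x <- df[[col]]
    if (all(is.na(x))) stop("cannot impute column '", col, "': all values missing")
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    df[[col]] <- x
  }
  df
}

#' Binarize periodontal severity
#'
#' Maps the staging category to the binary severe/non-severe grouping: severe
#' (1) is generalized Stage III or Stage IV periodontitis; periodontal health,
#' gingivitis, Stages I-II and localized Stage III are non-severe (0).
#'
#' @param stage_group character vector of staging categories.
#' @return integer 0/1 vector.
#' @export
binarize_severity <- function(stage_group) {
  bad <- setdiff(unique(stage_group), STAGE_LEVELS)
  if (length(bad)) stop("unrecognized stage category: ", paste(bad, collapse = ", "))
  as.integer(stage_group %in% SEVERE_STAGES)
}

#' Downsample the majority class
#'
#' Applied only when the class imbalance is extreme: if the majority class has
#' more than double the minority count, it is randomly downsampled without
#' replacement to the minority count; otherwise ids are returned unchanged.
#' All minority ids are always retained.
#'
#' @param ids subject ids.
#' @param labels 0/1 labels aligned with `ids`.
#' @param seed integer seed making the draw deterministic.
#' @return the retained ids (original order preserved).
#' @export
downsample_balance <- function(ids, labels, seed = 1L) {
  stopifnot(length(ids) == length(labels))
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab == 0)) stop("downsample_balance requires both classes present")
  maj <- names(tab)[which.max(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  if (n_maj <= 2 * n_min) return(ids)
  maj_idx <- which(labels == as.numeric(maj))
  set.seed(seed)
  keep_maj <- sort(sample(maj_idx, n_min))
  keep <- sort(c(which(labels != as.numeric(maj)), keep_maj))
  ids[keep]
}

#' Stratified train/test split with cross-validation folds
#'
#' Splits subjects 70/30 (configurable) into training and unseen test sets,
#' stratified by label, and assigns the training ids to `k` stratified
#' cross-validation folds whose sizes differ by at most one.
#'
#' @param ids subject ids.
#' @param labels 0/1 labels aligned with `ids`.
#' @param train_frac training fraction (default 0.70).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return a `split_plan` list: `train_ids`, `test_ids`, `fold_assignments`
#'   (named integer vector, folds `0..k-1`, train ids only), `seed`.
#' @export
make_split <- function(ids, labels, train_frac = 0.70, k = 10L, seed = 1L) {
  stopifnot(length(ids) == length(labels), !anyDuplicated(ids))
  pos <- ids[labels == 1]; neg <- ids[labels == 0]
  n_tr_pos <- round(train_frac * length(pos))
  n_tr_neg <- round(train_frac * length(neg))
  if (n_tr_pos < k || n_tr_neg < k)
    stop("insufficient class counts for ", k, "-fold CV: ",
         n_tr_pos, " positive / ", n_tr_neg, " negative training subjects")
  set.seed(seed)
  pos <- sample(pos); neg <- sample(neg)
  train_pos <- pos[seq_len(n_tr_pos)]; test_pos <- pos[-seq_len(n_tr_pos)]
  train_neg <- neg[seq_len(n_tr_neg)]; test_neg <- neg[-seq_len(n_tr_neg)]
  # positives fill folds 0,1,2,... round-robin; negatives continue from where
  # the positives stopped, so total fold sizes differ by at most one
  folds <- c(seq_along(train_pos) - 1L,
             length(train_pos) + seq_along(train_neg) - 1L) %% k
  names(folds) <- c(train_pos, train_neg)
  plan <- list(train_ids = c(train_pos, train_neg),
               test_ids = c(test_pos, test_neg),
               fold_assignments = folds,
               k = as.integer(k), seed = as.integer(seed))
  class(plan) <- "split_plan"
  plan
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Split plan:", length(x$train_ids), "train /", length(x$test_ids),
      "test;", x$k, "folds; seed", x$seed, "\n")
  invisible(x)
}

#' Serialize / restore a split plan
#'
#' @param plan a `split_plan`.
#' @param path JSON path.
#' @return `write_split_plan` returns `path`; `read_split_plan` the plan.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(list(train_ids = plan$train_ids, test_ids = plan$test_ids,
                            fold_assignments = as.list(plan$fold_assignments),
                            k = plan$k, seed = plan$seed),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan <- list(train_ids = x$train_ids, test_ids = x$test_ids,
               fold_assignments = unlist(x$fold_assignments),
               k = as.integer(x$k), seed = as.integer(x$seed))
  class(plan) <- "split_plan"
  plan
}

#' Extract the eight-feature matrix
#'
#' Convenience accessor: the eight demographic/clinical feature columns as a
#' numeric matrix with subject ids as rownames, ready for the fusion model.
#' Values must already be imputed (see [mean_impute()]).
#'
#' @param tabular data.frame with `subject_id` and the feature columns.
#' @return n x 8 numeric matrix.
#' @export
tabular_features <- function(tabular) {
  if (anyNA(tabular[, FEATURE_COLS])) stop("missing values present; impute first")
  m <- as.matrix(tabular[, FEATURE_COLS])
  rownames(m) <- tabular$subject_id
  m
}

#' Fit / apply a z-score standardizer
#'
#' Column means and standard deviations are estimated on training rows only
#' and applied unchanged elsewhere, so mixed feature scales (income vs stage)
#' do not dominate model training and no test statistics leak into training.
#' Zero-variance columns are passed through centered.
#'
#' @param x numeric matrix (rows = samples).
#' @param scaler object returned by `fit_scaler`.
#' @return `fit_scaler`: a scaler; `apply_scaler`: the standardized matrix.
#' @export
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  structure(list(mean = mu, sd = sd), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @export
apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}
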