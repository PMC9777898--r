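write_cohort_csv <- function(n = 5, seed = 1, mutate = identity) {
  co <- generate_cohort(tiny_spec(n = max(n, 20), seed = seed))
  df <- cbind(co$tabular, co$chapters)[seq_len(n), ]
  df <- mutate(df)
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

test_that("subject tables parse with missing cells flagged, not zeroed", {
  path <- write_cohort_csv(5, mutate = function(df) {
    df$bone_loss_max[2] <- NA
    df
  })
  out <- read_subject_table(path)
  expect_equal(nrow(out$tabular), 5)
  expect_true(is.na(out$tabular$bone_loss_max[2]))
  expect_false(anyNA(out$tabular$bone_loss_max[-2]))
  expect_true(all(out$chapters$ch_III %in% 0:1))
})

test_that("malformed subject tables fail with descriptive errors", {
  p1 <- write_cohort_csv(4, mutate = function(df) { df$extra <- 1; df })
  expect_error(read_subject_table(p1), "unknown column.*extra")
  p2 <- write_cohort_csv(4, mutate = function(df) { df$age[1] <- "old"; df })
  expect_error(read_subject_table(p2), "non-numeric.*age")
  p3 <- write_cohort_csv(4, mutate = function(df) { df$subject_id[2] <- df$subject_id[1]; df })
  expect_error(read_subject_table(p3), "duplicate subject_id: S0001")
})

test_that("mean imputation fills with column means and preserves them", {
  df <- data.frame(subject_id = c("a", "b", "c"),
                   age = c(2.0, NA, 4.0), bone_loss_max = c(1, 2, 3))
  out <- mean_impute(df, cols = c("age", "bone_loss_max"))
  expect_equal(out$age, c(2, 3, 4))
  expect_identical(out$bone_loss_max, df$bone_loss_max)  # no-missing: identity
  expect_equal(mean(out$age), mean(df$age, na.rm = TRUE))
  expect_error(mean_impute(data.frame(x = c(NA_real_, NA_real_)), cols = "x"),
               "all values missing")
})

test_that("imputation alters exactly the missing cells in a 1188-subject table", {
  co <- generate_cohort(cohort_spec(n_subjects = 1188, seed = 2))
  tab <- co$tabular
  miss_rows <- sample(seq_len(1188), 13)  # 13 subjects with unmeasurable bone level
  tab$bone_loss_max[miss_rows] <- NA
  out <- mean_impute(tab)
  changed <- which(out$bone_loss_max != co$tabular$bone_loss_max |
                   is.na(co$tabular$bone_loss_max))
  expect_identical(sort(changed), sort(miss_rows))
  expect_equal(length(miss_rows), 13)
})

test_that("severity binarization follows the severe-group definition", {
  expect_identical(binarize_severity(c("Stage IV", "Stage III generalized")), c(1L, 1L))
  expect_identical(binarize_severity(c("health", "gingivitis", "Stage I",
                                       "Stage II", "Stage III localized")),
                   rep(0L, 5))
  expect_error(binarize_severity("Stage V"), "unrecognized")
})

test_that("downsampling triggers only under extreme imbalance", {
  ids <- sprintf("id%03d", 1:130)
  labels <- rep(c(0, 1), c(100, 30))
  kept <- downsample_balance(ids, labels, seed = 1)
  expect_equal(sum(labels[match(kept, ids)] == 0), 30)
  expect_equal(sum(labels[match(kept, ids)] == 1), 30)
  expect_true(all(ids[labels == 1] %in% kept))  # minority always retained
  # 50/30: majority not more than double the minority -> unchanged
  expect_identical(downsample_balance(ids[1:80], rep(c(0, 1), c(50, 30))), ids[1:80])
  expect_identical(downsample_balance(ids[1:60], rep(c(0, 1), c(30, 30))), ids[1:60])
  expect_identical(downsample_balance(ids, labels, seed = 7),
                   downsample_balance(ids, labels, seed = 7))
  expect_error(downsample_balance(ids, rep(0, 130)), "both classes")
})

test_that("splits are stratified, disjoint and deterministic with balanced folds", {
  ids <- sprintf("id%03d", 1:100)
  labels <- rep(c(0, 1), 50)
  plan <- make_split(ids, labels, seed = 5)
  expect_length(plan$train_ids, 70)
  expect_length(plan$test_ids, 30)
  expect_length(intersect(plan$train_ids, plan$test_ids), 0)
  expect_setequal(c(plan$train_ids, plan$test_ids), ids)
  # stratification within one subject
  pos_tr <- sum(labels[match(plan$train_ids, ids)])
  expect_lte(abs(pos_tr - 35), 1)
  # folds partition the train ids with sizes differing by at most 1
  expect_setequal(names(plan$fold_assignments), plan$train_ids)
  sizes <- table(plan$fold_assignments)
  expect_length(sizes, 10)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(plan, make_split(ids, labels, seed = 5))
  expect_error(make_split(ids[1:26], labels[1:26], k = 10), "insufficient")
})

test_that("split plans survive JSON round trips", {
  plan <- make_split(sprintf("s%02d", 1:60), rep(c(0, 1), 30), seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_split_plan(plan, path)
  back <- read_split_plan(path)
  expect_identical(back$train_ids, plan$train_ids)
  expect_identical(back$test_ids, plan$test_ids)
  expect_identical(back$fold_assignments, plan$fold_assignments)
})

test_that("the scaler standardizes with train statistics only", {
  x <- matrix(rnorm(200, 5, 3), 50, 4)
  sc <- fit_scaler(x)
  z <- apply_scaler(x, sc)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4))
  xnew <- matrix(rnorm(40, 0, 1), 10, 4)
  expect_equal(apply_scaler(xnew, sc), sweep(sweep(xnew, 2, sc$mean), 2, sc$sd, "/"))
})
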