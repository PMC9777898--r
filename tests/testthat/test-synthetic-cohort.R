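test_that("cohort spec validation names the offending field", {
  expect_error(cohort_spec(n_subjects = 10), "n_subjects")
  expect_error(cohort_spec(image_size = c(30, 32)), "image_size")
  expect_error(cohort_spec(lesion_effect = -1), "lesion_effect")
  expect_error(cohort_spec(image_signal_weight = 0.7,
                           tabular_signal_weight = 0.6), "tabular_signal_weight")
  expect_error(cohort_spec(chapter_prevalences = c(ch_I = 1.2)), "chapter_prevalences")
  expect_error(cohort_spec(missing_rate = 1), "missing_rate")
})

test_that("generation is deterministic given the spec and stores consistent truth", {
  co1 <- generate_cohort(tiny_spec(seed = 3))
  co2 <- generate_cohort(tiny_spec(seed = 3))
  expect_identical(co1$tabular, co2$tabular)
  expect_identical(co1$images, co2$images)
  expect_identical(co1$chapters, co2$chapters)
  # severity is recoverable from the stage grouping
  expect_identical(binarize_severity(co1$tabular$stage_group), co1$severity)
  # latent decomposition adds up (residual variance absorbed in s)
  expect_true(all(is.finite(co1$truth$s)))
})

test_that("severe prevalence concentrates at the cohort's 45.8% split", {
  fr <- vapply(1:20, function(s)
    mean(generate_cohort(cohort_spec(n_subjects = 200, seed = s))$severity), 0)
  # binomial sd of the mean over 20 x 200 subjects ~ 0.008
  expect_lt(abs(mean(fr) - 544 / 1188), 0.02)
})

test_that("a 1188-subject cohort yields about 544 severe subjects", {
  co <- generate_cohort(cohort_spec(n_subjects = 1188, seed = 11))
  # binomial sd ~ 17; allow 3 sd
  expect_lt(abs(sum(co$severity) - 544), 52)
})

test_that("lesion masks are nonempty iff severe and mark exactly the differing pixels", {
  co <- generate_cohort(tiny_spec(n = 80, seed = 5))
  n <- co$spec$n_subjects
  for (i in seq_len(n)) {
    expect_identical(any(co$lesion_masks[, , i]), co$severity[i] == 1)
  }
  # expected intensity differs between labels only on mask pixels: compare
  # noise-free templates
  tmpl <- perifusion:::image_template(32, 32)
  sev_mask <- co$lesion_masks[, , which(co$severity == 1)[1]]
  expect_identical(sev_mask, tmpl$lesion)
  # mean image difference outside the mask is noise-level
  mu_sev <- apply(co$images[, , co$severity == 1], c(1, 2), mean)
  mu_non <- apply(co$images[, , co$severity == 0], c(1, 2), mean)
  diff <- abs(mu_sev - mu_non)
  expect_gt(mean(diff[tmpl$lesion]), 5 * mean(diff[!tmpl$lesion]))
})

test_that("zero lesion effect makes severe and non-severe images exchangeable", {
  co <- generate_cohort(cohort_spec(n_subjects = 200, lesion_effect = 0, seed = 9))
  expect_true(all(!co$lesion_masks))
  # a simple image statistic cannot separate the classes
  stat <- apply(co$images, 3, function(m) mean(m[perifusion:::image_template(32, 32)$lesion]))
  auc <- roc_auc(co$severity, stat)$auc
  expect_lt(abs(auc - 0.5), 0.12)
})

test_that("chapter prevalences match their targets on average", {
  prev <- colMeans(do.call(rbind, lapply(1:10, function(s)
    colMeans(generate_cohort(cohort_spec(n_subjects = 300, seed = s))$chapters))))
  target <- default_chapter_prevalences()
  expect_lt(max(abs(prev - target)), 0.04)
})

test_that("written cohorts round-trip: counts, tabular values, 8-bit images", {
  co <- generate_cohort(tiny_spec(n = 25, seed = 2, missing_rate = 0.1))
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir)
  manifest <- read.csv(man, stringsAsFactors = FALSE)
  expect_equal(nrow(manifest), 25)
  expect_equal(sum(file.exists(file.path(dir, manifest$image_path))), 25)
  back <- read_cohort(dir)
  expect_identical(back$tabular$subject_id, co$tabular$subject_id)
  for (col in c("age", "income", "bone_loss_max", "perio_stage"))
    expect_identical(back$tabular[[col]], co$tabular[[col]])
  expect_identical(back$chapters, co$chapters)
  expect_lt(max(abs(back$images - co$images)), 1 / 255 + 1e-9)
})

test_that("byte-identical CSV output for identical specs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(tiny_spec(n = 30, seed = 4)), d1)
  write_cohort(generate_cohort(tiny_spec(n = 30, seed = 4)), d2)
  expect_identical(readLines(file.path(d1, "subjects.csv")),
                   readLines(file.path(d2, "subjects.csv")))
})

test_that("missingness hits only bone columns at the requested rate", {
  counts <- vapply(1:15, function(s) {
    co <- generate_cohort(cohort_spec(n_subjects = 100, missing_rate = 0.1, seed = s))
    expect_false(anyNA(co$tabular[, c("age", "gender", "income", "n_teeth", "perio_stage")]))
    sum(is.na(co$tabular[, c("extent_bone_loss", "bone_loss_max", "age_adj_bone_loss")]))
  }, 0)
  # 300 maskable cells per cohort at rate 0.1: mean 30, sd ~5.2
  expect_lt(abs(mean(counts) - 30), 5)
})
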