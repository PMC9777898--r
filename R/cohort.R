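#' Specify a synthetic cohort
#'
#' Defines the generative conditions for a synthetic cohort of subjects, each
#' with a grayscale radiograph-like image, eight demographic/clinical features,
#' a periodontal severity grouping, and per-chapter systemic disease labels.
#'
#' The generator plants a latent risk score `s ~ N(0, 1)` per subject,
#' decomposed as `s = s_img + s_tab + s_res` with independent components of
#' variance `image_signal_weight`, `tabular_signal_weight` and the remainder.
#' Severity (the "severe periodontitis" group) is `s` above the quantile that
#' yields an expected severe fraction of 0.458. The image carries `s_img`
#' (through a planted crest-band lesion in severe subjects, with depth graded
#' by `s_img`), the clinical features carry `s_tab` through linear loadings,
#' and each chapter label is drawn from a logistic model on both components.
#' Because the two components are independent, the Bayes-optimal AUC of each
#' modality and of their fusion is known from normal theory, which downstream
#' tests exploit.
#'
#' @param n_subjects number of subjects (>= 20).
#' @param image_size `c(height, width)` in pixels; each must be divisible by 8.
#' @param lesion_effect pixel-intensity depression of the planted lesion
#'   (>= 0; 0 removes all image-borne signal).
#' @param image_signal_weight,tabular_signal_weight variance shares of the
#'   latent risk carried by each modality; their sum must be <= 1.
#' @param chapter_prevalences named vector of target chapter prevalences in
#'   (0, 1); names are chapter ids (e.g. `"ch_III"`).
#' @param noise_sd sd of additive Gaussian pixel noise.
#' @param missing_rate per-cell probability that a bone-level feature is
#'   recorded missing (in `[0, 1)`).
#' @param beta_img,beta_tab chapter-model log-odds coefficients on the image-
#'   and tabular-borne risk components.
#' @param seed integer seed; the whole cohort is deterministic given the spec.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_subjects = 400L,
                        image_size = c(32L, 32L),
                        lesion_effect = 0.5,
                        image_signal_weight = 0.35,
                        tabular_signal_weight = 0.35,
                        chapter_prevalences = default_chapter_prevalences(),
                        noise_sd = 0.05,
                        missing_rate = 0,
                        beta_img = 2,
                        beta_tab = 2,
                        seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               image_size = as.integer(image_size),
               lesion_effect = lesion_effect,
               image_signal_weight = image_signal_weight,
               tabular_signal_weight = tabular_signal_weight,
               chapter_prevalences = chapter_prevalences,
               noise_sd = noise_sd, missing_rate = missing_rate,
               beta_img = beta_img, beta_tab = beta_tab,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, msg) stop("invalid cohort spec: field '", field, "' ", msg, call. = FALSE)
  if (!is.numeric(spec$n_subjects) || spec$n_subjects < 20) fail("n_subjects", "must be >= 20")
  if (length(spec$image_size) != 2 || any(spec$image_size < 8) ||
      any(spec$image_size %% 8 != 0)) fail("image_size", "must be two multiples of 8")
  if (spec$lesion_effect < 0) fail("lesion_effect", "must be >= 0")
  for (f in c("image_signal_weight", "tabular_signal_weight"))
    if (spec[[f]] < 0 || spec[[f]] > 1) fail(f, "must be in [0, 1]")
  if (spec$image_signal_weight + spec$tabular_signal_weight > 1 + 1e-12)
    fail("image_signal_weight", "+ tabular_signal_weight must be <= 1")
  pv <- spec$chapter_prevalences
  if (length(pv) < 1 || is.null(names(pv)) || any(!nzchar(names(pv))))
    fail("chapter_prevalences", "must be a named vector")
  if (any(pv <= 0 | pv >= 1)) fail("chapter_prevalences", "must all lie in (0, 1)")
  if (spec$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (spec$missing_rate < 0 || spec$missing_rate >= 1) fail("missing_rate", "must be in [0, 1)")
  if (!is.finite(spec$seed)) fail("seed", "must be an integer")
  invisible(spec)
}

#' Default chapter prevalences
#'
#' Fourteen disease-chapter ids (top-level ICD-10 chapters excluding the oral
#' cavity chapter) with plausible adult cohort prevalences. Chapter IX
#' (circulatory) is the most prevalent, consistent with hypertension dominating
#' real cohorts.
#' @return named numeric vector of length 14.
#' @export
default_chapter_prevalences <- function() {
  c(ch_I = 0.10, ch_II = 0.12, ch_III = 0.15, ch_IV = 0.30, ch_V = 0.10,
    ch_VI = 0.20, ch_VII = 0.15, ch_VIII = 0.08, ch_IX = 0.40, ch_X = 0.12,
    ch_XI = 0.25, ch_XII = 0.10, ch_XIII = 0.22, ch_XIV = 0.18)
}

# Severe fraction of the source population: 544 of 1188 subjects.
SEVERE_FRACTION <- 544 / 1188

# Intercept of the chapter logistic model so that E[plogis(a + eta)] hits the
# target prevalence when eta ~ N(0, sd^2). Logistic-normal mean, solved
# numerically.
solve_chapter_intercept <- function(prevalence, eta_sd) {
  if (eta_sd < 1e-12) return(stats::qlogis(prevalence))
  mean_p <- function(a) {
    stats::integrate(function(z) stats::plogis(a + eta_sd * z) * stats::dnorm(z),
                     -8, 8)$value - prevalence
  }
  stats::uniroot(mean_p, c(-20, 20), tol = 1e-10)$root
}

# Linear loadings of each continuous clinical feature on the standardized
# tabular-borne risk component, with per-feature location/scale and rounding
# (records carry finite precision).
tabular_feature_defs <- function() {
  data.frame(
    name   = c("age", "income", "n_teeth", "perio_stage",
               "extent_bone_loss", "bone_loss_max", "age_adj_bone_loss"),
    mu     = c(56, 30000, 26, 2.0, 30, 35, 0.6),
    sigma  = c(12, 15000, 4, 1.0, 15, 18, 0.3),
    lambda = c(0.25, -0.20, -0.50, 0.80, 0.70, 0.70, 0.75),
    digits = c(1, 0, 0, 2, 2, 2, 3),
    lo     = c(35, 0, 0, 0, 0, 0, 0),
    hi     = c(97, Inf, 32, 4, 100, 100, Inf),
    stringsAsFactors = FALSE
  )
}

# Geometry of the planted texture: a periodic "tooth row" with a bright
# alveolar-crest band; the lesion erodes the central section of the band.
image_template <- function(H, W) {
  base <- matrix(0.15, H, W)
  tooth_rows <- seq(round(0.30 * H), round(0.90 * H))
  period <- max(4L, round(W / 8))
  cols <- seq_len(W)
  bright <- ((cols - 1L) %% period) < period / 2
  base[tooth_rows, bright] <- 0.75
  band_rows <- seq(round(0.38 * H), round(0.48 * H))
  base[band_rows, ] <- 0.85
  lesion <- matrix(FALSE, H, W)
  lesion[band_rows, seq(round(0.25 * W), round(0.75 * W))] <- TRUE
  list(base = base, lesion = lesion)
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort (images, tabular features, severity grouping, chapter
#' labels) from the generative model described in [cohort_spec()]. The hidden
#' risk components and per-subject lesion masks are returned as ground truth
#' for downstream benchmarking; a real cohort would not have them.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `perifusion_cohort`: a list with elements
#'   `images` (H x W x n array, intensities in `[0, 1]`), `tabular`
#'   (data.frame with the eight features plus `stage_group`), `chapters`
#'   (data.frame of 0/1 chapter labels), `severity` (0/1 vector),
#'   `lesion_masks` (H x W x n logical array; all-FALSE slice for non-severe
#'   subjects), `truth` (data.frame of hidden components `s`, `s_img`,
#'   `s_tab`), and `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_subjects
  H <- spec$image_size[1]; W <- spec$image_size[2]
  w_img <- spec$image_signal_weight
  w_tab <- spec$tabular_signal_weight

  s_img <- stats::rnorm(n) * sqrt(w_img)
  s_tab <- stats::rnorm(n) * sqrt(w_tab)
  s_res <- stats::rnorm(n) * sqrt(max(0, 1 - w_img - w_tab))
  s <- s_img + s_tab + s_res
  thr <- stats::qnorm(1 - SEVERE_FRACTION)
  severity <- as.integer(s > thr)

  # periodontal stage groups: ordered bands of the risk score; the top two
  # bands are the severe group (generalized Stage III and Stage IV)
  stage_breaks <- c(-Inf, -0.9, -0.5, -0.15, thr / 2, thr, 1.1, Inf)
  stage_levels <- c("health", "gingivitis", "Stage I", "Stage II",
                    "Stage III localized", "Stage III generalized", "Stage IV")
  stage_group <- as.character(cut(s, stage_breaks, labels = stage_levels))

  z_img <- if (w_img > 0) s_img / sqrt(w_img) else numeric(n)
  z_tab <- if (w_tab > 0) s_tab / sqrt(w_tab) else numeric(n)

  defs <- tabular_feature_defs()
  tab <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    raw <- d$mu + d$sigma * (d$lambda * z_tab +
                             sqrt(1 - d$lambda^2) * stats::rnorm(n))
    tab[[d$name]] <- round(pmin(pmax(raw, d$lo), d$hi), d$digits)
  }
  tab$gender <- stats::rbinom(n, 1, 0.61)  # 1 = female, independent of risk
  tab <- tab[, c("subject_id", "age", "gender", "income", "n_teeth",
                 "perio_stage", "extent_bone_loss", "bone_loss_max",
                 "age_adj_bone_loss")]
  tab$stage_group <- stage_group

  # inject missingness into the bone-level columns only
  if (spec$missing_rate > 0) {
    for (col in c("extent_bone_loss", "bone_loss_max", "age_adj_bone_loss")) {
      miss <- stats::runif(n) < spec$missing_rate
      tab[[col]][miss] <- NA_real_
    }
  }

  # chapter labels from the logistic risk model
  eta <- spec$beta_img * s_img + spec$beta_tab * s_tab
  eta_sd <- sqrt(spec$beta_img^2 * w_img + spec$beta_tab^2 * w_tab)
  chapters <- data.frame(row.names = seq_len(n))
  alphas <- numeric(length(spec$chapter_prevalences))
  names(alphas) <- names(spec$chapter_prevalences)
  for (ch in names(spec$chapter_prevalences)) {
    a <- solve_chapter_intercept(spec$chapter_prevalences[[ch]], eta_sd)
    alphas[[ch]] <- a
    chapters[[ch]] <- stats::rbinom(n, 1, stats::plogis(a + eta))
  }

  # images: shared template, lesion planted in severe subjects with depth
  # graded by the image-borne component, plus pixel noise
  tmpl <- image_template(H, W)
  images <- array(0, c(H, W, n))
  masks <- array(FALSE, c(H, W, n))
  depth <- spec$lesion_effect * (0.6 + 0.4 * stats::pnorm(z_img))
  for (i in seq_len(n)) {
    img <- tmpl$base
    if (severity[i] == 1 && spec$lesion_effect > 0) {
      # mask marks exactly the pixels whose expected intensity differs
      # between labels, so it is empty when no lesion is planted
      img[tmpl$lesion] <- img[tmpl$lesion] - depth[i]
      masks[, , i] <- tmpl$lesion
    }
    img <- img + stats::rnorm(H * W, sd = spec$noise_sd)
    images[, , i] <- pmin(pmax(img, 0), 1)
  }

  structure(list(images = images, tabular = tab, chapters = chapters,
                 severity = severity,
                 lesion_masks = masks,
                 truth = data.frame(subject_id = tab$subject_id,
                                    s = s, s_img = s_img, s_tab = s_tab,
                                    stringsAsFactors = FALSE),
                 chapter_intercepts = alphas,
                 spec = spec),
            class = "perifusion_cohort")
}

#' @export
print.perifusion_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$spec$n_subjects, "subjects,",
      paste(x$spec$image_size, collapse = "x"), "images,",
      ncol(x$chapters), "chapters;",
      sprintf("severe fraction %.3f\n", mean(x$severity)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one 8-bit grayscale PNG per subject, a subject table CSV (empty
#' string encodes a missing value), and a manifest CSV mapping `subject_id`
#' to image file. Re-reading reproduces tabular values exactly and images to
#' 8-bit quantization.
#'
#' @param cohort a `perifusion_cohort`.
#' @param out_dir output directory (created if needed).
#' @return the manifest path, invisibly usable by [read_cohort()].
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "perifusion_cohort"))
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) stop("cannot create output directory: ", img_dir)
  n <- cohort$spec$n_subjects
  ids <- cohort$tabular$subject_id
  paths <- file.path("images", paste0(ids, ".png"))
  for (i in seq_len(n)) {
    img8 <- round(cohort$images[, , i] * 255) / 255
    png::writePNG(img8, file.path(out_dir, paths[i]))
  }
  subj <- cbind(cohort$tabular, cohort$chapters)
  subj_path <- file.path(out_dir, "subjects.csv")
  utils::write.csv(subj, subj_path, row.names = FALSE, na = "")
  manifest <- data.frame(subject_id = ids, image_path = paths,
                         stringsAsFactors = FALSE)
  man_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, man_path, row.names = FALSE)
  man_path
}

#' Read a grayscale image
#'
#' Reads an 8-bit grayscale PNG into a `[0, 1]` intensity matrix. Multi-channel
#' PNGs are collapsed by channel mean. DICOM input is not supported by this
#' reader; convert to PNG first.
#'
#' @param path image path.
#' @return an H x W numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (grepl("\\.dcm$", path, ignore.case = TRUE))
    stop("DICOM input is not supported; convert '", path, "' to grayscale PNG")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE],
                                          c(1, 2), mean)
  img
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.csv`, `subjects.csv` and the
#'   image files.
#' @return a list with `images` (H x W x n array), `tabular`, `chapters`
#'   (as in [generate_cohort()]; hidden truth and lesion masks are absent,
#'   as they would be for a real cohort).
#' @export
read_cohort <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  if (!all(c("subject_id", "image_path") %in% names(man)))
    stop("manifest must have columns subject_id, image_path")
  tabs <- read_subject_table(file.path(dir, "subjects.csv"))
  imgs <- lapply(file.path(dir, man$image_path), read_image)
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  images <- array(0, c(H, W, length(imgs)))
  for (i in seq_along(imgs)) {
    if (!all(dim(imgs[[i]]) == c(H, W)))
      stop("image size mismatch for subject ", man$subject_id[i])
    images[, , i] <- imgs[[i]]
  }
  ord <- match(man$subject_id, tabs$tabular$subject_id)
  if (anyNA(ord)) stop("manifest subject missing from subjects.csv: ",
                       man$subject_id[which(is.na(ord))[1]])
  list(images = images,
       tabular = tabs$tabular[ord, , drop = FALSE],
       chapters = tabs$chapters[ord, , drop = FALSE])
}
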