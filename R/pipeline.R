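# End-to-end orchestration: synthetic image corpus -> hair removal ->
# filtering/enhancement -> ROI segmentation -> feature table -> scaling ->
# PCA feature selection -> balancing -> splitting -> optimizer-grid training
# and evaluation. A nested config (YAML-serializable) carries every stage's
# parameters plus the global seed.

#' Default pipeline configuration
#'
#' Returns the nested configuration list driving [run_full()] and
#' [run_preprocess()]: synthetic-corpus settings (two classes with distinct
#' lesion size and tone distributions, hairs on half the images), hair
#' removal (23 x 23 structuring element), rolling-ball radius, the mean
#' filter + piecewise-linear-transform enhancement combination, segmentation
#' polarity, PCA settings (5 leading components, 10 kept features), and the
#' training grid (five optimizers at learning rates 0.001 and 0.006 by
#' default).
#'
#' @param seed Global integer seed.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic = list(
      n_per_class = 200L,
      width = 224L, height = 224L,
      hair_fraction = 0.5,
      noise_sigma = 4,
      vignette_strength = 0.25,
      benign = list(axes = c(30, 22), axes_jitter = 6,
                    tone = c(150, 105, 85), tone_jitter = 12),
      malignant = list(axes = c(50, 36), axes_jitter = 8,
                       tone = c(95, 60, 45), tone_jitter = 12)
    ),
    hair_removal = list(se_size = 23L, threshold = 10, num_iterations = 32L),
    rolling_ball = list(enabled = TRUE, ball_radius = 30),
    filter = list(method = "mean", kernel_size = 3L, sigma = 1,
                  nlm_h = 10, nlm_patch = 7L, nlm_window = 21L),
    enhancement = list(method = "plt", lower = 0.02, upper = 0.98),
    segmentation = list(polarity = "dark", se_size = 3L,
                        flatten = TRUE, flatten_window = 127L),
    features = list(pixel_size = 1),
    pca = list(n_lead_components = 5L, n_keep = 10L),
    training = list(optimizers = c("rmsprop", "adam", "sgd", "adamax",
                                   "nadam"),
                    learning_rates = c(0.001, 0.006),
                    epochs = 150L, batch_size = 32L,
                    train_frac = 0.8, val_frac_of_train = 0.1,
                    positive_class = "benign")
  )
}

# recursively check `config` against the default template: unknown keys are
# rejected, missing keys fall back to defaults
merge_validate_config <- function(config, template = default_pipeline_config(),
                                  path = "") {
  if (is.null(config)) return(template)
  extra <- setdiff(names(config), names(template))
  if (length(extra)) {
    stop("unknown config key(s): ",
         paste0(path, extra, collapse = ", "), call. = FALSE)
  }
  out <- template
  for (key in names(config)) {
    if (is.list(template[[key]]) && !is.null(names(template[[key]]))) {
      out[[key]] <- merge_validate_config(config[[key]], template[[key]],
                                          paste0(path, key, "$"))
    } else {
      out[[key]] <- config[[key]]
    }
  }
  out
}

#' Load and validate a pipeline configuration
#'
#' @param config A partial configuration list, a YAML file path, or `NULL`
#'   for the defaults. Unknown keys are rejected before any computation;
#'   missing keys take their default values.
#' @return The completed configuration list.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  merge_validate_config(config)
}

# draw the per-image spec for one class, jittering axes/tone/center/angle
# (assumes the caller seeded the RNG); hairy images get 4-8 strokes
synth_class_specs <- function(cfg, class_cfg, n, seed_base) {
  lapply(seq_len(n), function(i) {
    axes <- pmax(class_cfg$axes + runif(2, -class_cfg$axes_jitter,
                                        class_cfg$axes_jitter), 8)
    axes <- sort(axes, decreasing = TRUE)
    tone <- pmin(pmax(class_cfg$tone + runif(3, -class_cfg$tone_jitter,
                                             class_cfg$tone_jitter), 0), 255)
    margin <- axes[1] + 4
    center <- c(runif(1, margin + 1, cfg$height - margin),
                runif(1, margin + 1, cfg$width - margin))
    hairy <- runif(1) < cfg$hair_fraction
    lesion_image_spec(width = cfg$width, height = cfg$height,
                      lesion_center = center, lesion_axes = axes,
                      lesion_angle = runif(1, 0, 180), lesion_tone = tone,
                      hair_count = if (hairy) sample(4:8, 1) else 0L,
                      vignette_strength = cfg$vignette_strength,
                      noise_sigma = cfg$noise_sigma,
                      seed = seed_base + i)
  })
}

#' Generate the synthetic two-class image corpus
#'
#' @param config A [pipeline_config()] (or partial list / YAML path).
#' @return A list with `images`, `lesion_masks`, `hair_masks` (parallel
#'   lists), `labels`, and the image `specs`.
#' @export
synth_corpus <- function(config = NULL) {
  config <- pipeline_config(config)
  cfg <- config$synthetic
  specs <- with_seed(config$seed, {
    c(synth_class_specs(cfg, cfg$benign, cfg$n_per_class,
                        config$seed * 1000L),
      synth_class_specs(cfg, cfg$malignant, cfg$n_per_class,
                        config$seed * 1000L + cfg$n_per_class))
  })
  rendered <- lapply(specs, generate_lesion_image)
  list(images = lapply(rendered, `[[`, "image"),
       lesion_masks = lapply(rendered, `[[`, "lesion_mask"),
       hair_masks = lapply(rendered, `[[`, "hair_mask"),
       labels = rep(c("benign", "malignant"), each = cfg$n_per_class),
       specs = specs)
}

# filter + enhancement of a grayscale image per the config
enhance_gray <- function(gray, config) {
  f <- config$filter
  filtered <- clip8(apply_filter(gray, f$method,
                                 params = f[setdiff(names(f), "method")]))
  e <- config$enhancement
  if (e$method == "he") {
    hist_equalize(filtered)
  } else {
    piecewise_linear_transform(filtered,
                               plt_stretch_breakpoints(filtered, e$lower,
                                                       e$upper))
  }
}

# the grayscale the segmentation thresholds: filtered, illumination-flattened
# (so vignettes cannot masquerade as a second intensity class), then enhanced
segmentation_gray <- function(gray, config) {
  f <- config$filter
  filtered <- clip8(apply_filter(gray, f$method,
                                 params = f[setdiff(names(f), "method")]))
  if (isTRUE(config$segmentation$flatten)) {
    filtered <- flatten_background(filtered,
                                   config$segmentation$flatten_window)
  }
  e <- config$enhancement
  if (e$method == "he") {
    hist_equalize(filtered)
  } else {
    piecewise_linear_transform(filtered,
                               plt_stretch_breakpoints(filtered, e$lower,
                                                       e$upper))
  }
}

#' Preprocess images and write every staged artifact
#'
#' Runs each image through the preprocessing chain -- hair removal,
#' rolling-ball background correction, the configured filter and enhancement,
#' color coding with Otsu ROI extraction, and the morphological gradient of
#' the ROI mask -- writing each stage as `<name>_<stage>.png` under `out_dir`
#' plus a quality CSV (`PSNR`, `MAE`, `SSIM`, histogram distance of the
#' enhanced image against the original grayscale; Dice of the ROI mask
#' against ground truth when a lesion mask is supplied).
#'
#' @param images List of RGB arrays, or a character vector of PNG paths.
#'   Unreadable paths are skipped with a warning; if every path fails the
#'   call is an error.
#' @param config A [pipeline_config()] (or partial list / YAML path).
#' @param out_dir Output directory (created if missing).
#' @param names Optional image names for the artifact files.
#' @param lesion_masks Optional list of ground-truth lesion masks.
#' @return Invisibly, the quality data frame (also written to
#'   `quality.csv`).
#' @export
run_preprocess <- function(images, config = NULL, out_dir, names = NULL,
                           lesion_masks = NULL) {
  config <- pipeline_config(config)
  if (is.character(images)) {
    paths <- images
    if (is.null(names)) names <- sub("\\.png$", "", basename(paths))
    images <- lapply(paths, function(pp) {
      tryCatch(read_image_png(pp), error = function(e) {
        warning("skipping unreadable image ", pp, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    })
    keep <- !vapply(images, is.null, logical(1))
    if (!any(keep)) stop("no readable input images", call. = FALSE)
    images <- images[keep]
    names <- names[keep]
  }
  if (is.null(names)) names <- sprintf("image%03d", seq_along(images))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    nm <- names[i]
    orig_gray <- to_grayscale(img)
    hr <- remove_hairs(img, config$hair_removal$se_size,
                       config$hair_removal$threshold,
                       config$hair_removal$num_iterations)
    gray <- to_grayscale(hr$image)
    write_image_png(hr$image, file.path(out_dir, paste0(nm, "_hairless.png")))
    if (isTRUE(config$rolling_ball$enabled)) {
      rb <- rolling_ball(gray, config$rolling_ball$ball_radius)
      write_image_png(clip8(rb$corrected),
                      file.path(out_dir, paste0(nm, "_background_corrected.png")))
    }
    enhanced <- enhance_gray(gray, config)
    write_image_png(clip8(enhanced),
                    file.path(out_dir, paste0(nm, "_enhanced.png")))
    write_image_png(color_code(clip8(enhanced)),
                    file.path(out_dir, paste0(nm, "_colorcoded.png")))
    roi <- extract_roi(hr$image, segmentation_gray(gray, config),
                       polarity = config$segmentation$polarity)
    write_mask_png(roi$mask, file.path(out_dir, paste0(nm, "_roi_mask.png")))
    write_image_png(roi$roi, file.path(out_dir, paste0(nm, "_roi.png")))
    grad <- morphological_gradient(roi$mask,
                                   structuring_element("square",
                                                       config$segmentation$se_size))
    write_mask_png(grad, file.path(out_dir, paste0(nm, "_gradient.png")))
    q <- quality_report(orig_gray, clip8(enhanced))
    row <- data.frame(image = nm, q)
    if (!is.null(lesion_masks)) {
      row$dice <- dice(roi$mask, lesion_masks[[i]])
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  write.csv(out, file.path(out_dir, "quality.csv"), row.names = FALSE)
  invisible(out)
}

#' Extract the feature table from a corpus
#'
#' Hair removal, filter + enhancement of the grayscale for segmentation, Otsu
#' ROI extraction, then geometric and textural feature computation per image.
#'
#' @param corpus A [synth_corpus()] result, or any list with `images` and
#'   `labels` (optionally `hair_masks` for the scratched-area ground truth).
#' @param config A [pipeline_config()] (or partial list / YAML path).
#' @return Data frame with the 20 features plus `prediction`.
#' @export
pipeline_features <- function(corpus, config = NULL) {
  config <- pipeline_config(config)
  n <- length(corpus$images)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    hr <- remove_hairs(corpus$images[[i]], config$hair_removal$se_size,
                       config$hair_removal$threshold,
                       config$hair_removal$num_iterations)
    gray <- to_grayscale(hr$image)
    roi <- extract_roi(hr$image, segmentation_gray(gray, config),
                       polarity = config$segmentation$polarity)
    rows[[i]] <- c(geometric_features(roi$mask, hr$mask,
                                      config$features$pixel_size),
                   textural_features(gray, roi$mask))
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- LESION_FEATURE_NAMES
  out$prediction <- factor(corpus$labels)
  out
}

#' Run the full pipeline end to end
#'
#' Synthesizes (or accepts) a labelled corpus, extracts the feature table,
#' min-max scales it, selects the top features by PCA loadings, balances the
#' classes, splits stratified train/validation/test, trains the classifier
#' over the optimizer grid, and returns the evaluation table. Reproducible
#' bit-for-bit from config + seed.
#'
#' @param config A [pipeline_config()] (or partial list / YAML path).
#' @param corpus Optional pre-built corpus (defaults to [synth_corpus()]).
#' @param out_dir Optional directory for artifacts (`features.csv`,
#'   `results.csv`, `pca.json`, `provenance.yaml`).
#' @return A list with `features` (raw table), `scaled`, `selected_features`,
#'   `pca`, `split`, `results` (the evaluation data frame), and `config`.
#' @export
run_full <- function(config = NULL, corpus = NULL, out_dir = NULL) {
  config <- pipeline_config(config)
  if (is.null(corpus)) corpus <- synth_corpus(config)
  features <- pipeline_features(corpus, config)

  scaled <- minmax_scale(features)
  pca <- fit_pca(scaled$table[LESION_FEATURE_NAMES],
                 n_components = max(config$pca$n_lead_components, 5L))
  selected <- select_features(pca, config$pca$n_lead_components,
                              config$pca$n_keep)
  reduced <- scaled$table[c(selected, "prediction")]
  balanced <- near_miss_balance(reduced, seed = config$seed)
  split <- split_dataset(balanced, config$training$train_frac,
                         config$training$val_frac_of_train,
                         seed = config$seed)
  results <- evaluate_run(balanced, split,
                          positive_class = config$training$positive_class,
                          optimizers = config$training$optimizers,
                          learning_rates = config$training$learning_rates,
                          epochs = config$training$epochs,
                          batch_size = config$training$batch_size,
                          seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(features, file.path(out_dir, "features.csv"),
              row.names = FALSE)
    write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    write_pca_json(pca, file.path(out_dir, "pca.json"))
    yaml::write_yaml(list(config = config, selected_features = selected,
                          n_images = length(corpus$images)),
                     file.path(out_dir, "provenance.yaml"))
  }
  list(features = features, scaled = scaled$table, scaler = scaled$state,
       pca = pca, selected_features = selected, split = split,
       results = results, config = config)
}
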