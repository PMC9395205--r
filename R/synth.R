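# Synthetic dermoscopy-like image and feature-table generators. These provide
# ground truth (lesion mask, hair mask, class labels) so every downstream stage
# of the pipeline can be exercised and scored without any external downloads.

#' Specification of a synthetic lesion image
#'
#' Describes one dermoscopy-like image: a uniform skin background darkened
#' towards the corners by a radial vignette, an elliptical pigmented lesion,
#' a number of curvilinear hair strokes, and i.i.d. Gaussian pixel noise.
#' The same spec (same seed) always renders to bit-identical output.
#'
#' @param width,height Image size in pixels.
#' @param skin_tone,lesion_tone,hair_tone RGB triples in \[0, 255\].
#' @param lesion_center `(row, col)` of the ellipse center.
#' @param lesion_axes `(a, b)` semi-axis lengths in pixels.
#' @param lesion_angle Ellipse rotation in degrees.
#' @param hair_count Number of hair strokes (0 for a hairless image).
#' @param hair_thickness Stroke thickness in pixels.
#' @param vignette_strength Fraction in \[0, 1\]; multiplicative radial gain
#'   `1 - strength * (r / r_max)^2` applied to the skin background.
#' @param noise_sigma Standard deviation of the additive Gaussian noise, in
#'   intensity units.
#' @param seed Integer RNG seed.
#'
#' @return An object of class `lesion_image_spec`.
#' @seealso [generate_lesion_image()]
#' @export
lesion_image_spec <- function(width = 224, height = 224,
                              skin_tone = c(228, 180, 152),
                              lesion_center = c(height / 2, width / 2),
                              lesion_axes = c(45, 30),
                              lesion_angle = 0,
                              lesion_tone = c(110, 72, 54),
                              hair_count = 5,
                              hair_thickness = 2,
                              hair_tone = c(42, 32, 26),
                              vignette_strength = 0.25,
                              noise_sigma = 4,
                              seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               skin_tone = as.numeric(skin_tone),
               lesion_center = as.numeric(lesion_center),
               lesion_axes = as.numeric(lesion_axes),
               lesion_angle = as.numeric(lesion_angle),
               lesion_tone = as.numeric(lesion_tone),
               hair_count = as.integer(hair_count),
               hair_thickness = as.numeric(hair_thickness),
               hair_tone = as.numeric(hair_tone),
               vignette_strength = as.numeric(vignette_strength),
               noise_sigma = as.numeric(noise_sigma),
               seed = as.integer(seed))
  class(spec) <- "lesion_image_spec"
  validate_lesion_image_spec(spec)
  spec
}

validate_lesion_image_spec <- function(spec) {
  if (spec$width < 8 || spec$height < 8) {
    stop("image must be at least 8 x 8 pixels", call. = FALSE)
  }
  tones <- c(spec$skin_tone, spec$lesion_tone, spec$hair_tone)
  if (any(tones < 0 | tones > 255)) {
    stop("all tones must lie in [0, 255]", call. = FALSE)
  }
  if (spec$vignette_strength < 0 || spec$vignette_strength > 1) {
    stop("vignette_strength must lie in [0, 1]", call. = FALSE)
  }
  if (spec$hair_count < 0) stop("hair_count must be >= 0", call. = FALSE)
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  a <- spec$lesion_axes[1]; b <- spec$lesion_axes[2]
  if (a <= 0 || b <= 0) stop("lesion axes must be positive", call. = FALSE)
  th <- spec$lesion_angle * pi / 180
  half_w <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  half_h <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  cr <- spec$lesion_center[1]; cc <- spec$lesion_center[2]
  if (cr - half_h < 1 || cr + half_h > spec$height ||
      cc - half_w < 1 || cc + half_w > spec$width) {
    stop("lesion ellipse does not fit inside the image frame", call. = FALSE)
  }
  invisible(spec)
}

# exact rasterization of the spec's ellipse: pixel centers inside the ellipse
rasterize_ellipse <- function(spec) {
  th <- spec$lesion_angle * pi / 180
  a <- spec$lesion_axes[1]; b <- spec$lesion_axes[2]
  y <- matrix(seq_len(spec$height) - spec$lesion_center[1],
              spec$height, spec$width)
  x <- matrix(rep(seq_len(spec$width) - spec$lesion_center[2],
                  each = spec$height), spec$height, spec$width)
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

# draw `n` random quadratic Bezier strokes of the given thickness; returns the
# rasterized hair mask (assumes the RNG is already seeded by the caller)
rasterize_hairs <- function(n, thickness, height, width) {
  mask <- matrix(FALSE, height, width)
  if (n == 0) return(mask)
  r <- thickness / 2
  rr <- ceiling(r)
  offs <- expand.grid(dy = -rr:rr, dx = -rr:rr)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, , drop = FALSE]
  nt <- 4L * (height + width)
  tt <- seq(0, 1, length.out = nt)
  for (i in seq_len(n)) {
    p0 <- c(runif(1, 1, height), runif(1, 1, width))
    p2 <- c(runif(1, 1, height), runif(1, 1, width))
    p1 <- (p0 + p2) / 2 + c(runif(1, -height / 3, height / 3),
                            runif(1, -width / 3, width / 3))
    by <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
    bx <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
    py <- rep(round(by), each = nrow(offs)) + offs$dy
    px <- rep(round(bx), each = nrow(offs)) + offs$dx
    keep <- py >= 1 & py <= height & px >= 1 & px <= width
    mask[cbind(py[keep], px[keep])] <- TRUE
  }
  mask
}

#' Render a synthetic lesion image with ground truth
#'
#' Composes skin background (with radial vignette), a flat-toned elliptical
#' lesion, hair strokes drawn as random quadratic Bezier curves, and additive
#' Gaussian noise, clipped and rounded to 8-bit levels. With `noise_sigma = 0`
#' and `hair_count = 0` the image restricted to the lesion mask is exactly
#' constant at `lesion_tone`.
#'
#' @param spec A [lesion_image_spec()].
#' @return A list with elements `image` (H x W x 3 numeric array, 0-255),
#'   `lesion_mask` and `hair_mask` (logical matrices).
#' @export
generate_lesion_image <- function(spec) {
  if (!inherits(spec, "lesion_image_spec")) {
    spec <- do.call(lesion_image_spec, spec)
  }
  validate_lesion_image_spec(spec)
  h <- spec$height; w <- spec$width
  lesion <- rasterize_ellipse(spec)

  with_seed(spec$seed, {
    hairs <- rasterize_hairs(spec$hair_count, spec$hair_thickness, h, w)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    y <- matrix(seq_len(h) - cy, h, w)
    x <- matrix(rep(seq_len(w) - cx, each = h), h, w)
    r2 <- y^2 + x^2
    gain <- 1 - spec$vignette_strength * r2 / max(r2)

    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- spec$skin_tone[ch] * gain
      plane[lesion] <- spec$lesion_tone[ch]
      plane[hairs] <- spec$hair_tone[ch]
      if (spec$noise_sigma > 0) {
        plane <- plane + matrix(rnorm(h * w, sd = spec$noise_sigma), h, w)
      }
      img[, , ch] <- clip8(plane)
    }
    list(image = img, lesion_mask = lesion, hair_mask = hairs)
  })
}

#' Specification of a synthetic two-class feature table
#'
#' Describes a Gaussian mixture with one multivariate normal per class over the
#' 20 canonical lesion features (see [lesion_feature_names()]), emulating the
#' CSV the imaging pipeline produces.
#'
#' @param n_per_class Rows per class.
#' @param class_means List of two length-20 mean vectors (benign, malignant).
#' @param covariance Shared 20 x 20 symmetric positive semi-definite matrix.
#' @param seed Integer RNG seed.
#' @return An object of class `feature_table_spec`.
#' @export
feature_table_spec <- function(n_per_class = 200,
                               class_means = list(rep(0, 20), rep(1, 20)),
                               covariance = diag(20),
                               seed = 1L) {
  spec <- list(n_per_class = as.integer(n_per_class),
               class_means = lapply(class_means, as.numeric),
               covariance = as.matrix(covariance),
               seed = as.integer(seed))
  class(spec) <- "feature_table_spec"
  validate_feature_table_spec(spec)
  spec
}

validate_feature_table_spec <- function(spec) {
  if (spec$n_per_class < 0) stop("n_per_class must be >= 0", call. = FALSE)
  if (length(spec$class_means) != 2 ||
      any(lengths(spec$class_means) != 20)) {
    stop("class_means must be two vectors of length 20", call. = FALSE)
  }
  S <- spec$covariance
  if (!identical(dim(S), c(20L, 20L)) || max(abs(S - t(S))) > 1e-8) {
    stop("covariance must be a symmetric 20 x 20 matrix", call. = FALSE)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("covariance must be positive semi-definite", call. = FALSE)
  }
  invisible(spec)
}

#' Generate a two-class Gaussian feature table
#'
#' @param spec A [feature_table_spec()].
#' @return A data frame with `2 * n_per_class` rows: the 20 feature columns
#'   named as [lesion_feature_names()] plus a `prediction` factor column with
#'   equal `"benign"` / `"malignant"` counts.
#' @export
generate_feature_table <- function(spec) {
  if (!inherits(spec, "feature_table_spec")) {
    spec <- do.call(feature_table_spec, spec)
  }
  validate_feature_table_spec(spec)
  n <- spec$n_per_class
  with_seed(spec$seed, {
    draw <- function(mu) {
      if (n == 0) {
        matrix(numeric(0), 0, 20)
      } else {
        MASS::mvrnorm(n, mu = mu, Sigma = spec$covariance)
      }
    }
    xb <- draw(spec$class_means[[1]])
    xm <- draw(spec$class_means[[2]])
    out <- as.data.frame(rbind(xb, xm))
    names(out) <- LESION_FEATURE_NAMES
    out$prediction <- factor(rep(c("benign", "malignant"), each = n),
                             levels = c("benign", "malignant"))
    rownames(out) <- NULL
    out
  })
}

#' Read and write 8-bit images and masks as PNG
#'
#' `write_image_png()`/`read_image_png()` handle RGB or grayscale images on the
#' 0-255 scale; `write_mask_png()`/`read_mask_png()` store binary masks as
#' single-channel 0/255 PNGs.
#'
#' @param img Numeric matrix (grayscale) or H x W x 3 array, values 0-255.
#' @param mask Logical matrix.
#' @param path File path.
#' @return Readers return the image/mask; writers return `path` invisibly.
#' @name lesion_png_io
NULL

#' @rdname lesion_png_io
#' @export
write_image_png <- function(img, path) {
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' @rdname lesion_png_io
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  round(img * 255)
}

#' @rdname lesion_png_io
#' @export
write_mask_png <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask * 1, target = path)
  invisible(path)
}

#' @rdname lesion_png_io
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Serialize an image spec to YAML and back
#'
#' @param spec A [lesion_image_spec()].
#' @param path File path.
#' @return `read_spec_yaml()` returns the reconstructed spec.
#' @export
write_spec_yaml <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_spec_yaml
#' @export
read_spec_yaml <- function(path) {
  do.call(lesion_image_spec, yaml::read_yaml(path))
}
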