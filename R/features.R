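# Geometric (shape) and textural (intensity) lesion features, min-max scaling,
# and the builder that turns a set of labelled images into the 21-column
# feature table used by the classifier.

# clockwise 8-neighborhood, image coordinates (row grows downwards)
MOORE_DIRS <- cbind(dy = c(-1, -1, 0, 1, 1, 1, 0, -1),
                    dx = c(0, 1, 1, 1, 0, -1, -1, -1))

# Moore-neighbor boundary trace of the component containing the
# uppermost-leftmost pixel of `mask`; returns the ordered boundary pixels.
# After a move in direction d the clockwise neighbor scan restarts two
# positions before d; the trace closes by Jacob's criterion (the start pixel
# is re-entered with the same outgoing direction as the first move).
moore_trace <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  start <- NULL
  for (y in seq_len(nr)) {
    xs <- which(mask[y, ])
    if (length(xs)) { start <- c(y, xs[1]); break }
  }
  is_fg <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc &&
    mask[p[1], p[2]]
  trace <- list(start)
  b <- start
  s <- 7L  # scan starts at the W neighbor, background for the start pixel
  first_d <- NA_integer_
  repeat {
    d <- NA_integer_
    for (k in 0:7) {
      idx <- ((s - 1L + k) %% 8L) + 1L
      if (is_fg(b + MOORE_DIRS[idx, ])) { d <- idx; break }
    }
    if (is.na(d)) return(matrix(start, nrow = 1))  # isolated pixel
    if (all(b == start) && !is.na(first_d) && d == first_d) break
    if (is.na(first_d)) first_d <- d
    cand <- b + MOORE_DIRS[d, ]
    if (!all(cand == start)) trace[[length(trace) + 1L]] <- cand
    b <- cand
    s <- ((d - 1L + 6L) %% 8L) + 1L
    if (length(trace) > 4L * nr * nc) {
      stop("boundary trace failed to close", call. = FALSE)
    }
  }
  do.call(rbind, trace)
}

# polygonal perimeter of a mask: summed outer-boundary trace lengths of all
# 8-connected components (orthogonal steps count 1, diagonal steps sqrt(2))
mask_perimeter <- function(mask) {
  lab <- cc_label_cpp(mask)
  total <- 0
  for (l in seq_len(max(lab))) {
    comp <- lab == l
    bnd <- moore_trace(comp)
    if (nrow(bnd) < 2) next
    closed <- rbind(bnd, bnd[1, , drop = FALSE])
    total <- total + sum(sqrt(rowSums(diff(closed)^2)))
  }
  total
}

# convex hull of the mask pixel centers: vertex coordinates, polygon
# perimeter, and the count of pixel centers inside the hull
mask_convex <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)  # (row, col)
  hull_idx <- grDevices::chull(pts[, 2], pts[, 1])
  hull <- pts[hull_idx, , drop = FALSE]
  closed <- rbind(hull, hull[1, , drop = FALSE])
  perim <- sum(sqrt(rowSums(diff(closed)^2)))
  # count pixel centers of the bounding box lying inside every hull half-plane
  ys <- seq(min(pts[, 1]), max(pts[, 1]))
  xs <- seq(min(pts[, 2]), max(pts[, 2]))
  py <- rep(ys, times = length(xs))
  px <- rep(xs, each = length(ys))
  inside <- rep(TRUE, length(py))
  n <- nrow(hull)
  if (n >= 3) {
    cy <- mean(hull[, 1]); cx <- mean(hull[, 2])
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      ey <- hull[j, 1] - hull[i, 1]; ex <- hull[j, 2] - hull[i, 2]
      side_c <- ex * (cy - hull[i, 1]) - ey * (cx - hull[i, 2])
      s <- sign(side_c)
      val <- ex * (py - hull[i, 1]) - ey * (px - hull[i, 2])
      inside <- inside & (s * val >= -1e-9)
    }
  } else {
    inside <- py %in% pts[, 1] & px %in% pts[, 2] &
      mask[cbind(py, px)]
  }
  list(perimeter = perim, area = sum(inside))
}

# fill holes: mask plus every background component not touching the border
fill_holes <- function(mask) {
  bg <- cc_label_cpp(!mask)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  hole <- !mask & !(bg %in% border_labels[border_labels > 0])
  mask | matrix(hole, nrow(mask), ncol(mask))
}

#' Geometric features of a lesion mask
#'
#' Computes the 14 shape features of the lesion region: pixel area, polygonal
#' boundary perimeter, perimeter/area ratio, the major/minor axis lengths of
#' the ellipse with the same second moments (and their ratio), solidity
#' (area / convex area), circularity (`4 * pi * area / convex_perimeter^2`),
#' hole-filled area, extent (area / bounding-box area), equivalent circle
#' diameter (`sqrt(4 * area / pi)`), convex hull area, and the scratched area:
#' the overlap of the detected hair mask with the lesion region (the damage
#' source this pipeline models), in pixels and, scaled by `pixel_size^2`, in
#' square microns.
#'
#' @param mask Logical lesion mask (nonempty).
#' @param hair_mask Optional logical hair mask (defaults to no hairs).
#' @param pixel_size Pixel edge length in microns (default 1, i.e. feature
#'   values stay in pixel units).
#' @return Named numeric vector with the 14 geometric features.
#' @export
geometric_features <- function(mask, hair_mask = NULL, pixel_size = 1) {
  assert_mask(mask)
  if (!any(mask)) stop("lesion mask is empty", call. = FALSE)
  if (is.null(hair_mask)) hair_mask <- matrix(FALSE, nrow(mask), ncol(mask))
  assert_mask(hair_mask, "hair_mask")

  area <- sum(mask)
  perim <- mask_perimeter(mask)
  hull <- mask_convex(mask)
  pts <- which(mask, arr.ind = TRUE)
  yc <- mean(pts[, 1]); xc <- mean(pts[, 2])
  mu20 <- mean((pts[, 2] - xc)^2)
  mu02 <- mean((pts[, 1] - yc)^2)
  mu11 <- mean((pts[, 2] - xc) * (pts[, 1] - yc))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  major <- 4 * sqrt(max(l1, 0))
  minor <- 4 * sqrt(max(l2, 0))
  bbox <- (diff(range(pts[, 1])) + 1) * (diff(range(pts[, 2])) + 1)
  scratched <- sum(mask & hair_mask)

  c(scratched_area = scratched,
    scratched_area_sq_microns = scratched * pixel_size^2,
    area = area,
    perimeter = perim,
    pa_ratio = perim / area,
    major_axis_length = major,
    minor_axis_length = minor,
    ls_ratio = if (minor > 0) major / minor else Inf,
    solidity = area / hull$area,
    circularity = 4 * pi * area / hull$perimeter^2,
    filled_area = sum(fill_holes(mask)),
    extent = area / bbox,
    equiv_diameter = sqrt(4 * area / pi),
    convex_area = hull$area)
}

#' Textural features of the lesion region
#'
#' Computes six intensity statistics over the masked pixels only: mean,
#' standard deviation, Shannon entropy in bits of the 256-level histogram,
#' entropy in bits of the normalized gray-level co-occurrence matrix
#' (symmetric, offset one pixel to the right, intensities quantized to
#' `glcm_levels` gray levels, both pixels of a pair inside the mask), skewness,
#' and excess kurtosis. Zero-variance regions report 0 for standard deviation,
#' both entropies, skewness, and kurtosis (documented sentinel convention).
#'
#' @param gray Grayscale image matrix (0-255).
#' @param mask Logical mask of the region (nonempty).
#' @param glcm_levels Number of gray levels for the co-occurrence matrix
#'   (default 32, which keeps the matrix well populated on small regions).
#' @return Named numeric vector with the 6 textural features.
#' @export
textural_features <- function(gray, mask, glcm_levels = 32) {
  assert_gray(gray, "gray")
  assert_mask(mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  v <- gray[mask]
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 > 0) {
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  p <- tabulate(as.integer(round(v)) + 1L, nbins = 256L) / length(v)
  p <- p[p > 0]
  shannon <- -sum(p * log2(p))

  q <- matrix(NA_integer_, nrow(gray), ncol(gray))
  q[mask] <- pmin(floor(round(gray[mask]) / 256 * glcm_levels),
                  glcm_levels - 1)
  left <- q[, -ncol(q), drop = FALSE]
  right <- q[, -1, drop = FALSE]
  ok <- !is.na(left) & !is.na(right)
  if (any(ok)) {
    pairs <- table(factor(left[ok], levels = 0:(glcm_levels - 1)),
                   factor(right[ok], levels = 0:(glcm_levels - 1)))
    pairs <- pairs + t(pairs)  # symmetric co-occurrence
    pg <- pairs / sum(pairs)
    pg <- pg[pg > 0]
    glcm_ent <- -sum(pg * log2(pg))
  } else {
    glcm_ent <- 0
  }

  c(mean = m,
    standard_deviation = sqrt(m2),
    shannon_entropy = shannon,
    glcm_entropy = glcm_ent,
    skewness = skew,
    kurtosis = kurt)
}

#' Min-max scale the feature columns of a table
#'
#' Affinely maps every numeric column to \[0, 1\] via
#' `(x - min) / (max - min)`; constant columns map to 0 (documented
#' convention). When `state` is supplied, its stored column minima/maxima are
#' applied instead (e.g. to scale test rows with the training scaler).
#'
#' @param table Data frame; non-numeric columns (such as `prediction`) pass
#'   through untouched.
#' @param state Optional scaler state from a previous call.
#' @return A list with `table` (scaled data frame) and `state` (per-column
#'   `min` and `max`).
#' @export
minmax_scale <- function(table, state = NULL) {
  num <- vapply(table, is.numeric, logical(1))
  cols <- names(table)[num]
  if (is.null(state)) {
    state <- list(min = vapply(table[cols], min, numeric(1)),
                  max = vapply(table[cols], max, numeric(1)))
  }
  out <- table
  for (cn in cols) {
    lo <- state$min[[cn]]; hi <- state$max[[cn]]
    out[[cn]] <- if (hi > lo) (table[[cn]] - lo) / (hi - lo) else
      rep(0, nrow(table))
  }
  list(table = out, state = state)
}

#' Build the lesion feature table from labelled images
#'
#' Runs each image through hair removal (optional), Otsu ROI segmentation, and
#' feature extraction, producing one row of the 20 features plus the
#' `prediction` label per image.
#'
#' @param images List of RGB arrays (0-255).
#' @param labels Character/factor vector of class labels, one per image.
#' @param masks Optional list of lesion masks to use instead of segmenting.
#' @param hair_masks Optional list of hair masks; by default the masks
#'   detected during hair removal are used.
#' @param remove_hair Run digital hair removal first (default `TRUE`).
#' @param pixel_size Pixel edge length in microns (see
#'   [geometric_features()]).
#' @param polarity Lesion polarity for [extract_roi()].
#' @return Data frame with 21 columns (20 features + `prediction`).
#' @export
build_dataset <- function(images, labels, masks = NULL, hair_masks = NULL,
                          remove_hair = TRUE, pixel_size = 1,
                          polarity = "dark") {
  if (length(images) != length(labels)) {
    stop("`images` and `labels` lengths differ", call. = FALSE)
  }
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    hm <- if (!is.null(hair_masks)) hair_masks[[i]] else NULL
    if (remove_hair) {
      hr <- remove_hairs(img)
      img <- hr$image
      if (is.null(hm)) hm <- hr$mask
    }
    gray <- to_grayscale(img)
    mask <- if (!is.null(masks)) masks[[i]] else
      extract_roi(img, gray, polarity = polarity)$mask
    rows[[i]] <- c(geometric_features(mask, hm, pixel_size),
                   textural_features(gray, mask))
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- LESION_FEATURE_NAMES
  out$prediction <- factor(as.character(labels))
  out
}
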