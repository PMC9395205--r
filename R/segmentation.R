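# Color coding, Otsu thresholding and ROI extraction, plus the binary
# morphology (erosion, dilation, morphological gradient) applied to the
# segmented lesion before feature extraction.
#
# Padding conventions: binary masks use the set definitions on the finite
# frame (outside pixels are background, so a structuring element hanging over
# the border never "fits"); grayscale inputs use reflected borders like the
# denoising filters.

#' Structuring element for binary and grayscale morphology
#'
#' @param shape `"square"` or `"disk"`.
#' @param size Odd side length / diameter in pixels.
#' @return An object of class `structuring_element` holding the offset lists.
#' @export
structuring_element <- function(shape = c("square", "disk"), size = 3) {
  shape <- match.arg(shape)
  assert_odd(size, "size")
  r <- (size - 1) / 2
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  if (shape == "disk") offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
  structure(list(shape = shape, size = size,
                 dy = as.integer(offs$dy), dx = as.integer(offs$dx)),
            class = "structuring_element")
}

as_se <- function(se) {
  if (inherits(se, "structuring_element")) return(se)
  if (is.numeric(se) && length(se) == 1) return(structuring_element(size = se))
  stop("`se` must be a structuring_element or an odd size", call. = FALSE)
}

#' Map a grayscale image through a fixed color code
#'
#' Applies a fixed "ember" colormap (dark blue-black through red to bright
#' yellow-white) that is injective on the 256 intensity levels and strictly
#' monotone in luminance, so ordering of gray levels is preserved in the
#' colorized rendering.
#'
#' @param gray Grayscale image matrix with values in \[0, 255\].
#' @return H x W x 3 RGB array on the 0-255 scale.
#' @export
color_code <- function(gray) {
  assert_gray(gray, "gray")
  v <- 0:255
  pal <- cbind(r = v, g = round(0.6 * v), b = round(255 * (v / 255)^2))
  g <- as.integer(round(gray))
  out <- array(0, dim = c(nrow(gray), ncol(gray), 3))
  for (ch in 1:3) {
    out[, , ch] <- matrix(pal[g + 1L, ch], nrow(gray), ncol(gray))
  }
  out
}

#' Flatten slowly varying illumination before thresholding
#'
#' Estimates the illumination field in two steps: a grayscale closing of the
#' image by a large flat square window (the closing fills in any dark
#' structure narrower than the window, leaving only the bright field plus a
#' blocky envelope error), then a least-squares quadratic surface fit to the
#' closing (vignettes and exposure gradients are low-order fields, and the
#' fit removes the envelope blockiness). Returns `gray - field + 255`: dark
#' lesions keep their depth while smooth illumination structure is removed.
#' The window must exceed the widest dark structure that should survive.
#'
#' @param gray Grayscale image matrix.
#' @param window Odd window side in pixels (default 127, wider than any
#'   lesion the synthetic corpus produces on a 224 x 224 frame).
#' @return Flattened matrix of 8-bit levels.
#' @export
flatten_background <- function(gray, window = 127) {
  assert_gray(gray, "gray")
  assert_odd(window, "window")
  closing <- flat_morph_gray(flat_morph_gray(gray, window, dilate = TRUE),
                             window, dilate = FALSE)
  nr <- nrow(gray); nc <- ncol(gray)
  ys <- (matrix(seq_len(nr), nr, nc) - (nr + 1) / 2) / nr
  xs <- (matrix(rep(seq_len(nc), each = nr), nr, nc) - (nc + 1) / 2) / nc
  sub <- seq(1, nr * nc, by = 7L)  # subsample pixels for the surface fit
  basis <- cbind(1, xs[sub], ys[sub], xs[sub]^2, ys[sub]^2,
                 xs[sub] * ys[sub])
  beta <- qr.coef(qr(basis), closing[sub])
  field <- beta[1] + beta[2] * xs + beta[3] * ys + beta[4] * xs^2 +
    beta[5] * ys^2 + beta[6] * xs * ys
  clip8(gray - field + 255)
}

#' Otsu's threshold
#'
#' Scans all 256 candidate thresholds and returns the `t` maximizing the
#' between-class variance of the split into levels `<= t` and `> t`; ties are
#' broken by the smallest `t`. Depends only on the intensity histogram.
#'
#' @param gray Grayscale image matrix with at least two distinct levels.
#' @return The threshold, an integer intensity in \[0, 255\].
#' @export
otsu_threshold <- function(gray) {
  assert_gray(gray, "gray")
  g <- as.integer(round(gray))
  p <- tabulate(g + 1L, nbins = 256L) / length(g)
  if (sum(p > 0) < 2) {
    stop("image has fewer than 2 distinct levels: histogram is degenerate",
         call. = FALSE)
  }
  w0 <- cumsum(p)
  mu <- cumsum(p * 0:255)
  mu_t <- mu[256]
  w1 <- 1 - w0
  sigma_b <- ifelse(w0 > 0 & w1 > 0, (mu_t * w0 - mu)^2 / (w0 * w1), 0)
  which.max(sigma_b) - 1L
}

#' Threshold-based region segmentation
#'
#' Binarizes the image at a threshold: pixels strictly above it form the
#' foreground region (rendered at full intensity, 255, when the mask is
#' written out as an image).
#'
#' @param gray Grayscale image matrix.
#' @param threshold Intensity cut in \[0, 255\].
#' @return Logical foreground mask.
#' @export
region_based_segmentation <- function(gray, threshold) {
  assert_gray(gray, "gray")
  gray > threshold
}

#' Extract the lesion region of interest
#'
#' Thresholds the grayscale image with Otsu's method, keeps the side of the
#' threshold the lesion lies on (`"dark"` by default, as pigmented lesions are
#' darker than surrounding skin), and retains the largest 8-connected
#' component of that side. The ROI image is the input with everything outside
#' the component zeroed.
#'
#' @param img RGB image array (0-255).
#' @param gray Optional grayscale matrix to threshold (defaults to the
#'   luminance of `img`).
#' @param polarity `"dark"` if the lesion is darker than the background,
#'   `"light"` otherwise.
#' @param exclude_border Drop components touching the image border before
#'   picking the largest (default `TRUE`): dark vignette corners and frame
#'   artifacts touch the border, while a fully imaged lesion does not. If
#'   every component touches the border the largest one is used regardless.
#' @return A list with `mask` (logical, a single connected component),
#'   `roi` (masked RGB array), and `threshold`.
#' @export
extract_roi <- function(img, gray = NULL, polarity = c("dark", "light"),
                        exclude_border = TRUE) {
  assert_rgb(img)
  polarity <- match.arg(polarity)
  if (is.null(gray)) gray <- to_grayscale(img)
  t <- otsu_threshold(gray)
  side <- if (polarity == "dark") gray <= t else gray > t
  if (!any(side)) {
    stop("no pixels on the ", polarity, " side of the Otsu threshold",
         call. = FALSE)
  }
  lab <- cc_label_cpp(side)
  counts <- tabulate(lab[lab > 0])
  if (exclude_border) {
    on_border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                          lab[, ncol(lab)]))
    interior <- setdiff(seq_along(counts), on_border)
    if (length(interior)) {
      counts[setdiff(seq_along(counts), interior)] <- 0L
    }
  }
  mask <- lab == which.max(counts)
  roi <- img
  for (ch in 1:3) {
    plane <- roi[, , ch]
    plane[!mask] <- 0
    roi[, , ch] <- plane
  }
  list(mask = mask, roi = roi, threshold = t)
}

# dispatch binary (pad 0) vs grayscale (reflect) morphology
morph_any <- function(x, se, dilate) {
  se <- as_se(se)
  if (is.logical(x)) {
    out <- morph_cpp(x + 0, se$dy, se$dx, numeric(length(se$dy)),
                     dilate, 1L, 0)
    out > 0.5
  } else {
    assert_gray(x, "x")
    morph_cpp(x, se$dy, se$dx, numeric(length(se$dy)), dilate, 0L, 0)
  }
}

#' Binary / grayscale erosion
#'
#' For a binary mask, `g(x, y) = 1` iff the structuring element placed at
#' `(x, y)` fits entirely inside the mask (outside the frame counts as
#' background); erosion peels pixels off object boundaries. Grayscale inputs
#' get the min-filter analogue with reflected borders.
#'
#' @param x Logical mask or grayscale matrix.
#' @param se A [structuring_element()] or an odd size (default 3 x 3 square).
#' @return Object of the same kind as `x`.
#' @export
erode <- function(x, se = structuring_element("square", 3)) {
  morph_any(x, se, dilate = FALSE)
}

#' Binary / grayscale dilation
#'
#' For a binary mask, `g(x, y) = 1` iff the structuring element placed at
#' `(x, y)` hits at least one mask pixel; dilation adds a layer of pixels to
#' object boundaries. Grayscale inputs get the max-filter analogue with
#' reflected borders.
#'
#' @inheritParams erode
#' @return Object of the same kind as `x`.
#' @export
dilate <- function(x, se = structuring_element("square", 3)) {
  morph_any(x, se, dilate = TRUE)
}

#' Morphological gradient
#'
#' Dilation minus erosion: a boundary-strength image that is nonzero exactly
#' where the structuring element straddles an object edge. For a binary mask
#' the result is the symmetric set difference of the dilation and the erosion,
#' returned as a logical matrix.
#'
#' @inheritParams erode
#' @return Logical matrix for mask input, non-negative numeric matrix for
#'   grayscale input.
#' @export
morphological_gradient <- function(x, se = structuring_element("square", 3)) {
  d <- dilate(x, se)
  e <- erode(x, se)
  if (is.logical(x)) d & !e else d - e
}
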