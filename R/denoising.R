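# Background correction and the five spatial denoising filters. All filters
# operate on grayscale matrices on the 0-255 scale, use reflected borders, and
# return unrounded numeric matrices so that repeated analysis steps do not
# accumulate quantization error; callers round with their final 8-bit write.

# offsets and height profile of a spherical-cap ("rolling ball") structuring
# element of the given radius
ball_element <- function(radius) {
  r <- ceiling(radius)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- offs$dy^2 + offs$dx^2 <= radius^2
  offs <- offs[keep, , drop = FALSE]
  list(dy = as.integer(offs$dy), dx = as.integer(offs$dx),
       h = sqrt(radius^2 - offs$dy^2 - offs$dx^2))
}

#' Rolling-ball background estimation and correction
#'
#' Estimates the background of a grayscale image as the grayscale opening of
#' the intensity surface by a ball-shaped (spherical-cap height profile)
#' structuring element -- the surface traced by a ball of the given radius
#' rolled beneath the image surface -- and subtracts it. Subtraction flattens
#' slowly varying illumination such as a vignette while preserving structures
#' the ball cannot follow.
#'
#' @param gray Grayscale image matrix.
#' @param ball_radius Ball radius in pixels (default 30, classic practice for
#'   images around 224 x 224).
#' @return A list with `background` (the opening; everywhere `<=` the input)
#'   and `corrected` (`input - background`, clipped to \[0, 255\]).
#' @export
rolling_ball <- function(gray, ball_radius = 30) {
  assert_gray(gray, "gray")
  if (ball_radius < 1) stop("`ball_radius` must be >= 1", call. = FALSE)
  b <- ball_element(ball_radius)
  eroded <- morph_cpp(gray, b$dy, b$dx, b$h, FALSE, 0L, 0)
  background <- morph_cpp(eroded, b$dy, b$dx, b$h, TRUE, 0L, 0)
  corrected <- gray - background
  corrected[corrected < 0] <- 0
  corrected[corrected > 255] <- 255
  list(background = background, corrected = corrected)
}

#' Non-local means denoising
#'
#' Replaces each pixel by a weighted average of the pixels in a search window,
#' with weights `exp(-||patch_i - patch_j||^2 / h^2)` computed from squared
#' Euclidean distances between the square patches around the two pixels and
#' normalized to sum to one at every pixel. Pixels whose neighborhoods look
#' alike average together regardless of spatial distance within the window.
#'
#' @param gray Grayscale image matrix.
#' @param nlm_h Filtering strength `h` in intensity units (default 10).
#' @param nlm_patch Odd patch side (default 7).
#' @param nlm_window Odd search-window side (default 21); must be `>=`
#'   `nlm_patch`.
#' @return Filtered numeric matrix.
#' @export
nlm_filter <- function(gray, nlm_h = 10, nlm_patch = 7, nlm_window = 21) {
  assert_gray(gray, "gray")
  assert_odd(nlm_patch, "nlm_patch")
  assert_odd(nlm_window, "nlm_window")
  if (nlm_h <= 0) stop("`nlm_h` must be > 0", call. = FALSE)
  if (nlm_patch > nlm_window) {
    stop("`nlm_patch` must not exceed `nlm_window`", call. = FALSE)
  }
  nlm_cpp(gray, nlm_h, as.integer(nlm_patch), as.integer(nlm_window))
}

#' Mean (box) filter
#'
#' Sliding-window arithmetic mean over a `kernel_size` square neighborhood.
#'
#' @param gray Grayscale image matrix.
#' @param kernel_size Odd window side (default 3).
#' @return Filtered numeric matrix.
#' @export
mean_filter <- function(gray, kernel_size = 3) {
  assert_gray(gray, "gray")
  assert_odd(kernel_size, "kernel_size")
  r <- (kernel_size - 1) / 2
  acc <- matrix(0, nrow(gray), ncol(gray))
  for (dy in -r:r) {
    for (dx in -r:r) {
      acc <- acc + shift_reflect(gray, dy, dx)
    }
  }
  acc / kernel_size^2
}

#' Median filter
#'
#' Sliding-window median over a `kernel_size` square neighborhood; removes
#' impulse noise while preserving edges.
#'
#' @inheritParams mean_filter
#' @return Filtered numeric matrix.
#' @export
median_filter <- function(gray, kernel_size = 3) {
  assert_gray(gray, "gray")
  assert_odd(kernel_size, "kernel_size")
  median_filter_cpp(gray, as.integer(kernel_size))
}

#' Gaussian filter
#'
#' Convolution with a normalized, truncated Gaussian kernel
#' `exp(-(dx^2 + dy^2) / (2 sigma^2)) / M`, where the normalizer `M` makes the
#' kernel weights sum to one. The kernel is truncated at radius
#' `ceiling(3 sigma)`.
#'
#' @param gray Grayscale image matrix.
#' @param sigma Kernel standard deviation in pixels (default 1).
#' @return Filtered numeric matrix.
#' @export
gaussian_filter <- function(gray, sigma = 1) {
  assert_gray(gray, "gray")
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  r <- ceiling(3 * sigma)
  k <- outer(-r:r, -r:r, function(dy, dx) exp(-(dy^2 + dx^2) / (2 * sigma^2)))
  k <- k / sum(k)
  acc <- matrix(0, nrow(gray), ncol(gray))
  for (i in seq_len(2 * r + 1)) {
    for (j in seq_len(2 * r + 1)) {
      acc <- acc + k[i, j] * shift_reflect(gray, i - r - 1, j - r - 1)
    }
  }
  acc
}

#' Conservative smoothing
#'
#' Clamps each pixel to the range of its neighbors: a pixel above the maximum
#' of its `kernel_size` square neighborhood (center excluded) is replaced by
#' that maximum, one below the neighborhood minimum by that minimum, and any
#' other pixel is left unchanged. Removes isolated impulse pixels while
#' leaving all genuine detail untouched.
#'
#' @inheritParams mean_filter
#' @return Filtered numeric matrix, globally bounded by the input range.
#' @export
conservative_smoothing <- function(gray, kernel_size = 3) {
  assert_gray(gray, "gray")
  assert_odd(kernel_size, "kernel_size")
  conservative_cpp(gray, as.integer(kernel_size))
}

#' Apply one of the five denoising filters by name
#'
#' @param gray Grayscale image matrix.
#' @param method One of `"nlmd"`, `"mean"`, `"median"`, `"gaussian"`,
#'   `"conservative"`.
#' @param params Optional named list of filter parameters (`kernel_size`,
#'   `sigma`, `nlm_h`, `nlm_patch`, `nlm_window`).
#' @return Filtered numeric matrix.
#' @export
apply_filter <- function(gray, method = c("nlmd", "mean", "median", "gaussian",
                                          "conservative"),
                         params = list()) {
  method <- match.arg(method)
  call_with <- function(fn, allowed) {
    do.call(fn, c(list(gray), params[intersect(names(params), allowed)]))
  }
  switch(method,
         nlmd = call_with(nlm_filter, c("nlm_h", "nlm_patch", "nlm_window")),
         mean = call_with(mean_filter, "kernel_size"),
         median = call_with(median_filter, "kernel_size"),
         gaussian = call_with(gaussian_filter, "sigma"),
         conservative = call_with(conservative_smoothing, "kernel_size"))
}
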