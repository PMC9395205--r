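# Digital hair removal: grayscale conversion, morphological BlackHat, binary
# thresholding of the hair response, and diffusion inpainting of the detected
# strokes. Hairs are thin structures darker than the surrounding skin, so the
# BlackHat response (closing minus image) is large exactly on them.

#' Convert an RGB image to 8-bit grayscale
#'
#' Weighted-luminance conversion with ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B), rounded to whole levels.
#'
#' @param img H x W x 3 numeric array on the 0-255 scale.
#' @return Numeric matrix of 8-bit intensities.
#' @export
to_grayscale <- function(img) {
  assert_rgb(img)
  out <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  matrix(round(out), dim(img)[1], dim(img)[2])
}

#' Morphological BlackHat transform
#'
#' `closing(A, B) - A` with a flat square structuring element `B`, computed
#' with reflected image borders. The response is non-negative and highlights
#' structures darker than their surroundings and thinner than the structuring
#' element -- for dermoscopy, hairs.
#'
#' @param gray Grayscale image matrix.
#' @param se_size Odd side length of the square structuring element
#'   (default 23, sized for hairs in 224 x 224 images).
#' @return Matrix of non-negative BlackHat responses.
#' @export
blackhat <- function(gray, se_size = 23) {
  assert_gray(gray, "gray")
  assert_odd(se_size, "se_size")
  closed <- flat_morph_gray(flat_morph_gray(gray, se_size, dilate = TRUE),
                            se_size, dilate = FALSE)
  closed - gray
}

#' Threshold a BlackHat response into a hair mask
#'
#' @param bh BlackHat response matrix.
#' @param threshold Intensity cut in \[0, 255\]; pixels with response strictly
#'   greater are marked as hair. The default 10 is a configurable choice (low
#'   enough for faint hairs, above the noise floor), not a value fixed by the
#'   method.
#' @return Logical hair mask.
#' @export
hair_mask <- function(bh, threshold = 10) {
  assert_gray(bh, "bh")
  if (threshold < 0 || threshold > 255) {
    stop("`threshold` must lie in [0, 255]", call. = FALSE)
  }
  bh > threshold
}

#' Diffusion inpainting of masked pixels
#'
#' Reconstructs the masked region by iterated neighbor-averaging diffusion:
#' each masked pixel is repeatedly replaced by the unweighted mean of its
#' available 8-neighbors (zero weight at the center, kernel renormalized over
#' in-bounds, already-valid neighbors), each RGB channel independently.
#' Pixels outside the mask are preserved bit-exactly, and inpainted values obey
#' the discrete maximum principle: they stay within the range of the boundary
#' values they diffuse from.
#'
#' @param img RGB array (0-255) or grayscale matrix.
#' @param mask Logical mask of pixels to reconstruct.
#' @param num_iterations Maximum number of diffusion sweeps (default 32); the
#'   iteration stops early once every masked pixel is filled and the largest
#'   per-pixel change drops below half an intensity level.
#' @return Image of the same kind as `img`, rounded to 8-bit levels.
#' @export
inpaint <- function(img, mask, num_iterations = 32) {
  assert_mask(mask)
  if (num_iterations < 1) stop("`num_iterations` must be >= 1", call. = FALSE)
  if (all(mask)) {
    stop("mask covers the whole image: no boundary to diffuse from",
         call. = FALSE)
  }
  if (is.matrix(img)) {
    if (!all(dim(mask) == dim(img))) {
      stop("mask and image dimensions differ", call. = FALSE)
    }
    out <- inpaint_cpp(img, mask, as.integer(num_iterations), 0.5)
    out[mask] <- clip8(out[mask])
    return(out)
  }
  assert_rgb(img)
  if (!all(dim(mask) == dim(img)[1:2])) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  out <- img
  for (ch in 1:3) {
    plane <- inpaint_cpp(img[, , ch], mask, as.integer(num_iterations), 0.5)
    plane[mask] <- clip8(plane[mask])
    out[, , ch] <- plane
  }
  out
}

#' Remove hairs from a dermoscopy image
#'
#' Composition of the four hair-removal steps: grayscale conversion,
#' BlackHat transform, binary thresholding into a hair mask, and diffusion
#' inpainting of the masked strokes.
#'
#' @inheritParams blackhat
#' @inheritParams inpaint
#' @param img RGB image array on the 0-255 scale.
#' @param threshold Binary threshold on the BlackHat response (see
#'   [hair_mask()]).
#' @return A list with `image` (hair-free RGB array) and `mask` (the detected
#'   logical hair mask).
#' @export
remove_hairs <- function(img, se_size = 23, threshold = 10,
                         num_iterations = 32) {
  assert_rgb(img)
  gray <- to_grayscale(img)
  mask <- hair_mask(blackhat(gray, se_size), threshold)
  out <- if (any(mask)) inpaint(img, mask, num_iterations) else img
  list(image = out, mask = mask)
}
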