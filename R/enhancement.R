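# Contrast enhancement (histogram equalization, piecewise linear transform),
# full-reference image quality metrics (PSNR, MAE, SSIM, histogram distance,
# Dice), and the rank-sum procedure that picks the best filter x enhancement
# combination from a grid of per-image quality reports.

#' Histogram equalization
#'
#' Maps each intensity `n` to `floor((L - 1) * cumsum(p)[n])`, where `p` is the
#' normalized 256-bin histogram of the image (`L = 256`). Spreads the intensity
#' mass so the cumulative distribution of the output is approximately linear.
#'
#' @param gray Grayscale image matrix with values in \[0, 255\].
#' @return Equalized matrix of integers in \[0, 255\].
#' @export
hist_equalize <- function(gray) {
  assert_gray(gray, "gray")
  g <- as.integer(round(gray))
  p <- tabulate(g + 1L, nbins = 256L) / length(g)
  lut <- floor(255 * cumsum(p))
  matrix(lut[g + 1L], nrow(gray), ncol(gray))
}

#' Piecewise linear intensity transformation
#'
#' Maps pixel intensities through the continuous piecewise-linear function
#' defined by control points, stretching chosen input ranges over the full
#' dynamic range. The mapping is monotone whenever the output coordinates are.
#'
#' @param gray Grayscale image matrix.
#' @param breakpoints Two-column matrix (or data frame) of `(input, output)`
#'   control points; inputs must be strictly increasing with endpoints at 0
#'   and 255.
#' @return Transformed matrix, rounded to integers in \[0, 255\].
#' @export
piecewise_linear_transform <- function(gray, breakpoints) {
  assert_gray(gray, "gray")
  bp <- as.matrix(breakpoints)
  if (ncol(bp) != 2 || nrow(bp) < 2) {
    stop("`breakpoints` must be a matrix of (input, output) pairs",
         call. = FALSE)
  }
  if (any(diff(bp[, 1]) <= 0)) {
    stop("breakpoint inputs must be strictly increasing", call. = FALSE)
  }
  if (bp[1, 1] != 0 || bp[nrow(bp), 1] != 255) {
    stop("breakpoint inputs must start at 0 and end at 255", call. = FALSE)
  }
  out <- approx(bp[, 1], bp[, 2], xout = as.vector(gray))$y
  matrix(clip8(out), nrow(gray), ncol(gray))
}

#' Percentile-stretch control points for the piecewise linear transform
#'
#' Builds breakpoints mapping the \[`lower`, `upper`\] intensity percentiles of
#' the image onto the full \[0, 255\] range (defaults: 2 percent and 98
#' percent), the usual way to realize a dynamic-range increase without fixing
#' absolute control points.
#'
#' @param gray Grayscale image matrix.
#' @param lower,upper Percentile fractions in \[0, 1\].
#' @return A breakpoint matrix suitable for [piecewise_linear_transform()].
#' @export
plt_stretch_breakpoints <- function(gray, lower = 0.02, upper = 0.98) {
  assert_gray(gray, "gray")
  q <- unname(quantile(gray, c(lower, upper), names = FALSE))
  lo <- floor(q[1]); hi <- ceiling(q[2])
  if (hi <= lo) return(cbind(c(0, 255), c(0, 255)))
  xin <- c(0, lo, hi, 255)
  yout <- c(0, 0, 255, 255)
  keep <- !duplicated(xin)
  cbind(xin[keep], yout[keep])
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(255^2 / MSE)` in dB for 8-bit images; identical images are
#' reported as `Inf`. Symmetric in its arguments.
#'
#' @param reference,test Grayscale matrices of equal size.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test) {
  assert_gray(reference, "reference"); assert_gray(test, "test")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

#' Mean absolute error between two images
#'
#' @inheritParams psnr
#' @return MAE in intensity units.
#' @export
mae <- function(reference, test) {
  assert_gray(reference, "reference"); assert_gray(test, "test")
  mean(abs(reference - test))
}

# sums of all k x k windows fully inside the matrix, via an integral image
box_sums <- function(mat, k) {
  s <- apply(apply(mat, 2, cumsum), 1, cumsum)  # transposed integral image
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  nr <- nrow(mat); nc <- ncol(mat)
  iy <- seq_len(nr - k + 1); ix <- seq_len(nc - k + 1)
  s[iy + k, ix + k, drop = FALSE] - s[iy, ix + k, drop = FALSE] -
    s[iy + k, ix, drop = FALSE] + s[iy, ix, drop = FALSE]
}

#' Structural similarity index
#'
#' Mean SSIM over all uniform square windows (default 8 x 8, stride 1) fully
#' inside the image, with the standard stabilizers `C1 = (0.01 * 255)^2` and
#' `C2 = (0.03 * 255)^2` and population (divide-by-N) moments per window.
#' Equals 1 for identical images and never exceeds 1.
#'
#' @inheritParams psnr
#' @param window Window side in pixels (default 8).
#' @return SSIM value in \[-1, 1\].
#' @export
ssim <- function(reference, test, window = 8) {
  assert_gray(reference, "reference"); assert_gray(test, "test")
  if (!all(dim(reference) == dim(test))) {
    stop("images must have the same dimensions", call. = FALSE)
  }
  if (any(dim(reference) < window)) {
    stop("image smaller than the SSIM window", call. = FALSE)
  }
  n <- window^2
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  mx <- box_sums(reference, window) / n
  my <- box_sums(test, window) / n
  vx <- box_sums(reference^2, window) / n - mx^2
  vy <- box_sums(test^2, window) / n - my^2
  cxy <- box_sums(reference * test, window) / n - mx * my
  s <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`, in \[0, 1\]; 1 for identical masks
#' (two empty masks count as identical), 0 for disjoint nonempty masks.
#'
#' @param mask_a,mask_b Logical matrices of equal size.
#' @return Dice score.
#' @export
dice <- function(mask_a, mask_b) {
  assert_mask(mask_a, "mask_a"); assert_mask(mask_b, "mask_b")
  if (!all(dim(mask_a) == dim(mask_b))) {
    stop("masks must have the same dimensions", call. = FALSE)
  }
  tot <- sum(mask_a) + sum(mask_b)
  if (tot == 0) return(1)
  2 * sum(mask_a & mask_b) / tot
}

#' Histogram distance between two images
#'
#' Half the L1 distance between the normalized intensity histograms of the two
#' images (`bins` equal-width bins over \[0, 255\]): 0 for identical
#' histograms, 1 for fully disjoint ones.
#'
#' @inheritParams psnr
#' @param bins Number of histogram bins (default 256).
#' @return Distance in \[0, 1\].
#' @export
histogram_compare <- function(reference, test, bins = 256) {
  assert_gray(reference, "reference"); assert_gray(test, "test")
  bin_of <- function(img) {
    b <- floor(as.vector(img) / 256 * bins) + 1
    b[b > bins] <- bins
    tabulate(b, nbins = bins) / length(img)
  }
  sum(abs(bin_of(reference) - bin_of(test))) / 2
}

#' Bundle the quality metrics for one reference/test pair
#'
#' @inheritParams psnr
#' @inheritParams histogram_compare
#' @param mask_a,mask_b Optional logical masks; when both are given a Dice
#'   score is included.
#' @return A one-row data frame with columns `psnr`, `mae`, `ssim`,
#'   `histogram_distance`, and optionally `dice`.
#' @export
quality_report <- function(reference, test, bins = 256,
                           mask_a = NULL, mask_b = NULL) {
  out <- data.frame(psnr = psnr(reference, test),
                    mae = mae(reference, test),
                    ssim = ssim(reference, test),
                    histogram_distance = histogram_compare(reference, test,
                                                           bins))
  if (!is.null(mask_a) && !is.null(mask_b)) out$dice <- dice(mask_a, mask_b)
  out
}

#' Select the best filter and enhancement combination
#'
#' Given per-image quality reports for every filter x enhancement candidate,
#' ranks the candidates within each image on each metric (higher PSNR and SSIM
#' better, lower MAE better) and returns the candidate with the lowest summed
#' rank; ties are broken by the higher mean PSNR. The result is invariant to
#' the order the grid rows are listed in.
#'
#' @param grid Data frame with columns `image`, `filter`, `enhancement`,
#'   `psnr`, `mae`, `ssim`; every image must carry a row for every
#'   filter x enhancement combination.
#' @return A list with `filter`, `enhancement`, and the aggregate `ranks`
#'   table.
#' @export
select_best <- function(grid) {
  need <- c("image", "filter", "enhancement", "psnr", "mae", "ssim")
  if (!all(need %in% names(grid))) {
    stop("grid must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  grid$candidate <- paste(grid$filter, grid$enhancement, sep = "|")
  combos <- sort(unique(grid$candidate))
  for (im in unique(grid$image)) {
    have <- sort(grid$candidate[grid$image == im])
    if (!identical(have, combos)) {
      stop("grid is incomplete: image ", im,
           " is missing filter x enhancement combinations", call. = FALSE)
    }
  }
  score <- setNames(numeric(length(combos)), combos)
  for (im in unique(grid$image)) {
    sub <- grid[grid$image == im, ]
    o <- match(combos, sub$candidate)
    score <- score + rank(-sub$psnr[o]) + rank(-sub$ssim[o]) +
      rank(sub$mae[o])
  }
  best <- names(score)[score == min(score)]
  if (length(best) > 1) {
    mean_psnr <- vapply(best, function(cand) {
      mean(grid$psnr[grid$candidate == cand])
    }, numeric(1))
    best <- best[order(-mean_psnr, best)][1]
  }
  parts <- strsplit(best, "|", fixed = TRUE)[[1]]
  ranks <- data.frame(filter = sub("\\|.*$", "", names(score)),
                      enhancement = sub("^.*\\|", "", names(score)),
                      rank_sum = as.numeric(score), row.names = NULL)
  list(filter = parts[1], enhancement = parts[2],
       ranks = ranks[order(ranks$rank_sum), ])
}
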