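# Internal helpers shared across modules: image validation, seeded evaluation,
# boundary-reflecting shifts, and 8-bit clipping.

# run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never disturb the session RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix (grayscale image)", arg),
         call. = FALSE)
  }
  invisible(img)
}

assert_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop(sprintf("`%s` must be an H x W x 3 array (RGB image)", arg),
         call. = FALSE)
  }
  invisible(img)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop(sprintf("`%s` must be a logical matrix (binary mask)", arg),
         call. = FALSE)
  }
  invisible(mask)
}

assert_odd <- function(x, arg) {
  if (length(x) != 1L || is.na(x) || x < 1 || x %% 2 != 1) {
    stop(sprintf("`%s` must be a positive odd integer", arg), call. = FALSE)
  }
  invisible(x)
}

# clip to [0, 255] and round to whole 8-bit levels
clip8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  round(x)
}

# symmetric boundary reflection of indices 1..n (matches the C++ kernels)
reflect_index <- function(i, n) {
  i <- i - 1L
  while (any(bad <- (i < 0L | i >= n))) {
    i[bad & i < 0L] <- -i[bad & i < 0L] - 1L
    bad <- i >= n
    i[bad] <- 2L * n - i[bad] - 1L
  }
  i + 1L
}

# shift a matrix by (dy, dx) with reflected borders
shift_reflect <- function(mat, dy, dx) {
  nr <- nrow(mat); nc <- ncol(mat)
  mat[reflect_index(seq_len(nr) + dy, nr), reflect_index(seq_len(nc) + dx, nc),
      drop = FALSE]
}

# flat grayscale erosion/dilation by a k x k square SE, reflect borders;
# separable into a row pass and a column pass
flat_morph_gray <- function(img, k, dilate) {
  r <- (k - 1L) / 2L
  offs <- seq.int(-r, r)
  out <- morph_cpp(img, as.integer(offs), integer(length(offs)),
                   numeric(length(offs)), dilate, 0L, 0)
  morph_cpp(out, integer(length(offs)), as.integer(offs),
            numeric(length(offs)), dilate, 0L, 0)
}
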