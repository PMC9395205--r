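# Independent brute-force oracles used across the suite. Everything here is a
# literal, slow evaluation of the mathematical definitions, deliberately
# sharing no code with the package implementation.

# symmetric border reflection of a 1-based index (literal while-loop version)
oref <- function(i, n) {
  i <- i - 1L
  while (i < 0L || i >= n) {
    if (i < 0L) i <- -i - 1L
    if (i >= n) i <- 2L * n - i - 1L
  }
  i + 1L
}

# grayscale min/max filter over explicit offsets, reflect borders
oracle_morph_reflect <- function(img, offs, dilate) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (y in seq_len(nr)) {
    for (x in seq_len(nc)) {
      vals <- apply(offs, 1, function(o) {
        img[oref(y + o[1], nr), oref(x + o[2], nc)]
      })
      out[y, x] <- if (dilate) max(vals) else min(vals)
    }
  }
  out
}

square_offsets <- function(k) {
  r <- (k - 1) / 2
  as.matrix(expand.grid(dy = -r:r, dx = -r:r))
}

# BlackHat by its definition: max-filter, then min-filter, minus the input
oracle_blackhat <- function(img, k = 3) {
  offs <- square_offsets(k)
  oracle_morph_reflect(oracle_morph_reflect(img, offs, TRUE), offs, FALSE) -
    img
}

# binary erosion/dilation set definitions with the frame exterior treated as
# background: erosion requires every SE cell on a mask pixel inside the frame
oracle_erode_binary <- function(mask, k = 3) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- square_offsets(k)
  out <- matrix(FALSE, nr, nc)
  for (y in seq_len(nr)) {
    for (x in seq_len(nc)) {
      fits <- TRUE
      for (j in seq_len(nrow(offs))) {
        yy <- y + offs[j, 1]; xx <- x + offs[j, 2]
        if (yy < 1 || yy > nr || xx < 1 || xx > nc || !mask[yy, xx]) {
          fits <- FALSE; break
        }
      }
      out[y, x] <- fits
    }
  }
  out
}

oracle_dilate_binary <- function(mask, k = 3) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- square_offsets(k)
  out <- matrix(FALSE, nr, nc)
  for (y in seq_len(nr)) {
    for (x in seq_len(nc)) {
      hit <- FALSE
      for (j in seq_len(nrow(offs))) {
        yy <- y + offs[j, 1]; xx <- x + offs[j, 2]
        if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc && mask[yy, xx]) {
          hit <- TRUE; break
        }
      }
      out[y, x] <- hit
    }
  }
  out
}

# every 4 x 4 binary mask as a row of a 65536 x 16 matrix (column-major pixel
# order), plus vectorized evaluations of the same set definitions: each output
# pixel is a pmin/pmax over the neighbor columns of all masks at once
all_masks_4x4 <- function() {
  bits <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 16)))
  dimnames(bits) <- NULL
  bits
}

neighbor_cols_4x4 <- function(k = 3, reflect = FALSE) {
  offs <- square_offsets(k)
  lapply(seq_len(16), function(j) {
    y <- ((j - 1) %% 4) + 1; x <- ((j - 1) %/% 4) + 1
    cols <- integer(0); oob <- FALSE
    for (r in seq_len(nrow(offs))) {
      yy <- y + offs[r, 1]; xx <- x + offs[r, 2]
      if (reflect) { yy <- oref(yy, 4L); xx <- oref(xx, 4L) }
      if (yy < 1 || yy > 4 || xx < 1 || xx > 4) oob <- TRUE
      else cols <- c(cols, (xx - 1) * 4 + yy)
    }
    list(cols = cols, oob = oob)
  })
}

# vectorized over all masks M (rows): binary erode with zero padding
oracle_erode_all <- function(M, nb) {
  out <- matrix(FALSE, nrow(M), 16)
  for (j in seq_len(16)) {
    if (nb[[j]]$oob) next  # SE hangs over the frame: never fits
    out[, j] <- rowSums(M[, nb[[j]]$cols, drop = FALSE]) ==
      length(nb[[j]]$cols)
  }
  out
}

oracle_dilate_all <- function(M, nb) {
  out <- matrix(FALSE, nrow(M), 16)
  for (j in seq_len(16)) {
    out[, j] <- rowSums(M[, nb[[j]]$cols, drop = FALSE]) > 0
  }
  out
}

# vectorized grayscale min/max with reflected borders (for BlackHat grids)
oracle_minmax_all <- function(V, nb, dilate) {
  out <- matrix(0, nrow(V), 16)
  for (j in seq_len(16)) {
    block <- V[, nb[[j]]$cols, drop = FALSE]
    out[, j] <- if (dilate) do.call(pmax, as.data.frame(block)) else
      do.call(pmin, as.data.frame(block))
  }
  out
}

# literal double-loop filters with reflect borders
oracle_mean_filter <- function(img, k = 3) {
  offs <- square_offsets(k)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    out[y, x] <- mean(apply(offs, 1, function(o) {
      img[oref(y + o[1], nr), oref(x + o[2], nc)]
    }))
  }
  out
}

oracle_median_filter <- function(img, k = 3) {
  offs <- square_offsets(k)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    out[y, x] <- median(apply(offs, 1, function(o) {
      img[oref(y + o[1], nr), oref(x + o[2], nc)]
    }))
  }
  out
}

oracle_gaussian_filter <- function(img, sigma = 1) {
  r <- ceiling(3 * sigma)
  kern <- outer(-r:r, -r:r,
                function(dy, dx) exp(-(dy^2 + dx^2) / (2 * sigma^2)))
  kern <- kern / sum(kern)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    acc <- 0
    for (dy in -r:r) for (dx in -r:r) {
      acc <- acc + kern[dy + r + 1, dx + r + 1] *
        img[oref(y + dy, nr), oref(x + dx, nc)]
    }
    out[y, x] <- acc
  }
  out
}

oracle_conservative <- function(img, k = 3) {
  offs <- square_offsets(k)
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    vals <- apply(offs, 1, function(o) {
      img[oref(y + o[1], nr), oref(x + o[2], nc)]
    })
    out[y, x] <- min(max(vals), max(min(vals), img[y, x]))
  }
  out
}

# literal four-nested-loop non-local means (plain squared Euclidean patch
# distance, normalized weights, reflect borders)
oracle_nlm <- function(img, h, patch, window) {
  nr <- nrow(img); nc <- ncol(img)
  pr <- (patch - 1) / 2; wr <- (window - 1) / 2
  out <- matrix(0, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    wsum <- 0; vsum <- 0
    for (jy in (y - wr):(y + wr)) for (jx in (x - wr):(x + wr)) {
      d2 <- 0
      for (py in -pr:pr) for (px in -pr:pr) {
        a <- img[oref(y + py, nr), oref(x + px, nc)]
        b <- img[oref(jy + py, nr), oref(jx + px, nc)]
        d2 <- d2 + (a - b)^2
      }
      w <- exp(-d2 / h^2)
      wsum <- wsum + w
      vsum <- vsum + w * img[oref(jy, nr), oref(jx, nc)]
    }
    out[y, x] <- vsum / wsum
  }
  out
}

# non-flat (ball) grayscale opening by brute force: min of (f - h) then
# max of (g + h) over the ball offsets, reflect borders
oracle_ball_opening <- function(img, radius) {
  r <- ceiling(radius)
  offs <- as.matrix(expand.grid(dy = -r:r, dx = -r:r))
  offs <- offs[offs[, 1]^2 + offs[, 2]^2 <= radius^2, , drop = FALSE]
  hts <- sqrt(radius^2 - offs[, 1]^2 - offs[, 2]^2)
  nr <- nrow(img); nc <- ncol(img)
  pass <- function(src, dilate) {
    out <- matrix(0, nr, nc)
    for (y in seq_len(nr)) for (x in seq_len(nc)) {
      vals <- vapply(seq_len(nrow(offs)), function(j) {
        v <- src[oref(y + offs[j, 1], nr), oref(x + offs[j, 2], nc)]
        if (dilate) v + hts[j] else v - hts[j]
      }, numeric(1))
      out[y, x] <- if (dilate) max(vals) else min(vals)
    }
    out
  }
  pass(pass(img, FALSE), TRUE)
}

# direct between-class-variance scan for Otsu (class statistics recomputed
# from scratch at every candidate threshold)
oracle_otsu <- function(values) {
  v <- as.integer(round(values))
  best_t <- NA_integer_; best_s <- -Inf
  for (t in 0:255) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# single-window SSIM formula, evaluated directly
oracle_ssim <- function(a, b, window = 8) {
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  nr <- nrow(a); nc <- ncol(a)
  vals <- c()
  for (y in seq_len(nr - window + 1)) {
    for (x in seq_len(nc - window + 1)) {
      wa <- a[y:(y + window - 1), x:(x + window - 1)]
      wb <- b[y:(y + window - 1), x:(x + window - 1)]
      ma <- mean(wa); mb <- mean(wb)
      va <- mean((wa - ma)^2); vb <- mean((wb - mb)^2)
      cab <- mean((wa - ma) * (wb - mb))
      vals <- c(vals, ((2 * ma * mb + c1) * (2 * cab + c2)) /
                  ((ma^2 + mb^2 + c1) * (va + vb + c2)))
    }
  }
  mean(vals)
}

# pixel-count rasterization of an axis-aligned ellipse, written independently
oracle_ellipse_count <- function(h, w, cy, cx, a, b) {
  count <- 0
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1) count <- count + 1
  }
  count
}

# a small random 8-bit test image
rand_gray <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
}

# numerical gradient of the full training loss by central finite differences
fd_gradients <- function(model, x, y, eps = 1e-5) {
  loss_of <- function(m) {
    skinnet_loss(skinnet_forward(m, x)$probs, y, m)
  }
  num_for <- function(getter, setter) {
    p <- getter(model)
    g <- array(0, dim = dim(as.array(p)))
    for (i in seq_along(p)) {
      pp <- p; pp[i] <- p[i] + eps
      lp <- loss_of(setter(model, pp))
      pp[i] <- p[i] - eps
      lm <- loss_of(setter(model, pp))
      g[i] <- (lp - lm) / (2 * eps)
    }
    g
  }
  list(
    weights = lapply(seq_along(model$weights), function(l) {
      num_for(function(m) m$weights[[l]],
              function(m, v) { m$weights[[l]] <- v; m })
    }),
    biases = lapply(seq_along(model$biases), function(l) {
      num_for(function(m) m$biases[[l]],
              function(m, v) { m$biases[[l]] <- v; m })
    })
  )
}
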