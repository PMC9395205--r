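test_that("histogram equalization follows the cumulative-histogram mapping", {
  expect_true(all(hist_equalize(matrix(7, 4, 4)) == 255))
  two <- matrix(c(0, 0, 255, 255), 2, 2)
  expect_equal(sort(unique(as.vector(hist_equalize(two)))), c(127, 255))
  expect_equal(hist_equalize(two)[two == 0], c(127, 127))

  img <- rand_gray(16, 16, 21)
  he <- hist_equalize(img)
  expect_true(all(he >= 0 & he <= 255))
  # idempotent up to quantization: at most 1-level changes on reapplication
  expect_lte(max(abs(hist_equalize(he) - he)), 1)
})

test_that("piecewise linear transform interpolates through control points", {
  img <- matrix(c(0, 50, 125, 200, 255, 99), 2, 3)
  ident <- piecewise_linear_transform(img, cbind(c(0, 255), c(0, 255)))
  expect_equal(ident, img)

  bp <- cbind(c(0, 50, 200, 255), c(0, 0, 255, 255))
  out <- piecewise_linear_transform(img, bp)
  expect_equal(out[img == 125], 128)  # round(255 * 75 / 150)
  expect_equal(out[img == 50], 0)
  expect_equal(out[img == 255], 255)

  # monotone breakpoints preserve pixel ordering
  a <- rand_gray(8, 8, 2)
  outm <- piecewise_linear_transform(a, bp)
  ord <- order(as.vector(a))
  expect_true(all(diff(as.vector(outm)[ord]) >= 0))

  expect_error(piecewise_linear_transform(img, cbind(c(0, 100, 50, 255),
                                                     c(0, 1, 2, 255))),
               "increasing")
  expect_error(piecewise_linear_transform(img, cbind(c(10, 255), c(0, 255))),
               "start at 0")
})

test_that("PSNR has its closed forms and decreases with noise", {
  a <- rand_gray(16, 16, 5)
  expect_identical(psnr(a, a), Inf)
  expect_equal(psnr(a, a + 1), 10 * log10(255^2))
  b <- rand_gray(16, 16, 6)
  expect_equal(psnr(a, b), psnr(b, a))

  set.seed(31)
  vals <- vapply(c(1, 2, 4, 8, 16), function(s) {
    psnr(a, a + matrix(rnorm(256, sd = s), 16, 16))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("MAE and histogram distance follow their definitions", {
  a <- rand_gray(8, 8, 9)
  expect_equal(mae(a, a), 0)
  expect_equal(mae(a, a + 3), 3)
  x <- matrix(c(0, 10, 20, 30), 2, 2)
  y <- matrix(c(4, 10, 26, 30), 2, 2)
  expect_equal(mae(x, y), (4 + 0 + 6 + 0) / 4)

  expect_equal(histogram_compare(a, a), 0)
  expect_equal(histogram_compare(matrix(0, 4, 4), matrix(255, 4, 4)), 1)
  # hand-binned L1/2 on a toy pair with 4 bins of width 64
  h1 <- matrix(c(0, 0, 100, 200), 2, 2)   # bins 1,1,2,4
  h2 <- matrix(c(0, 100, 100, 100), 2, 2) # bins 1,2,2,2
  expect_equal(histogram_compare(h1, h2, bins = 4),
               0.5 * (abs(2 - 1) + abs(1 - 3) + 0 + abs(1 - 0)) / 4)
})

test_that("SSIM equals 1 on identical images and matches the formula", {
  a <- rand_gray(16, 16, 12)
  expect_equal(ssim(a, a), 1)
  b <- rand_gray(16, 16, 13)
  expect_lte(ssim(a, b), 1)
  expect_equal(ssim(a, b), oracle_ssim(a, b), tolerance = 1e-10)
  noisy <- a + matrix(round(rnorm(256, sd = 10)), 16, 16)
  expect_equal(ssim(a, noisy), oracle_ssim(a, noisy), tolerance = 1e-10)
})

test_that("Dice handles identity, disjointness, and partial overlap", {
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(dice(m, m), 1)
  expect_equal(dice(m, !m), 0)
  a <- matrix(FALSE, 4, 4); a[1, 1:4] <- TRUE
  b <- matrix(FALSE, 4, 4); b[1, 3:4] <- TRUE; b[2, 1:2] <- TRUE
  expect_equal(dice(a, b), 2 * 2 / (4 + 4))
})

# the published per-image PSNR/MAE/SSIM assessments for the five filters
# under both enhancements (five sample images)
published_grid <- local({
  filters <- c("NLMD", "MF", "GF", "MDF", "CSF")
  imgs <- c("img4", "img7", "img17", "img38", "img56")
  vals <- list(
    HE = list(
      psnr = rbind(c(39.8, 41.95, 40.3, 40.36, 40.3),
                   c(37.28, 43.13, 37.14, 38.42, 31.47),
                   c(38.55, 39.76, 38.55, 39.04, 36.33),
                   c(39.63, 42.97, 41.44, 40.79, 38.17),
                   c(38.61, 41.63, 39.89, 40.13, 39.24)),
      mae = rbind(c(4.8, 1.53, 3.31, 4.3, 3.8),
                  c(4.39, 0.66, 4.45, 3.24, 11.09),
                  c(1.71, 1.18, 1.72, 1.74, 3.93),
                  c(1.66, 0.62, 0.81, 1.11, 2.79),
                  c(4.99, 3.18, 4.31, 3.82, 3.93)),
      ssim = rbind(c(0.90, 0.95, 0.92, 0.90, 0.90),
                   c(0.91, 0.98, 0.92, 0.92, 0.89),
                   c(0.92, 0.96, 0.92, 0.93, 0.91),
                   c(0.94, 0.99, 0.98, 0.96, 0.94),
                   c(0.88, 0.94, 0.90, 0.91, 0.89))),
    PLT = list(
      psnr = rbind(c(41.65, 42.38, 40.43, 41.86, 41.65),
                   c(42.8, 44.2, 43.21, 42.90, 33.04),
                   c(40.18, 42.78, 41.51, 40.72, 39.84),
                   c(40.77, 44.58, 41.44, 42.5, 41.93),
                   c(41.62, 43.54, 41.99, 42.24, 38.14)),
      mae = rbind(c(1.6, 0.71, 1.42, 1.32, 1.59),
                  c(0.70, 0.42, 0.51, 0.61, 5.71),
                  c(1.77, 0.77, 1.15, 1.33, 1.75),
                  c(1.18, 0.43, 1.2, 1.03, 1.53),
                  c(0.96, 0.51, 0.68, 0.73, 2.73)),
      ssim = rbind(c(0.95, 0.97, 0.94, 0.96, 0.95),
                   c(0.97, 0.99, 0.98, 0.98, 0.96),
                   c(0.96, 0.99, 0.98, 0.97, 0.96),
                   c(0.95, 0.99, 0.98, 0.99, 0.96),
                   c(0.97, 0.99, 0.98, 0.98, 0.94))))
  rows <- list()
  for (enh in names(vals)) {
    for (i in seq_along(imgs)) {
      for (f in seq_along(filters)) {
        rows[[length(rows) + 1]] <- data.frame(
          image = imgs[i], filter = filters[f], enhancement = enh,
          psnr = vals[[enh]]$psnr[i, f], mae = vals[[enh]]$mae[i, f],
          ssim = vals[[enh]]$ssim[i, f])
      }
    }
  }
  do.call(rbind, rows)
})

test_that("rank-sum selection picks the mean filter with PLT on the published grid", {
  sel <- select_best(published_grid)
  expect_equal(sel$filter, "MF")
  expect_equal(sel$enhancement, "PLT")
})

test_that("selection is dominated-candidate consistent and order invariant", {
  grid <- data.frame(
    image = rep(c("a", "b"), each = 2),
    filter = rep(c("f1", "f2"), 2),
    enhancement = "e",
    psnr = c(40, 30, 41, 31), mae = c(1, 2, 1, 2), ssim = c(0.99, 0.9,
                                                            0.98, 0.91))
  expect_equal(select_best(grid)$filter, "f1")

  set.seed(44)
  shuffled <- published_grid[sample(nrow(published_grid)), ]
  sel <- select_best(shuffled)
  expect_equal(sel$filter, "MF")
  expect_equal(sel$enhancement, "PLT")

  # brute-force rank enumeration oracle on random two-candidate grids
  for (s in 1:20) {
    set.seed(s)
    g <- expand.grid(image = c("i1", "i2", "i3"), filter = c("A", "B"),
                     enhancement = c("X", "Y"),
                     stringsAsFactors = FALSE)
    g$psnr <- runif(nrow(g), 30, 50)
    g$mae <- runif(nrow(g), 0, 5)
    g$ssim <- runif(nrow(g), 0.8, 1)
    cand <- unique(g[c("filter", "enhancement")])
    sums <- apply(cand, 1, function(cr) {
      tot <- 0
      for (im in unique(g$image)) {
        sub <- g[g$image == im, ]
        key <- paste(sub$filter, sub$enhancement)
        j <- match(paste(cr[1], cr[2]), key)
        tot <- tot + rank(-sub$psnr)[j] + rank(-sub$ssim)[j] +
          rank(sub$mae)[j]
      }
      tot
    })
    best <- cand[sums == min(sums), , drop = FALSE]
    sel <- select_best(g)
    expect_true(paste(sel$filter, sel$enhancement) %in%
                  paste(best$filter, best$enhancement))
  }
})

test_that("incomplete selection grids are rejected", {
  g <- published_grid[-1, ]
  expect_error(select_best(g), "incomplete")
})
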