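raster_disk <- function(radius, pad = 4) {
  n <- 2 * (radius + pad)
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(y, x) (y - ctr)^2 + (x - ctr)^2 <= radius^2)
}

test_that("a filled square has the textbook geometric features", {
  m <- matrix(FALSE, 14, 14); m[3:12, 3:12] <- TRUE
  gf <- geometric_features(m)
  expect_equal(gf[["area"]], 100)
  expect_equal(gf[["perimeter"]], 36)  # 4 sides of length 9 through centers
  expect_equal(gf[["extent"]], 1)
  expect_equal(gf[["solidity"]], 1)
  expect_equal(gf[["filled_area"]], 100)
  expect_equal(gf[["convex_area"]], 100)
  expect_equal(gf[["equiv_diameter"]], sqrt(400 / pi))
  expect_equal(gf[["scratched_area"]], 0)
})

test_that("rasterized disks approach ideal circularity and diameter", {
  gf <- geometric_features(raster_disk(32))
  expect_lt(abs(gf[["equiv_diameter"]] - 64) / 64, 0.01)
  expect_gt(gf[["circularity"]], 0.95)
  expect_lt(gf[["circularity"]], 1.05)
  expect_lt(abs(gf[["ls_ratio"]] - 1), 0.02)

  # |circularity - 1| shrinks as the radius grows
  errs <- vapply(c(8, 16, 32, 64), function(r) {
    abs(geometric_features(raster_disk(r))[["circularity"]] - 1)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0.005))
  expect_lt(errs[4], 0.02)
})

test_that("axis ratio of a 2:1 ellipse comes out near 2", {
  m <- outer(seq_len(100), seq_len(100),
             function(y, x) ((y - 50) / 20)^2 + ((x - 50) / 40)^2 <= 1)
  gf <- geometric_features(m)
  expect_lt(abs(gf[["ls_ratio"]] - 2) / 2, 0.03)
  expect_lt(abs(gf[["major_axis_length"]] - 80) / 80, 0.03)
})

test_that("area orderings and the diameter identity hold on random lesions", {
  for (s in 1:8) {
    spec <- lesion_image_spec(width = 96, height = 96,
                              lesion_center = c(48, 48),
                              lesion_axes = c(20 + 2 * s %% 5, 14),
                              lesion_angle = 37 * s, hair_count = 3,
                              seed = s)
    g <- generate_lesion_image(spec)
    gf <- geometric_features(g$lesion_mask, g$hair_mask, pixel_size = 2)
    expect_lte(gf[["area"]], gf[["filled_area"]])
    expect_lte(gf[["filled_area"]], gf[["convex_area"]])
    expect_equal(gf[["equiv_diameter"]], sqrt(4 * gf[["area"]] / pi))
    expect_lte(gf[["solidity"]], 1)
    expect_gte(gf[["ls_ratio"]], 1)
    expect_gt(gf[["extent"]], 0)
    expect_lte(gf[["extent"]], 1)
    expect_equal(gf[["scratched_area"]], sum(g$lesion_mask & g$hair_mask))
    expect_equal(gf[["scratched_area_sq_microns"]],
                 4 * gf[["scratched_area"]])
  }
  expect_error(geometric_features(matrix(FALSE, 4, 4)), "empty")
})

test_that("hole filling counts enclosed background", {
  n <- 38; ctr <- (n + 1) / 2
  r2 <- outer(seq_len(n), seq_len(n),
              function(y, x) (y - ctr)^2 + (x - ctr)^2)
  donut <- r2 <= 15^2 & r2 > 6^2
  gf <- geometric_features(donut)
  expect_gt(gf[["filled_area"]], gf[["area"]])
  expect_equal(gf[["filled_area"]], sum(r2 <= 15^2))
})

test_that("textural features follow their zero-variance and entropy conventions", {
  m <- matrix(TRUE, 8, 8)
  tf <- textural_features(matrix(77, 8, 8), m)
  expect_equal(tf[["mean"]], 77)
  expect_equal(tf[["standard_deviation"]], 0)
  expect_equal(tf[["shannon_entropy"]], 0)
  expect_equal(tf[["glcm_entropy"]], 0)
  expect_equal(tf[["skewness"]], 0)
  expect_equal(tf[["kurtosis"]], 0)

  two <- matrix(rep(c(40, 200), 32), 8, 8)
  expect_equal(textural_features(two, m)[["shannon_entropy"]], 1)

  set.seed(5)
  for (s in 1:20) {
    g <- matrix(round(128 + 30 * rnorm(64 * 64)), 64, 64)
    g[g < 0] <- 0; g[g > 255] <- 255
    sk <- textural_features(g, matrix(TRUE, 64, 64))[["skewness"]]
    expect_lt(abs(sk), 0.2)
  }
  expect_error(textural_features(matrix(0, 3, 3), matrix(FALSE, 3, 3)),
               "empty")
})

test_that("textural features ignore pixels outside the mask", {
  set.seed(9)
  g <- rand_gray(32, 32, 9)
  m <- matrix(FALSE, 32, 32); m[8:24, 8:24] <- TRUE
  base <- textural_features(g, m)
  g2 <- g
  g2[!m] <- sample(0:255, sum(!m), replace = TRUE)
  expect_identical(textural_features(g2, m), base)
})

test_that("min-max scaling maps columns onto [0, 1] and replays its state", {
  tab <- data.frame(a = c(2, 4, 6), b = c(5, 5, 5), c = c(-1, 0, 3),
                    prediction = factor(c("x", "y", "x")))
  sc <- minmax_scale(tab)
  expect_equal(sc$table$a, c(0, 0.5, 1))
  expect_equal(sc$table$b, c(0, 0, 0))  # constant column convention
  expect_equal(min(sc$table$c), 0)
  expect_equal(max(sc$table$c), 1)
  expect_identical(sc$table$prediction, tab$prediction)
  replay <- minmax_scale(tab, sc$state)
  expect_equal(replay$table, sc$table)
  # new data scaled with the stored training extremes
  out <- minmax_scale(data.frame(a = 5, b = 7, c = 1,
                                 prediction = factor("x")), sc$state)
  expect_equal(out$table$a, 0.75)
})

test_that("build_dataset yields one labelled row per image, reproducibly", {
  mk <- function(seed, axes) {
    generate_lesion_image(lesion_image_spec(
      width = 96, height = 96, lesion_center = c(48, 48),
      lesion_axes = axes, hair_count = 2, noise_sigma = 2,
      vignette_strength = 0.1, seed = seed))
  }
  small <- lapply(1:5, function(s) mk(s, c(14, 10)))
  large <- lapply(6:10, function(s) mk(s, c(30, 22)))
  images <- c(lapply(small, `[[`, "image"), lapply(large, `[[`, "image"))
  labels <- rep(c("benign", "malignant"), each = 5)
  tab <- build_dataset(images, labels)
  expect_equal(dim(tab), c(10L, 21L))
  expect_equal(names(tab), c(lesion_feature_names(), "prediction"))

  # the area column alone separates the size-differing classes
  pos <- tab$area[tab$prediction == "malignant"]
  neg <- tab$area[tab$prediction == "benign"]
  auc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_gt(auc, 0.9)

  expect_identical(build_dataset(images, labels), tab)
})
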