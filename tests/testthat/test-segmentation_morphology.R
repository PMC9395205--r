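test_that("color coding is injective and luminance-monotone", {
  ramp <- matrix(0:255, 16, 16)
  rgb <- color_code(ramp)
  cols <- unique(cbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
                       as.vector(rgb[, , 3])))
  expect_equal(nrow(cols), 256)  # 256 distinct levels -> 256 distinct colors

  img <- matrix(c(5, 5, 9, 9), 2, 2)
  cc <- color_code(img)
  expect_equal(cc[1, 1, ], cc[2, 1, ])  # equal inputs, equal colors

  lum <- vapply(0:255, function(v) {
    px <- color_code(matrix(v, 1, 1))
    0.299 * px[1, 1, 1] + 0.587 * px[1, 1, 2] + 0.114 * px[1, 1, 3]
  }, numeric(1))
  expect_true(all(diff(lum) > 0))
})

test_that("Otsu threshold maximizes between-class variance", {
  set.seed(17)
  two <- matrix(sample(c(rep(50, 60), rep(200, 40))), 10, 10)
  t2 <- otsu_threshold(two)
  expect_gte(t2, 50)
  expect_lt(t2, 200)

  # depends only on the histogram, not on image size
  small <- matrix(c(50, 50, 50, 200), 2, 2)
  big <- matrix(rep(c(50, 50, 50, 200), 25), 10, 10)
  expect_equal(otsu_threshold(small), otsu_threshold(big))

  set.seed(18)
  mix <- matrix(round(c(rnorm(300, 60, 10), rnorm(300, 190, 10))), 20, 30)
  mix[mix < 0] <- 0; mix[mix > 255] <- 255
  tm <- otsu_threshold(mix)
  expect_gt(tm, 60)
  expect_lt(tm, 190)
  expect_equal(tm, oracle_otsu(mix))

  expect_error(otsu_threshold(matrix(5, 4, 4)), "degenerate")
})

test_that("Otsu equals the exhaustive scan on 100 random histograms", {
  for (s in 1:100) {
    set.seed(s)
    lv <- sample(0:255, sample(2:12, 1))
    v <- matrix(sample(lv, 400, replace = TRUE), 20, 20)
    if (length(unique(as.vector(v))) < 2) next
    expect_equal(otsu_threshold(v), oracle_otsu(v))
  }
})

test_that("region segmentation binarizes strictly above the threshold", {
  img <- matrix(c(1, 60, 128, 254), 2, 2)
  expect_true(all(region_based_segmentation(img, 0)))
  expect_false(any(region_based_segmentation(img, 255)))
  expect_identical(region_based_segmentation(img, 100),
                   matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
})

test_that("ROI extraction recovers the lesion on noise-free images", {
  spec <- lesion_image_spec(width = 128, height = 128,
                            lesion_center = c(64, 64),
                            lesion_axes = c(30, 20), hair_count = 0,
                            noise_sigma = 0, vignette_strength = 0.1,
                            seed = 12)
  g <- generate_lesion_image(spec)
  roi <- extract_roi(g$image)
  expect_gt(dice(roi$mask, g$lesion_mask), 0.9)
  # the mask is a single 8-connected component
  lab <- lesionpipe:::cc_label_cpp(roi$mask)
  expect_equal(max(lab), 1)
  # the ROI image is black outside the mask, untouched inside
  expect_true(all(roi$roi[, , 1][!roi$mask] == 0))
  expect_equal(roi$roi[, , 2][roi$mask], g$image[, , 2][roi$mask])

  expect_error(extract_roi(array(100, dim = c(8, 8, 3))), "degenerate")
})

test_that("binary erosion and dilation obey the set definitions", {
  ones <- matrix(TRUE, 5, 5)
  er <- erode(ones)
  expect_identical(er, {
    m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE; m
  })
  expect_true(all(er <= ones))  # anti-extensive
  expect_false(any(erode(matrix(FALSE, 4, 4))))

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  di <- dilate(single)
  expect_identical(di, { m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE; m })
  expect_true(all(single <= di))  # extensive

  # erosion/dilation duality holds away from the frame border
  for (s in 1:10) {
    set.seed(s)
    m <- matrix(FALSE, 12, 12)
    m[4:9, 4:9] <- matrix(runif(36) < 0.5, 6, 6)
    dual <- !erode(!m)
    expect_identical(dual[2:11, 2:11], dilate(m)[2:11, 2:11])
  }
})

test_that("disk structuring elements drop the square's corners", {
  se <- structuring_element("disk", 5)
  expect_lt(length(se$dy), 25)
  single <- matrix(FALSE, 7, 7); single[4, 4] <- TRUE
  di <- dilate(single, se)
  expect_false(di[2, 2])  # corner of the 5 x 5 box is outside the disk
  expect_true(di[4, 2])
})

test_that("morphological gradient marks exactly the boundary", {
  expect_true(all(morphological_gradient(matrix(100, 6, 6)) == 0))

  sq <- matrix(FALSE, 8, 8); sq[3:6, 3:6] <- TRUE
  grad <- morphological_gradient(sq)
  expect_identical(grad, oracle_dilate_binary(sq) & !oracle_erode_binary(sq))
  expect_true(all(grad[sq & !erode(sq)]))   # inner boundary ring covered
  expect_false(any(grad[4:5, 4:5] & erode(sq)[4:5, 4:5]))  # interior clear

  gg <- rand_gray(8, 8, 3)
  expect_true(all(morphological_gradient(gg) >= 0))
})

test_that("morphology matches brute force exhaustively on all 4x4 masks", {
  M <- all_masks_4x4()
  nb0 <- neighbor_cols_4x4(3, reflect = FALSE)
  nbr <- neighbor_cols_4x4(3, reflect = TRUE)
  exp_er <- oracle_erode_all(M, nb0)
  exp_di <- oracle_dilate_all(M, nb0)
  V <- M * 1
  exp_bh <- oracle_minmax_all(oracle_minmax_all(V, nbr, TRUE), nbr, FALSE) - V

  got_er <- matrix(FALSE, nrow(M), 16)
  got_di <- matrix(FALSE, nrow(M), 16)
  got_bh <- matrix(0, nrow(M), 16)
  for (i in seq_len(nrow(M))) {
    m <- matrix(M[i, ], 4, 4)
    got_er[i, ] <- erode(m)
    got_di[i, ] <- dilate(m)
    got_bh[i, ] <- blackhat(m * 1, 3)
  }
  expect_identical(got_er, exp_er)
  expect_identical(got_di, exp_di)
  expect_equal(got_bh, exp_bh)
})

test_that("illumination flattening makes vignetted skin unimodal", {
  n <- 128
  r2 <- outer(seq_len(n) - (n + 1) / 2, seq_len(n) - (n + 1) / 2,
              function(y, x) y^2 + x^2)
  skin <- 200 * (1 - 0.3 * r2 / max(r2))
  lesion <- r2 <= 18^2
  img <- round(skin); img[lesion] <- 90
  flat <- flatten_background(img, 63)
  # skin spread shrinks and the lesion separates cleanly from all skin
  expect_lt(diff(range(flat[!lesion])), diff(range(img[!lesion])))
  expect_lt(mean(flat[lesion]), min(flat[!lesion]))
})
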