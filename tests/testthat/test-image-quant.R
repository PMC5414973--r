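test_that("bin assignment splits the 4096 levels into ten equal classes", {
  expect_equal(assign_bin(0), 1L)
  expect_equal(assign_bin(409), 1L)
  expect_equal(assign_bin(410), 2L)
  expect_equal(assign_bin(4095), 10L)
  # every boundary: bin k starts at ceiling(409.6 * (k - 1))
  for (k in 1:10) {
    lo <- ceiling(409.6 * (k - 1))
    hi <- floor(409.6 * k - 1e-9)
    expect_equal(assign_bin(lo), k)
    expect_equal(assign_bin(hi), k)
  }
  expect_error(assign_bin(4096), "domain error")
  expect_error(assign_bin(-1), "domain error")
})

test_that("mean intensity matches hand sums and rejects empty masks", {
  img <- make_image(c(0, 1000, 3000, 4095), 2, 2)
  all_mask <- matrix(TRUE, 2, 2)
  expect_equal(mean_intensity(img, all_mask), 2023.75)
  expect_equal(mean_intensity(make_image(0, 3, 3), matrix(TRUE, 3, 3)), 0)
  expect_equal(mean_intensity(make_image(4095, 3, 3), matrix(TRUE, 3, 3)), 4095)
  expect_error(mean_intensity(img, matrix(FALSE, 2, 2)), "empty mask")
  expect_error(mean_intensity(img, matrix(TRUE, 3, 3)), "shape")
})

test_that("rectangle and single-pixel-triangle AOIs rasterize to known masks", {
  rect <- aoi_polygon(cbind(c(1, 1, 4, 4), c(1, 4, 4, 1)))
  mask <- rasterize_aoi(rect, c(6, 6))
  expect_equal(sum(mask), 16)
  # brute-force check over all 36 pixel centers: inside iff 1<=r<=4, 1<=c<=4
  for (r in 0:5) for (cc in 0:5) {
    expect_equal(mask[r + 1, cc + 1], r >= 1 && r <= 4 && cc >= 1 && cc <= 4)
  }
  tri <- aoi_polygon(cbind(c(1.6, 2.4, 2.4), c(2, 1.6, 2.4)))
  tm <- rasterize_aoi(tri, c(5, 5))
  expect_equal(sum(tm), 1)
  expect_true(tm[3, 3])  # pixel center (2, 2)
})

test_that("rasterization is invariant to vertex orientation", {
  v <- cbind(c(1, 1.5, 4, 3.2), c(1, 4.5, 4, 0.8))
  fwd <- rasterize_aoi(aoi_polygon(v), c(7, 7))
  rev <- rasterize_aoi(aoi_polygon(v[nrow(v):1, ]), c(7, 7))
  expect_identical(fwd, rev)
})

test_that("degenerate and out-of-image polygons are rejected", {
  expect_error(rasterize_aoi(aoi_polygon(cbind(c(1, 2, 3), c(1, 2, 3))),
                             c(6, 6)), "degenerate")
  expect_error(rasterize_aoi(aoi_polygon(cbind(c(1, 1, 9), c(1, 4, 4))),
                             c(6, 6)), "outside image bounds")
})

test_that("histogram counts come from assign_bin and conserve mask size", {
  img <- make_image(c(0, 500, 4095, 2048), 2, 2)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  h <- histogram_ten_bins(img, mask)
  expect_equal(sum(h), 3)
  expect_equal(which(h > 0), c(1, 2, 10))
  uni <- make_image(0, 10, 10)
  expect_equal(histogram_ten_bins(uni, matrix(TRUE, 10, 10)),
               c(100, rep(0, 9)))
})

test_that("percent_brightest follows the histogram and the scheme", {
  expect_equal(percent_brightest(c(100, rep(0, 9))), 0)
  expect_equal(percent_brightest(c(rep(0, 9), 100)), 100)
  expect_equal(percent_brightest(c(50, 0, 0, 0, 0, 0, 0, 10, 20, 20)), 50)
  top <- binning_scheme(brightest = "top_bin")
  expect_equal(percent_brightest(c(50, 0, 0, 0, 0, 0, 0, 10, 20, 20), top), 20)
  expect_error(percent_brightest(rep(0, 10)), "zero total")
})

test_that("quantification agrees with naive per-pixel loops on random images", {
  set.seed(42)
  rect <- aoi_polygon(cbind(c(2, 2, 12, 12), c(3, 13, 13, 3)))
  mask <- rasterize_aoi(rect, c(16, 16))
  for (trial in 1:200) {
    px <- matrix(sample(0:4095, 256, replace = TRUE), 16, 16)
    img <- gray_image(px)
    expect_equal(mean_intensity(img, mask), naive_mean(px, mask))
    h <- histogram_ten_bins(img, mask)
    expect_equal(h, naive_hist10(px, mask))
    expect_equal(sum(h), sum(mask))
    expect_equal(percent_brightest(h), naive_pct_brightest(px, mask))
  }
})

test_that("percent_brightest is monotone under pixelwise brightening and mean is permutation-invariant", {
  set.seed(7)
  mask <- matrix(TRUE, 8, 8)
  for (trial in 1:20) {
    px <- matrix(sample(0:3500, 64, replace = TRUE), 8, 8)
    up <- pmin(px + sample(0:500, 64, replace = TRUE), 4095)
    p1 <- percent_brightest(histogram_ten_bins(gray_image(px), mask))
    p2 <- percent_brightest(histogram_ten_bins(gray_image(up), mask))
    expect_gte(p2, p1)
    perm <- matrix(sample(px), 8, 8)
    expect_equal(mean_intensity(gray_image(perm), mask),
                 mean_intensity(gray_image(px), mask))
  }
})

test_that("summarize_body_part combines AOIs by either rule", {
  # three disjoint 2x2 AOIs over constant regions 0 / 2048 / 4095
  px <- matrix(0L, 8, 12)
  px[2:3, 2:3] <- 0L
  px[2:3, 6:7] <- 2048L
  px[2:3, 10:11] <- 4095L
  img <- gray_image(px)
  sq <- function(r0, c0) {
    aoi_polygon(cbind(c(r0, r0, r0 + 1, r0 + 1), c(c0, c0 + 1, c0 + 1, c0)),
                body_part = "abdomen")
  }
  aois <- list(sq(1, 1), sq(1, 5), sq(1, 9))
  s_mean <- summarize_body_part(img, aois, combine_rule = "mean_of_aois")
  expect_equal(s_mean$mean_intensity, mean(c(0, 2048, 4095)), tolerance = 1e-9)
  expect_equal(s_mean$n_pixels, 12)
  expect_equal(sum(s_mean$histogram), 12)
  s_pool <- summarize_body_part(img, aois, combine_rule = "pooled")
  pooled_mask <- matrix(FALSE, 8, 12)
  pooled_mask[2:3, c(2:3, 6:7, 10:11)] <- TRUE
  expect_equal(s_pool$mean_intensity, naive_mean(px, pooled_mask))
  expect_equal(s_pool$percent_brightest, naive_pct_brightest(px, pooled_mask))
  # single AOI: both rules collapse to that AOI's measurements
  one_m <- summarize_body_part(img, aois[1], combine_rule = "mean_of_aois")
  one_p <- summarize_body_part(img, aois[1], combine_rule = "pooled")
  expect_equal(one_m$mean_intensity, one_p$mean_intensity)
  expect_equal(one_m$percent_brightest, one_p$percent_brightest)
})

test_that("gray_image rejects out-of-depth values and TIFF round-trips", {
  expect_error(gray_image(matrix(5000, 2, 2)), "12-bit")
  expect_error(gray_image(matrix(-3, 2, 2)), "12-bit")
  tmp <- withr::local_tempfile(fileext = ".tif")
  px <- matrix(sample(0:4095, 64), 8, 8)
  write_gray_image(gray_image(px), tmp)
  back <- read_gray_image(tmp)
  expect_identical(back$pixels, matrix(as.integer(px), 8))
  # wrong-depth file: 16-bit sample above 4095 must be a hard error
  bad <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(50000 / 65535, 4, 4), bad, bits.per.sample = 16L)
  expect_error(read_gray_image(bad), "12-bit maximum")
})

test_that("AOI JSON round-trips polygons with metadata", {
  tmp <- withr::local_tempfile(fileext = ".json")
  aois <- list(aoi_polygon(cbind(c(1, 1, 4, 4), c(1, 4, 4, 1)),
                           body_part = "abdomen", aoi_index = 1L),
               aoi_polygon(cbind(c(0.5, 2.5, 4.5), c(0.5, 4.5, 0.5)),
                           body_part = "abdomen", aoi_index = 2L))
  write_aois(aois, tmp)
  back <- read_aois(tmp)
  expect_equal(length(back), 2)
  expect_equal(unname(back[[1]]$vertices), unname(aois[[1]]$vertices))
  expect_equal(back[[2]]$aoi_index, 2L)
  expect_equal(back[[2]]$body_part, "abdomen")
})
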