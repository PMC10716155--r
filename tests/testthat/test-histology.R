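test_that("local contrast enhancement honors its guards and range", {
  const <- matrix(37, 40, 60)
  expect_identical(local_contrast_enhance(const), const)
  img <- generate_onl_image(8, seed = 3)$pixels
  e <- local_contrast_enhance(img)
  expect_gte(min(e), 0); expect_lte(max(e), 255)
  expect_error(local_contrast_enhance(img, window_px = 2), "window_px")
})

test_that("enhancement removes linear shading gradients", {
  base <- generate_onl_image(10, seed = 4)
  px <- base$pixels
  contrast_of <- function(m) {
    e <- local_contrast_enhance(m)
    fg <- threshold_binary(e)
    mean(e[fg]) - mean(e[!fg])
  }
  ref <- contrast_of(px)
  for (slope in c(0.1, 0.3)) {   # additive shading, 8-bit units per column
    shade <- matrix(rep(seq_len(ncol(px)) * slope, each = nrow(px)),
                    nrow(px), ncol(px))
    shaded <- pmin(px + shade, 255)
    expect_lt(abs(contrast_of(shaded) - ref) / ref, 0.05)
  }
})

test_that("binary thresholding uses the inclusive 8-bit cutoff", {
  m <- matrix(c(103, 104, 105, 0), 2, 2)
  b <- threshold_binary(m)
  expect_identical(as.vector(b), c(FALSE, TRUE, TRUE, FALSE))
  expect_true(all(!threshold_binary(matrix(0, 4, 4))))
  # normalized [0, 1] images use 0.4
  mn <- matrix(c(0.39, 0.4, 0.41, 0), 2, 2)
  expect_identical(as.vector(threshold_binary(mn)), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("component labeling is 8-connected", {
  b <- matrix(FALSE, 6, 6)
  b[2, 2] <- b[3, 3] <- b[4, 4] <- TRUE    # diagonal chain
  lab <- rgcfidelity:::label_components_8(b)
  expect_identical(max(lab), 1L)
  b[6, 6] <- TRUE                           # clearly separate pixel
  expect_identical(max(rgcfidelity:::label_components_8(b)), 2L)
})

test_that("planted nuclei are detected with matching centroids and widths", {
  img <- generate_onl_image(12, seed = 6)
  det <- detect_nuclei(threshold_binary(img), img$scale_um_per_px)
  expect_identical(nrow(det), 12L)
  tr <- img$truth
  for (i in seq_len(nrow(tr))) {
    d <- sqrt((det$x_um - tr$x_um[i])^2 + (det$y_um - tr$y_um[i])^2)
    j <- which.min(d)
    expect_lt(d[j], img$scale_um_per_px)            # centroid within 1 px
    expect_lt(abs(det$width_um[j] - tr$width_um[i]) / tr$width_um[i], 0.25)
  }
  expect_identical(nrow(detect_nuclei(matrix(FALSE, 20, 20), 0.2)), 0L)
})

test_that("width and separation filters remove exactly the violators", {
  for (seed in 1:4) {
    img <- generate_onl_image(15, n_invalid_nuclei = 4,
                              n_separation_pairs = 2, seed = seed)
    det <- detect_nuclei(threshold_binary(img), img$scale_um_per_px)
    expect_identical(nrow(det), sum(img$truth$valid))
    expect_identical(attr(det, "n_separation_rejected"), 4L)
    # every truth-valid nucleus has a detection; no violator does
    for (i in seq_len(nrow(img$truth))) {
      d <- min(sqrt((det$x_um - img$truth$x_um[i])^2 +
                      (det$y_um - img$truth$y_um[i])^2))
      if (img$truth$valid[i]) expect_lt(d, 1) else expect_gt(d, 1)
    }
  }
})

test_that("truth labels follow the stated constraint rules", {
  img <- generate_onl_image(5, n_invalid_nuclei = 3, n_separation_pairs = 1,
                            seed = 12)
  tr <- img$truth
  expect_identical(tr$passes_width, tr$width_um >= 2.1)
  pair <- tr[tr$kind == "close_pair", ]
  expect_identical(nrow(pair), 2L)
  expect_true(all(!pair$passes_separation))   # both members fail
  gap <- sqrt(diff(pair$x_um)^2 + diff(pair$y_um)^2) -
    sum(pair$major_um) / 2
  expect_lt(gap, 1.05)
  blank <- generate_onl_image(0, seed = 1)
  expect_identical(nrow(blank$truth), 0L)
  expect_true(all(blank$pixels < 104 + 30))   # background + noise only
})

test_that("sampling regions are exactly 1000 square microns and average", {
  det <- data.frame(x_um = c(rep(20, 10), rep(51.2, 12), rep(80, 14)),
                    y_um = rep(20, 36), width_um = 3, major_um = 3,
                    n_px = 100L)
  res <- sample_regions(det, c(102.4, 40))
  expect_true(all(abs(res$regions$area_um2 - 1000) < 1e-9))
  expect_identical(res$per_region_counts, c(10L, 12L, 14L))
  expect_equal(res$mean_count, 12)
  expect_error(sample_regions(det, c(30, 40)), "overlap|narrow")
})

test_that("survival fraction is exact arithmetic with propagated error", {
  expect_equal(survival_fraction(100, 100)$fraction, 1)
  expect_equal(survival_fraction(30, 100)$fraction, 0.30)
  expect_error(survival_fraction(10, 0), "reference")
  sf <- survival_fraction(c(28, 30, 32), c(98, 100, 102))
  expect_equal(sf$fraction, 0.3, tolerance = 1e-12)
  expect_gt(sf$se, 0)
})

test_that("planted-density ratios are recovered by the survival estimator", {
  fr <- sapply(1:20, function(s) {
    a <- count_nuclei(generate_onl_image(13, seed = s), enhance = FALSE)
    b <- count_nuclei(generate_onl_image(20, seed = 100 + s),
                      enhance = FALSE)
    survival_fraction(a$per_region_counts, b$per_region_counts)$fraction
  })
  # unbiasedness: planted density ratio 13/20 = 0.65
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.65), 3 * se)
  expect_lt(abs(mean(fr) - 0.65), 0.2)
})

test_that("counts are invariant to global linear intensity rescaling", {
  img <- generate_onl_image(22, seed = 7)
  n <- sapply(c(0.4, 0.7, 1), function(g) {
    px <- matrix(as.integer(pmin(255, round(img$pixels * g))),
                 nrow(img$pixels), ncol(img$pixels))
    nrow(count_nuclei(px, img$scale_um_per_px, enhance = TRUE)$detections)
  })
  expect_identical(n[1], n[2])
  expect_identical(n[2], n[3])
})

test_that("image IO round-trips pixels and truth sidecar", {
  img <- generate_onl_image(6, seed = 9)
  for (ext in c(".tif", ".png")) {
    path <- tempfile(fileext = ext)
    write_onl_image(img, path)
    back <- read_onl_image(path, img$scale_um_per_px)
    expect_identical(back$pixels, img$pixels)
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    expect_equal(nrow(side$truth), 6)
    unlink(c(path, paste0(path, ".json")))
  }
})
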