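test_that("segmentation keeps the largest 8-connected dark object", {
  # two blobs on a light background: keep the 50-px one, not the 20-px one
  img <- matrix(0.9, 60, 60)
  img[10:14, 10:19] <- 0.2   # 50 px
  img[40:43, 40:44] <- 0.2   # 20 px
  seg <- segment_largest_object(img, min_size = 30)
  expect_equal(seg$pixel_count, 50L)
  expect_equal(unname(seg$bbox[c("row_min", "row_max")]), c(10, 14))

  # diagonally touching parts count as one component (8-connectivity)
  img2 <- matrix(0.9, 40, 40)
  img2[5:10, 5:9] <- 0.2          # 30 px
  img2[11:15, 10:14] <- 0.2       # 25 px, touches only at a corner
  expect_equal(segment_largest_object(img2, min_size = 10)$pixel_count, 55L)

  # degenerate inputs
  expect_error(segment_largest_object(matrix(0.5, 20, 20)), "no organoid")
  expect_error(segment_largest_object(img, min_size = 1000), "min_size")
})

test_that("segmented disc area matches the analytic circle area", {
  r <- 40
  img <- 0.9 - 0.6 * mk_disc_mask(r)
  seg <- segment_largest_object(img)
  expect_lt(abs(seg$pixel_count / (pi * r^2) - 1), 0.02)
})

test_that("circularity reproduces the analytic identities", {
  # ideal disc -> 1 (clamped; digitization keeps it within 2%)
  disc <- measure_features(mk_disc_mask(50), pixel_size = 1)
  expect_gt(disc$circularity, 0.97)
  expect_lte(disc$circularity, 1)

  # axis-aligned square -> pi/4
  sq <- measure_features(mk_square_mask(100), pixel_size = 1)
  expect_equal(sq$circularity, pi / 4, tolerance = 0.025)

  # 2:1 ellipse vs the Ramanujan perimeter oracle
  a <- 80; b <- 40
  p_or <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  circ_or <- 4 * pi * (pi * a * b) / p_or^2
  ell <- measure_features(mk_ellipse_mask(a, b), pixel_size = 1)
  expect_equal(ell$circularity, circ_or, tolerance = 0.02)
  expect_equal(ell$perimeter_um, p_or, tolerance = 0.02 * p_or)

  expect_error(measure_features(matrix(0, 10, 10)), "empty mask")
})

test_that("area scales with magnification squared, circularity is scale-invariant", {
  small <- measure_features(mk_disc_mask(30), pixel_size = 2)
  big <- measure_features(mk_disc_mask(60), pixel_size = 2)
  expect_equal(big$area_um2 / small$area_um2, 4, tolerance = 0.02)

  # same physical shape rendered at 2 um/px and 1 um/px
  cfg2 <- generator_config(noise_sd = 0, pixel_size = 2, seed = 5)
  cfg1 <- generator_config(noise_sd = 0, pixel_size = 1, seed = 5)
  rec <- tibble::tibble(pdo_id = "e", area_um2 = 2.5e4, circularity = 0.9)
  c2 <- measure_features(segment_largest_object(render_pdo_image(rec, cfg2)))
  c1 <- measure_features(segment_largest_object(render_pdo_image(rec, cfg1)))
  expect_lt(abs(c1$circularity / c2$circularity - 1), 0.02)
})

test_that("render -> segment -> measure round-trips within 3% on noiseless shapes", {
  cfg <- generator_config(noise_sd = 0, pixel_size = 2, seed = 6)
  shapes <- list(
    tibble::tibble(pdo_id = "disc", area_um2 = pi * 100^2, circularity = 1),
    tibble::tibble(pdo_id = "ell", area_um2 = pi * 100^2, circularity = 0.8412)
  )
  for (rec in shapes) {
    img <- render_pdo_image(rec, cfg)
    got <- measure_features(segment_largest_object(img))
    expect_lt(abs(got$area_um2 / img$ground_truth$area_um2 - 1), 0.03)
    expect_lt(abs(got$circularity - img$ground_truth$circularity), 0.03)
  }
})

test_that("feature extraction from PNG files matches in-memory measurement", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(pdos_per_patient_per_batch = 2, noise_sd = 0.02,
                          seed = 11)
  co <- generate_cohort(cfg)[1:3, ]
  gt <- write_image_set(co, cfg, dir)
  feats <- extract_features(dir, pixel_size = cfg$pixel_size)
  expect_equal(nrow(feats), 3)
  m <- merge(feats, gt, by = "pdo_id")
  expect_true(all(abs(m$area_um2 / m$true_area_um2 - 1) < 0.05))
  expect_true(all(abs(m$circularity - m$true_circularity) < 0.05))
})

test_that("coefficient of variation follows the n-1 sample convention", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  expect_error(coefficient_of_variation(3), "at least 2")
  expect_error(coefficient_of_variation(c(-2, 0)), "mean")
})

test_that("pearson_r is the product-moment correlation with guarded input", {
  x <- c(1, 2, 4, 7, 9)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  # construct y with exactly zero sample covariance with x
  y <- withr::with_seed(2, rnorm(5))
  xc <- x - mean(x)
  y <- y - mean(y)
  y <- y - xc * sum(xc * y) / sum(xc^2)
  expect_equal(pearson_r(x, y), 0, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})
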