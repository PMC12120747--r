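test_that("cohort size is patients x batches x organoids and output is reproducible", {
  cfg <- generator_config(n_high_patients = 3, n_low_patients = 2,
                          pdos_per_patient_per_batch = 49,
                          batches = "training", seed = 4)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 5 * 1 * 49)
  expect_named(co, c("patient_id", "platform", "batch", "pdo_id",
                     "area_um2", "perimeter_um", "circularity", "cea_class"))
  expect_equal(length(unique(co$patient_id)), 5)

  cfg2 <- generator_config(n_high_patients = 2, n_low_patients = 2,
                           pdos_per_patient_per_batch = 10,
                           batches = c("training", "validation"), seed = 4)
  expect_equal(nrow(generate_cohort(cfg2)), 4 * 2 * 10)

  # identical config + seed => byte-identical tables
  expect_identical(generate_cohort(cfg), co)
  # a different seed changes the draws
  cfg3 <- generator_config(seed = 5)
  expect_false(identical(generate_cohort(cfg3)$area_um2, co$area_um2))
})

test_that("generated areas reproduce the platform dispersion (CV 0.18 Eba, 0.71 Std)", {
  for (case in list(list(pf = "Eba", cv = 0.18, tol = 0.01),
                    list(pf = "Std", cv = 0.71, tol = 0.03))) {
    cfg <- generator_config(n_high_patients = 3, n_low_patients = 2,
                            pdos_per_patient_per_batch = 2000,
                            platform = case$pf, seed = 0)
    areas <- generate_cohort(cfg)$area_um2
    expect_length(areas, 10000)
    expect_lt(abs(coefficient_of_variation(areas) - case$cv), case$tol)
  }
})

test_that("patient profiles respect the 2.5 ng/mL CEA class threshold", {
  co <- generate_cohort(generator_config(seed = 9))
  pp <- patient_profiles(co)
  expect_equal(pp$cea_class, ifelse(pp$serum_cea > 2.5, "High", "Low"))
  expect_setequal(unique(co$cea_class), c("High", "Low"))
  # perimeter honours the deterministic identity P = sqrt(4*pi*A/C)
  expect_equal(co$perimeter_um, sqrt(4 * pi * co$area_um2 / co$circularity))
})

test_that("calibrate_separation matches the inverse-normal closed form", {
  expect_equal(calibrate_separation(0.5), 0)
  expect_equal(calibrate_separation(0.86), 2.161, tolerance = 1e-3)
  expect_equal(calibrate_separation(0.64), 0.717, tolerance = 1e-3)
  expect_error(calibrate_separation(1), "unattainable")
  expect_error(calibrate_separation(0.4))
})

test_that("a Bayes oracle on the discriminant feature recovers the calibrated accuracy", {
  cfg <- generator_config(n_high_patients = 100, n_low_patients = 100,
                          pdos_per_patient_per_batch = 50, platform = "Eba",
                          target_single_pdo_accuracy = 0.86, seed = 1)
  co <- generate_cohort(cfg)
  # oracle threshold: the known log-area midpoint of the two classes
  mu_mid <- log(pi * (cfg$mean_diameter / 2)^2) - log(1 + cfg$area_cv^2) / 2
  pred <- ifelse(log(co$area_um2) > mu_mid, "High", "Low")
  expect_lt(abs(mean(pred == co$cea_class) - 0.86), 0.02)
})

test_that("with zero class effect the class labels are exchangeable", {
  cfg <- generator_config(n_high_patients = 10, n_low_patients = 10,
                          pdos_per_patient_per_batch = 200,
                          class_effect = 0, seed = 3)
  co <- generate_cohort(cfg)
  hi <- co[co$cea_class == "High", ]
  lo <- co[co$cea_class == "Low", ]
  expect_gt(suppressWarnings(ks.test(hi$area_um2, lo$area_um2))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(hi$circularity, lo$circularity))$p.value, 0.01)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_high_patients = 0), "counts")
  expect_error(generator_config(area_cv = -1), "area_cv")
  expect_error(generator_config(pixel_size = 0), "pixel_size")
  expect_error(generator_config(target_single_pdo_accuracy = 0.5))
  expect_error(generator_config(target_single_pdo_accuracy = 1))
  expect_error(generator_config(batches = "test"), "batch tags")
  # the patient effect must fit inside the platform dispersion
  expect_error(generator_config(class_effect = 5), "patient_effect_frac")
})

test_that("rendered organoids have the right scale and analytic ground truth", {
  cfg <- generator_config(noise_sd = 0, seed = 2)
  rec <- tibble::tibble(pdo_id = "disc", area_um2 = pi * 100^2, circularity = 1)
  img <- render_pdo_image(rec, cfg)
  # 200 um disc at 2 um/px spans ~100 px
  mask <- img$raster < 0.5
  expect_lt(abs(diff(range(which(apply(mask, 1, any)))) + 1 - 100), 3)
  # noiseless measured area within 2% of analytic pi r^2
  expect_lt(abs(sum(mask) * cfg$pixel_size^2 / (pi * 100^2) - 1), 0.02)
  expect_equal(img$ground_truth$area_um2, pi * 100^2, tolerance = 1e-6)

  # same seed -> identical rasters; organoid must fit a requested canvas
  img2 <- render_pdo_image(rec, cfg)
  expect_identical(img$raster, img2$raster)
  expect_error(render_pdo_image(rec, cfg, canvas_px = 40), "canvas")
})

test_that("the feature library CSV round-trips with its exact header", {
  co <- generate_cohort(generator_config(pdos_per_patient_per_batch = 5, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_identical(
    readLines(path, n = 1),
    "patient_id,platform,batch,pdo_id,area_um2,perimeter_um,circularity,cea_class"
  )
  back <- read_cohort(path)
  expect_equal(back$area_um2, co$area_um2, tolerance = 1e-12)
  expect_identical(back$patient_id, co$patient_id)
})
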