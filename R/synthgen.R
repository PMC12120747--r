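#' Platform-specific defaults for the cohort generator
#'
#' Dispersion and circularity defaults for the two culture platforms. The
#' arrayed bioprinting platform ("Eba") produces uniform, near-spherical
#' organoids (day-21 area CV 0.18); the conventional dome culture ("Std")
#' produces heterogeneous ones (area CV 0.71).
#'
#' @param platform `"Eba"` or `"Std"`.
#' @return A list with `area_cv`, `circ_mean`, `circ_logit_sd`.
#' @keywords internal
platform_defaults <- function(platform) {
  switch(platform,
    Eba = list(area_cv = 0.18, circ_mean = 0.92, circ_logit_sd = 0.30),
    Std = list(area_cv = 0.71, circ_mean = 0.78, circ_logit_sd = 0.60),
    stop("unknown platform: ", platform)
  )
}

#' Configure the synthetic organoid-cohort generator
#'
#' Builds and validates the configuration object consumed by
#' [generate_cohort()] and [render_pdo_image()]. The generator draws
#' organoid cross-sectional areas from a log-normal distribution
#' parameterized by the mean equivalent diameter and the platform's
#' coefficient of variation (CV), draws circularity on the logit scale,
#' and derives perimeter from the exact identity P = sqrt(4*pi*A / C).
#'
#' Class separation between High- and Low-CEA patients is a standardized
#' shift `class_effect` of the log-area mean (the designated discriminant
#' feature). Setting `target_single_pdo_accuracy` instead calibrates
#' `class_effect` with [calibrate_separation()] so that the single-organoid
#' Bayes accuracy on the discriminant feature equals the target.
#'
#' Patient-level random effects (SD = `patient_effect_frac` times the
#' between-class shift) are carved out of the platform's total dispersion,
#' not added on top, so the pooled area CV stays at `area_cv` and the
#' marginal Bayes accuracy stays at its calibrated value.
#'
#' @param n_high_patients,n_low_patients Patients per class (>= 1).
#' @param pdos_per_patient_per_batch Organoids per patient per batch.
#' @param batches Character vector of batch tags, each one of
#'   `"training"`, `"validation"`, `"external"`.
#' @param platform `"Eba"` (uniform) or `"Std"` (heterogeneous).
#' @param mean_diameter Mean organoid equivalent diameter, micrometres.
#' @param area_cv Area coefficient of variation; `NULL` takes the platform
#'   default (Eba 0.18, Std 0.71).
#' @param class_effect Standardized log-area mean shift between classes.
#' @param target_single_pdo_accuracy Optional probability in (0.5, 1);
#'   when set, overrides `class_effect` via [calibrate_separation()].
#' @param patient_effect_frac Patient random-effect SD as a fraction of the
#'   between-class shift (default 0.25).
#' @param circ_mean,circ_logit_sd Circularity location (probability scale)
#'   and logit-scale SD; `NULL` takes platform defaults.
#' @param circ_class_effect Optional standardized class shift on logit
#'   circularity (default 0: area is the only discriminant feature).
#' @param pixel_size Image scale, micrometres per pixel (default 2).
#' @param noise_sd Additive Gaussian image noise SD, intensity units in
#'   \[0, 1\] (default 0.02).
#' @param roughness Relative amplitude of low-order boundary perturbations
#'   when rendering (default 0: exact ellipses).
#' @param patient_id_start First patient number used in generated ids.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return An object of class `organovote_config`.
#' @examples
#' cfg <- generator_config(platform = "Eba", seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
generator_config <- function(n_high_patients = 3,
                             n_low_patients = 2,
                             pdos_per_patient_per_batch = 49,
                             batches = "training",
                             platform = c("Eba", "Std"),
                             mean_diameter = 200,
                             area_cv = NULL,
                             class_effect = 0,
                             target_single_pdo_accuracy = NULL,
                             patient_effect_frac = 0.25,
                             circ_mean = NULL,
                             circ_logit_sd = NULL,
                             circ_class_effect = 0,
                             pixel_size = 2,
                             noise_sd = 0.02,
                             roughness = 0,
                             patient_id_start = 1,
                             seed = 0L) {
  platform <- match.arg(platform)
  def <- platform_defaults(platform)
  if (is.null(area_cv)) area_cv <- def$area_cv
  if (is.null(circ_mean)) circ_mean <- def$circ_mean
  if (is.null(circ_logit_sd)) circ_logit_sd <- def$circ_logit_sd

  stopifnot(
    "counts must be >= 1" = n_high_patients >= 1 && n_low_patients >= 1 &&
      pdos_per_patient_per_batch >= 1,
    "area_cv must be > 0" = area_cv > 0,
    "pixel_size must be > 0" = pixel_size > 0,
    "mean_diameter must be > 0" = mean_diameter > 0,
    "circ_mean must be in (0, 1)" = circ_mean > 0 && circ_mean < 1,
    "noise_sd must be >= 0" = noise_sd >= 0,
    "roughness must be >= 0" = roughness >= 0
  )
  if (!all(batches %in% c("training", "validation", "external"))) {
    stop("batch tags must be among training/validation/external")
  }
  if (!is.null(target_single_pdo_accuracy)) {
    if (target_single_pdo_accuracy <= 0.5 || target_single_pdo_accuracy >= 1) {
      stop("target_single_pdo_accuracy must lie in (0.5, 1)")
    }
    class_effect <- calibrate_separation(target_single_pdo_accuracy)
  }
  if (patient_effect_frac < 0 || patient_effect_frac * abs(class_effect) >= 1) {
    stop("patient_effect_frac * class_effect must lie in [0, 1) so the ",
         "patient random effect fits inside the platform dispersion")
  }

  structure(
    list(
      n_high_patients = as.integer(n_high_patients),
      n_low_patients = as.integer(n_low_patients),
      pdos_per_patient_per_batch = as.integer(pdos_per_patient_per_batch),
      batches = batches,
      platform = platform,
      mean_diameter = mean_diameter,
      area_cv = area_cv,
      class_effect = class_effect,
      target_single_pdo_accuracy = target_single_pdo_accuracy,
      patient_effect_frac = patient_effect_frac,
      circ_mean = circ_mean,
      circ_logit_sd = circ_logit_sd,
      circ_class_effect = circ_class_effect,
      pixel_size = pixel_size,
      noise_sd = noise_sd,
      roughness = roughness,
      patient_id_start = as.integer(patient_id_start),
      seed = as.integer(seed)
    ),
    class = "organovote_config"
  )
}

#' Calibrate class separation for a target single-organoid accuracy
#'
#' Returns the standardized mean shift Delta between two equal-variance
#' Gaussian classes such that the optimal (Bayes) single-observation
#' classifier on that feature has accuracy `target_accuracy`:
#' accuracy = Phi(Delta / 2), hence Delta = 2 * qnorm(target_accuracy).
#'
#' @param target_accuracy Probability in \[0.5, 1).
#' @return The standardized shift Delta (0 when `target_accuracy` is 0.5).
#' @examples
#' calibrate_separation(0.86) # ~2.161
#' @export
calibrate_separation <- function(target_accuracy) {
  if (!is.numeric(target_accuracy) || length(target_accuracy) != 1 ||
      is.na(target_accuracy)) {
    stop("target_accuracy must be a single number")
  }
  if (target_accuracy >= 1) stop("target_accuracy of 1 is unattainable")
  if (target_accuracy < 0.5) stop("target_accuracy must be >= 0.5")
  2 * qnorm(target_accuracy)
}

#' Generate a synthetic organoid cohort
#'
#' Draws one feature row per organoid for every patient x batch
#' combination declared in the configuration. High-CEA patients are
#' assigned serum CEA above the 2.5 ng/mL clinical threshold, Low-CEA
#' patients below it; the class shifts the log-area mean by
#' `class_effect` standardized units (High up, Low down). Per-patient
#' random effects induce within-patient correlation.
#'
#' @param config An [generator_config()] object.
#' @return A tibble with columns `patient_id`, `platform`, `batch`,
#'   `pdo_id`, `area_um2`, `perimeter_um`, `circularity`, `cea_class`,
#'   one row per organoid, and the patient table available through
#'   [patient_profiles()].
#' @examples
#' cohort <- generate_cohort(generator_config(seed = 7))
#' nrow(cohort) # 5 patients x 1 batch x 49 organoids
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "organovote_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n_hi <- config$n_high_patients
  n_lo <- config$n_low_patients
  start <- config$patient_id_start

  patients <- tibble(
    patient_id = c(
      sprintf("CEA_hi-%02d", seq(start, length.out = n_hi)),
      sprintf("CEA_lo-%02d", seq(start, length.out = n_lo))
    ),
    cea_class = rep(c("High", "Low"), c(n_hi, n_lo)),
    # serum CEA consistent with the 2.5 ng/mL class threshold
    serum_cea = c(
      exp(runif(n_hi, log(3), log(60))),
      runif(n_lo, 0.3, 2.4)
    ),
    effect_area = rnorm(n_hi + n_lo),
    effect_circ = rnorm(n_hi + n_lo)
  )

  # log-normal area: mean area fixed by mean diameter, spread by the CV
  mean_area <- pi * (config$mean_diameter / 2)^2
  sig_a <- sqrt(log(1 + config$area_cv^2))
  mu_a <- log(mean_area) - sig_a^2 / 2

  delta <- config$class_effect
  f <- config$patient_effect_frac
  re_sd_a <- f * abs(delta) * sig_a
  res_sd_a <- sig_a * sqrt(1 - (f * delta)^2)

  sig_c <- config$circ_logit_sd
  delta_c <- config$circ_class_effect
  mu_c <- qlogis(config$circ_mean)
  re_sd_c <- f * abs(delta_c) * sig_c
  res_sd_c <- sig_c * sqrt(max(0, 1 - (f * delta_c)^2))

  n_b <- config$pdos_per_patient_per_batch
  rows <- vector("list", nrow(patients) * length(config$batches))
  k <- 0L
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    sgn <- if (p$cea_class == "High") 1 else -1
    for (b in config$batches) {
      k <- k + 1L
      log_area <- mu_a + sgn * delta * sig_a / 2 +
        p$effect_area * re_sd_a + rnorm(n_b, 0, res_sd_a)
      logit_circ <- mu_c + sgn * delta_c * sig_c / 2 +
        p$effect_circ * re_sd_c + rnorm(n_b, 0, res_sd_c)
      area <- exp(log_area)
      circ <- plogis(logit_circ)
      rows[[k]] <- tibble(
        patient_id = p$patient_id,
        platform = config$platform,
        batch = b,
        pdo_id = sprintf("%s_%s_%03d", p$patient_id, b, seq_len(n_b)),
        area_um2 = area,
        perimeter_um = sqrt(4 * pi * area / circ),
        circularity = circ,
        cea_class = p$cea_class
      )
    }
  }
  cohort <- dplyr::bind_rows(rows)
  attr(cohort, "patients") <- patients
  attr(cohort, "config") <- config
  cohort
}

#' Patient profile table of a generated cohort
#'
#' @param cohort A cohort produced by [generate_cohort()].
#' @return Tibble with one row per patient: id, class, serum CEA (ng/mL)
#'   and standardized patient random effects.
#' @export
patient_profiles <- function(cohort) {
  p <- attr(cohort, "patients")
  if (is.null(p)) stop("cohort carries no patient profiles")
  p
}

# --- ellipse geometry helpers (shared with the renderer) ------------------

#' @keywords internal
ramanujan_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

# circularity of an ellipse with aspect ratio k = a/b >= 1
ellipse_circularity <- function(k) {
  4 * k / (3 * (k + 1) - sqrt((3 * k + 1) * (k + 3)))^2
}

# invert circularity -> aspect ratio
aspect_from_circularity <- function(circ) {
  if (circ >= 1) return(1)
  lo <- ellipse_circularity(60)
  if (circ <= lo) return(60)
  stats::uniroot(function(k) ellipse_circularity(k) - circ,
                 interval = c(1, 60), tol = 1e-10)$root
}

#' Render a synthetic bright-field organoid image
#'
#' Rasterizes one organoid as a dark elliptical object (aspect ratio chosen
#' so the noiseless shape reproduces the record's circularity) on a lighter
#' background, with optional low-order boundary roughness and additive
#' Gaussian noise. Row-major raster, origin top-left, intensities in
#' \[0, 1\]; lengths map to micrometres through `config$pixel_size`.
#'
#' @param record One row of a [generate_cohort()] table (or any list with
#'   `area_um2`, `circularity`, `pdo_id`).
#' @param config The [generator_config()] used for scale, noise, roughness.
#' @param canvas_px Optional square canvas side in pixels; default sizes
#'   the canvas to the organoid plus a margin. An organoid that does not
#'   fit in a requested canvas is an error.
#' @param seed Integer seed; defaults to a value derived from the config
#'   seed and the record's `pdo_id`, so each organoid gets a distinct but
#'   reproducible raster.
#' @return An `organovote_image`: list with `raster` (matrix), `pixel_size`
#'   and `ground_truth` (center, semi-axes in micrometres, roughness terms,
#'   analytic `area_um2` / `perimeter_um` / `circularity` of the noiseless
#'   shape).
#' @export
render_pdo_image <- function(record, config, canvas_px = NULL, seed = NULL) {
  stopifnot(inherits(config, "organovote_config"))
  area <- record$area_um2[1]
  circ <- min(record$circularity[1], 1)
  if (!is.finite(area) || area <= 0) stop("record area must be positive")
  if (is.null(seed)) {
    seed <- (config$seed + sum(utf8ToInt(as.character(record$pdo_id[1]))) *
               131L) %% .Machine$integer.max
  }
  with_seed(as.integer(seed),
            render_pdo_image_impl(area, circ, config, canvas_px))
}

render_pdo_image_impl <- function(area, circ, config, canvas_px) {
  k <- aspect_from_circularity(circ)
  b <- sqrt(area / (pi * k))   # semi-minor, um
  a <- k * b                   # semi-major, um
  px <- config$pixel_size

  # random orientation + roughness harmonics (zero-amplitude when smooth)
  theta0 <- runif(1, 0, pi)
  mharm <- 2:5
  amp <- if (config$roughness > 0) rnorm(length(mharm), 0, config$roughness / mharm) else numeric(length(mharm))
  phase <- runif(length(mharm), 0, 2 * pi)
  rmod <- function(th) 1 + colSums(amp * sin(outer(mharm, th) + phase))

  margin <- 10
  need <- 2L * ceiling(a * max(1, 1 + sum(abs(amp))) / px) + 2L * margin
  if (is.null(canvas_px)) canvas_px <- need
  if (canvas_px < need) stop("organoid larger than canvas")
  n <- as.integer(canvas_px)
  cx <- (n + 1) / 2

  # 2x2 supersampled coverage of the (possibly rough) rotated ellipse
  ss <- c(-0.25, 0.25)
  cover <- matrix(0, n, n)
  ct <- cos(theta0); st <- sin(theta0)
  for (dx in ss) for (dy in ss) {
    x <- ((seq_len(n) - cx) + dx) * px
    y <- ((seq_len(n) - cx) + dy) * px
    xr <- outer(x, y, function(u, v) u * ct + v * st)
    yr <- outer(x, y, function(u, v) -u * st + v * ct)
    u <- xr / a
    v <- yr / b
    rho <- sqrt(u^2 + v^2)
    inside <- if (any(amp != 0)) {
      th <- atan2(v, u)
      rho <= matrix(rmod(as.vector(th)), n, n)
    } else {
      rho <= 1
    }
    cover <- cover + inside / 4
  }

  bg <- 0.85; fg <- 0.30
  raster <- bg + (fg - bg) * cover
  if (config$noise_sd > 0) {
    raster <- raster + rnorm(n * n, 0, config$noise_sd)
  }
  raster <- pmin(pmax(raster, 0), 1)

  gt <- if (any(amp != 0)) {
    th <- seq(0, 2 * pi, length.out = 4096L)
    r <- rmod(th)
    xs <- a * r * cos(th); ys <- b * r * sin(th)
    list(area_um2 = abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2,
         perimeter_um = sum(sqrt(diff(xs)^2 + diff(ys)^2)))
  } else {
    list(area_um2 = pi * a * b, perimeter_um = ramanujan_perimeter(a, b))
  }
  gt$circularity <- 4 * pi * gt$area_um2 / gt$perimeter_um^2
  gt$center_px <- c(cx, cx)
  gt$semi_axes_um <- c(a = a, b = b)
  gt$orientation <- theta0
  gt$roughness_amp <- amp

  structure(list(raster = raster, pixel_size = px, ground_truth = gt),
            class = "organovote_image")
}

#' Write / read the feature-library CSV
#'
#' The on-disk interchange format is a plain CSV with the exact header
#' `patient_id,platform,batch,pdo_id,area_um2,perimeter_um,circularity,cea_class`.
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("patient_id", "platform", "batch", "pdo_id",
            "area_um2", "perimeter_um", "circularity", "cea_class")
  stopifnot(all(cols %in% names(cohort)))
  write.csv(as.data.frame(cohort)[, cols], path, row.names = FALSE,
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  cols <- c("patient_id", "platform", "batch", "pdo_id",
            "area_um2", "perimeter_um", "circularity", "cea_class")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("feature library is missing columns: ", paste(missing, collapse = ", "))
  }
  as_tibble(df[, cols])
}

#' Render and save a cohort as grayscale PNGs with a ground-truth sidecar
#'
#' @param cohort Cohort tibble.
#' @param config Generator configuration (scale, noise, roughness, seed).
#' @param dir Output directory (created if absent).
#' @return Tibble mapping `pdo_id` to `image_path`, with the analytic
#'   ground-truth area/perimeter/circularity; also written as
#'   `ground_truth.csv` in `dir`.
#' @export
write_image_set <- function(cohort, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    rec <- cohort[i, ]
    img <- render_pdo_image(rec, config)
    path <- file.path(dir, paste0(rec$pdo_id, ".png"))
    png::writePNG(img$raster, path)
    tibble(pdo_id = rec$pdo_id, image_path = path,
           true_area_um2 = img$ground_truth$area_um2,
           true_perimeter_um = img$ground_truth$perimeter_um,
           true_circularity = img$ground_truth$circularity)
  })
  out <- dplyr::bind_rows(out)
  write.csv(as.data.frame(out), file.path(dir, "ground_truth.csv"),
            row.names = FALSE, quote = FALSE)
  out
}
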