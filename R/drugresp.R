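#' Survival fraction from end-point luminescence
#'
#' Viability readout of a drug-treated well relative to its vehicle
#' (DMSO) control at the same end point:
#' 100 * lum_drug / lum_control (percent). Scale-invariant in
#' luminescence units.
#'
#' @param lum_drug Luminescence of the drug-treated well(s), >= 0.
#' @param lum_control Luminescence of the matched control(s), > 0.
#' @return Survival percentage (vectorized).
#' @examples
#' survival_fraction(250, 500) # 50
#' @export
survival_fraction <- function(lum_drug, lum_control) {
  if (any(lum_control <= 0)) stop("control luminescence must be positive")
  if (any(lum_drug < 0)) stop("drug luminescence must be non-negative")
  100 * lum_drug / lum_control
}

#' Normalized area under a dose-response curve
#'
#' Trapezoidal integral of percent survival over log10(concentration),
#' divided by the log10-concentration span. The result is a percent-scale
#' summary bounded by the minimum and maximum survival: a flat 100%
#' curve scores exactly 100, and rescaling all concentrations by a common
#' factor leaves the value unchanged.
#'
#' @param concentrations Drug concentrations (e.g. uM), strictly
#'   increasing, > 0, length >= 2.
#' @param survival Percent survival at each concentration, >= 0.
#' @return Normalized AUC in percent units.
#' @examples
#' auc_drc(c(0.1, 1, 10), c(100, 100, 100)) # 100
#' @export
auc_drc <- function(concentrations, survival) {
  if (length(concentrations) < 2) stop("AUC needs at least 2 concentrations")
  if (length(concentrations) != length(survival)) {
    stop("concentrations and survival must have equal length")
  }
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (any(diff(concentrations) <= 0)) {
    stop("concentrations must be strictly increasing")
  }
  if (any(survival < 0)) stop("survival must be non-negative")
  x <- log10(concentrations)
  sum(diff(x) * (head(survival, -1) + survival[-1]) / 2) / (max(x) - min(x))
}

#' Summarize per-sample dose-response plates into AUC values
#'
#' Expects the plate layout CSV columns
#' `sample_id,patient_id,platform,concentration_uM,lum_drug,lum_control`;
#' computes [survival_fraction()] per well and [auc_drc()] per sample.
#'
#' @param plate Data frame / tibble with the columns above.
#' @return Tibble: one row per `sample_id` with `patient_id`, `platform`,
#'   `n_doses`, `auc`.
#' @export
dose_response_auc <- function(plate) {
  need <- c("sample_id", "patient_id", "platform",
            "concentration_uM", "lum_drug", "lum_control")
  missing <- setdiff(need, names(plate))
  if (length(missing)) stop("missing plate columns: ", paste(missing, collapse = ", "))
  plate <- as_tibble(plate)
  plate$survival <- survival_fraction(plate$lum_drug, plate$lum_control)
  dplyr::bind_rows(lapply(split(plate, plate$sample_id), function(d) {
    d <- d[order(d$concentration_uM), ]
    tibble(sample_id = d$sample_id[1], patient_id = d$patient_id[1],
           platform = d$platform[1], n_doses = nrow(d),
           auc = auc_drc(d$concentration_uM, d$survival))
  }))
}

#' Compare group mean AUC between classes
#'
#' Per-group mean and standard error plus a Welch two-sample t test
#' (descriptive; no multiplicity correction), for comparing average drug
#' sensitivity between High- and Low-CEA groups.
#'
#' @param aucs_by_class Named list of two numeric vectors (one per
#'   class), each of length >= 2.
#' @return List: `groups` tibble (`class`, `n`, `mean`, `sem`),
#'   `mean_difference` (first minus second), `t`, `df`, `p_value`.
#' @export
compare_group_auc <- function(aucs_by_class) {
  if (!is.list(aucs_by_class) || length(aucs_by_class) != 2) {
    stop("aucs_by_class must be a named list of two numeric vectors")
  }
  if (any(vapply(aucs_by_class, length, 1L) < 2)) {
    stop("each group needs at least 2 values")
  }
  groups <- tibble(
    class = names(aucs_by_class),
    n = unname(vapply(aucs_by_class, length, 1L)),
    mean = unname(vapply(aucs_by_class, mean, 1)),
    sem = unname(vapply(aucs_by_class, function(v) sd(v) / sqrt(length(v)), 1))
  )
  tt <- t.test(aucs_by_class[[1]], aucs_by_class[[2]], var.equal = FALSE)
  list(groups = groups,
       mean_difference = groups$mean[1] - groups$mean[2],
       t = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value)
}
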