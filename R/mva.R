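#' Tukey-fence outlier filtering of a feature table
#'
#' For each named feature, computes Q1 and Q3 by linear interpolation
#' between order statistics (R quantile type 7 — the convention used for
#' all quantile math in this package), forms the fences
#' Q1 - 1.5*IQR and Q3 + 1.5*IQR, and drops every record with any named
#' feature outside its fences. Row order is preserved.
#'
#' @param table Feature tibble (>= 4 rows).
#' @param features Character vector of feature column names.
#' @return The filtered tibble, with attributes `n_input` and
#'   `n_removed`.
#' @examples
#' iqr_filter(tibble::tibble(area_um2 = c(1, 2, 3, 4, 100)), "area_um2")
#' @export
iqr_filter <- function(table,
                       features = c("area_um2", "perimeter_um", "circularity")) {
  if (nrow(table) < 4) stop("Tukey fences need at least 4 records")
  missing <- setdiff(features, names(table))
  if (length(missing)) stop("missing feature columns: ", paste(missing, collapse = ", "))
  keep <- rep(TRUE, nrow(table))
  for (f in features) {
    v <- table[[f]]
    q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    keep <- keep & v >= q[1] - 1.5 * iqr & v <= q[2] + 1.5 * iqr
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "n_input") <- nrow(table)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Percentile tail trimming (alternative to Tukey fences)
#'
#' Removes the lowest and highest `tail` fraction of each named feature
#' (type-7 quantiles). Provided as an explicit trimming mode for
#' protocols specified as a per-tail percentage rather than as IQR
#' fences; the two rules do not coincide on near-normal data.
#'
#' @inheritParams iqr_filter
#' @param tail Fraction trimmed at each end (default 0.125).
#' @return The filtered tibble, with `n_input` / `n_removed` attributes.
#' @export
trim_tails <- function(table,
                       features = c("area_um2", "perimeter_um", "circularity"),
                       tail = 0.125) {
  if (nrow(table) < 4) stop("trimming needs at least 4 records")
  stopifnot(tail >= 0, tail < 0.5)
  keep <- rep(TRUE, nrow(table))
  for (f in features) {
    v <- table[[f]]
    q <- quantile(v, c(tail, 1 - tail), names = FALSE, type = 7)
    keep <- keep & v >= q[1] & v <= q[2]
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "n_input") <- nrow(table)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Strict-majority vote over per-organoid calls
#'
#' @param votes Non-empty vector of `"High"` / `"Low"` calls.
#' @return `"High"` or `"Low"` for a strict majority; `"Indeterminate"`
#'   on an exact tie (scored as incorrect downstream).
#' @examples
#' majority_vote(c("High", "High", "Low")) # "High"
#' @export
majority_vote <- function(votes) {
  if (length(votes) == 0) stop("empty vote list")
  votes <- as.character(votes)
  if (!all(votes %in% c("High", "Low"))) stop("votes must be High or Low")
  nh <- sum(votes == "High")
  nl <- length(votes) - nh
  if (nh > nl) "High" else if (nl > nh) "Low" else "Indeterminate"
}

#' Patient-level prediction by filtered majority voting
#'
#' The patient-level call: Tukey-fence filter the patient's organoid panel
#' on the three morphometric features, truncate to at most `max_panel`
#' organoids (uniform seeded subsample when more are available), collect
#' per-organoid classifier predictions, and take the strict majority.
#'
#' @param model A fitted classifier (anything with a `predict` method
#'   returning `"High"` / `"Low"` per row).
#' @param panel Feature table of organoids from a single patient.
#' @param max_panel Maximum panel size used for voting (default 49, odd,
#'   so ties cannot occur at full panels).
#' @param filter Apply [iqr_filter()] before voting (default TRUE).
#' @param seed Seed for the truncation subsample.
#' @return One-row tibble: `patient_id`, `n_input`, `n_after_filter`,
#'   `n_voted`, `votes_high`, `votes_low`, `call`.
#' @export
predict_patient <- function(model, panel, max_panel = 49, filter = TRUE,
                            seed = 0L) {
  ids <- unique(panel$patient_id)
  if (length(ids) != 1) stop("panel spans multiple patients: ",
                             paste(ids, collapse = ", "))
  n_input <- nrow(panel)
  if (filter) panel <- iqr_filter(panel)
  if (nrow(panel) == 0) stop("empty panel after filtering")
  n_after <- nrow(panel)
  if (n_after > max_panel) {
    pick <- sort(with_seed(as.integer(seed),
                           sample.int(n_after, max_panel)))
    panel <- panel[pick, , drop = FALSE]
  }
  votes <- as.character(predict(model, panel))
  tibble(
    patient_id = ids,
    n_input = n_input,
    n_after_filter = n_after,
    n_voted = nrow(panel),
    votes_high = sum(votes == "High"),
    votes_low = sum(votes == "Low"),
    call = majority_vote(votes)
  )
}

#' Patient-level calls for every patient in a cohort
#'
#' Applies [predict_patient()] per patient and, when the cohort is
#' labeled, appends the true class and whether the call is correct
#' (an `Indeterminate` call counts as incorrect).
#'
#' @inheritParams predict_patient
#' @param cohort Feature table spanning one or more patients.
#' @return Tibble with one row per patient.
#' @export
predict_cohort <- function(model, cohort, max_panel = 49, filter = TRUE,
                           seed = 0L) {
  out <- dplyr::bind_rows(lapply(split(cohort, cohort$patient_id),
    function(panel) predict_patient(model, panel, max_panel = max_panel,
                                    filter = filter, seed = seed)))
  if ("cea_class" %in% names(cohort)) {
    truth <- vapply(split(cohort$cea_class, cohort$patient_id),
                    function(x) as.character(x[1]), character(1))
    out$truth <- truth[out$patient_id]
    out$correct <- out$call == out$truth
  }
  out[order(out$patient_id), ]
}
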