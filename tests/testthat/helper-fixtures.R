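# Shape fixtures built in code, and stub predictors for voting tests.

mk_disc_mask <- function(r, n = ceiling(2 * r) + 20) {
  cx <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) as.numeric((i - cx)^2 + (j - cx)^2 <= r^2))
}

mk_square_mask <- function(s, n = s + 20) {
  m <- matrix(0, n, n)
  o <- 10
  m[(o + 1):(o + s), (o + 1):(o + s)] <- 1
  m
}

mk_ellipse_mask <- function(a, b, n = ceiling(2 * a) + 20) {
  cx <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) as.numeric(((i - cx) / a)^2 + ((j - cx) / b)^2 <= 1))
}

# Feature table for a single patient: well-behaved features so the Tukey
# filter keeps (almost) everything.
mk_panel <- function(n, patient_id = "P1", cea_class = "Low", seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    patient_id = patient_id,
    platform = "Eba",
    batch = "external",
    pdo_id = sprintf("%s_%03d", patient_id, seq_len(n)),
    area_um2 = exp(rnorm(n, log(3e4), 0.05)),
    circularity = plogis(rnorm(n, qlogis(0.9), 0.1)),
    cea_class = cea_class
  )) |> dplyr::mutate(perimeter_um = sqrt(4 * pi * area_um2 / circularity))
}

# Predictor that is correct with fixed probability p regardless of features:
# the setting in which strict-majority voting is exactly iid binomial.
stub_predictor <- function(p_correct) {
  structure(list(p = p_correct), class = "stub_predictor")
}
predict.stub_predictor <- function(object, newdata, ...) {
  correct <- runif(nrow(newdata)) < object$p
  ifelse(correct, as.character(newdata$cea_class),
         ifelse(newdata$cea_class == "High", "Low", "High"))
}
registerS3method("predict", "stub_predictor", predict.stub_predictor)

# Predictor that always answers the same class.
constant_predictor <- function(call = "High") {
  structure(list(call = call), class = "constant_predictor")
}
predict.constant_predictor <- function(object, newdata, ...) {
  rep(object$call, nrow(newdata))
}
registerS3method("predict", "constant_predictor", predict.constant_predictor)

# Independent binomial oracle: strict-majority tail by explicit summation
# (kept free of the package's pbinom-based implementation).
majority_tail_oracle <- function(p, n) {
  k <- seq(floor(n / 2) + 1, n)
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}
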