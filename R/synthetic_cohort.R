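#' Default regression coefficients for cohort simulation
#'
#' Coefficients for the exponential dependence of a microvascular-injury
#' index on the seven thrombus k-fractions, chosen so that simulated values
#' span the clinically observed range: IMR roughly 35-100 U (observed median
#' ~50 U, IQR ~22-69 U) and MVO roughly 1-6% of LV mass.
#'
#' @param target `"imr"` or `"mvo"`.
#' @param k number of fractions (default 7).
#' @return numeric vector `c(c0, c1, ..., ck)`.
#' @export
default_cohort_coefficients <- function(target = c("imr", "mvo"), k = 7L) {
  target <- match.arg(target)
  base <- c(2.6, 0.6, 2.4, 0.8, 2.2, 1.0, 1.6)
  ck <- rep_len(base, k)
  c0 <- if (target == "imr") 300 else 15
  c(c0, ck)
}

#' Specify a synthetic patient cohort
#'
#' @param n_patients number of patients (>= 1; a fit needs >= k + 2).
#' @param k number of k-fractions per patient (default 7).
#' @param model generative family: `"linear"`, `"power"`, `"exp"` (default)
#'   or `"sat_exp"`; see [model_predict()] for the formulas.
#' @param coefficients numeric `c(c0, c1..ck)`.
#' @param noise_sd s.d. of additive Gaussian noise on the index (truncated
#'   at zero; indices are non-negative).
#' @param fraction_concentration symmetric Dirichlet concentration for
#'   sampling fraction vectors (1 = uniform on the simplex).
#' @param p_success probability a patient's thrombus area fraction is drawn
#'   above the 0.22 adequacy threshold (below otherwise), so downstream
#'   threshold filtering has work to do.
#' @param target which index the model generates: `"imr"` or `"mvo"`.
#' @param score_levels thrombus scores sampled uniformly per patient
#'   (default 4:5, the grades eligible for the adequacy rule).
#' @param seed integer seed.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, k = 7L,
                        model = c("exp", "linear", "power", "sat_exp"),
                        coefficients = default_cohort_coefficients("imr", k),
                        noise_sd = 6, fraction_concentration = 1,
                        p_success = 0.6,
                        target = c("imr", "mvo"),
                        score_levels = 4:5, seed = 0L) {
  model <- match.arg(model)
  target <- match.arg(target)
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(coefficients) != k + 1)
    stop("coefficients must have length k + 1 = ", k + 1, call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), k = as.integer(k),
                 model = model, coefficients = as.numeric(coefficients),
                 noise_sd = noise_sd,
                 fraction_concentration = fraction_concentration,
                 p_success = p_success, target = target,
                 score_levels = score_levels, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Symmetric Dirichlet sample via normalised gammas; rows sum to 1.
rdirichlet_sym <- function(n, k, concentration) {
  g <- matrix(stats::rgamma(n * k, shape = concentration), n, k)
  g / rowSums(g)
}

#' Generate a synthetic patient cohort
#'
#' Samples fraction vectors on the simplex, computes the target index from
#' the chosen model family plus truncated Gaussian noise, and attaches the
#' clinical plumbing: a thrombus score, an area fraction straddling the 0.22
#' adequacy threshold, and (for IMR) hyperaemic distal pressure and transit
#' time consistent with the index (so `compute_imr(pd, tmn)` reproduces it).
#' Deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `patient_id`, `f_1..f_k`, `area_fraction`,
#'   `thrombus_score`, `pd_hyperaemic`, `transit_time`, `imr`, `mvo` (the
#'   non-target index is `NA`).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients; k <- spec$k
  withr::with_seed(spec$seed, {
    f <- rdirichlet_sym(n, k, spec$fraction_concentration)
    if (spec$model == "power") f <- pmax(f, 1e-6)
    y <- as.vector(model_predict(spec$model, spec$coefficients, f))
    if (spec$noise_sd > 0)
      y <- pmax(y + stats::rnorm(n, sd = spec$noise_sd), 0)
    ok <- stats::runif(n) < spec$p_success
    area <- ifelse(ok, stats::runif(n, 0.22, 0.60), stats::runif(n, 0.01, 0.2199))
    score <- sample(spec$score_levels, n, replace = TRUE)
    df <- data.frame(patient_id = sprintf("P%03d", seq_len(n)))
    for (j in seq_len(k)) df[[paste0("f_", j)]] <- f[, j]
    df$area_fraction <- area
    df$thrombus_score <- score
    if (spec$target == "imr") {
      df$pd_hyperaemic <- stats::runif(n, 50, 90)
      df$transit_time <- y / df$pd_hyperaemic
      df$imr <- y
      df$mvo <- NA_real_
    } else {
      df$pd_hyperaemic <- NA_real_
      df$transit_time <- NA_real_
      df$imr <- NA_real_
      df$mvo <- y
    }
    df
  })
}

#' Noise level as a fraction of the noiseless index range
#'
#' Convenience for simulation studies: renders the cohort without noise and
#' returns `frac * (max(y) - min(y))`, the noise s.d. corresponding to a
#' stated fraction of the signal range under that spec.
#'
#' @param spec a `cohort_spec`.
#' @param frac fraction of the noiseless range (e.g. 0.1).
#' @return numeric noise s.d.
#' @export
noise_sd_from_range <- function(spec, frac) {
  spec$noise_sd <- 0
  y <- make_cohort(spec)[[spec$target]]
  frac * (max(y) - min(y))
}
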