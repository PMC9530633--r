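# Independent oracles used across tests. These are deliberately naive
# (enumeration / direct linear algebra) and share no code with the package
# implementation paths they check.

# Globally optimal k-means SSE by exhaustive enumeration of all K^n
# assignments (n <= 8, K <= 3 keeps this < 6561 cases).
kmeans_brute_force_sse <- function(x, K) {
  n <- nrow(x)
  stopifnot(n <= 8, K <= 3)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    sse <- 0
    for (j in seq_len(K)) {
      in_j <- assign == j
      if (any(in_j)) {
        ctr <- colMeans(x[in_j, , drop = FALSE])
        sse <- sse + sum(sweep(x[in_j, , drop = FALSE], 2, ctr)^2)
      }
    }
    if (sse < best) best <- sse
    # next assignment in base-K counting
    i <- 1L
    while (i <= n && assign[i] == K) { assign[i] <- 1L; i <- i + 1L }
    if (i > n) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# OLS through the normal equations, independent of the package's QR path.
ols_normal_equations <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))[, 1]
}

# Majority-vote mapping of cluster ids to ground-truth region kinds, and the
# resulting pixel agreement (the optimal many-to-one matching for 0/1 loss).
majority_map_agreement <- function(labels, truth_labels) {
  K <- max(labels)
  map <- character(K)
  for (j in seq_len(K)) {
    px <- truth_labels[labels == j]
    if (length(px)) map[j] <- names(which.max(table(px)))
  }
  list(map = map, agreement = mean(map[labels] == truth_labels))
}

# Small shared fixtures ---------------------------------------------------

toy_grid <- function(n = 12) default_wavelengths(n)

toy_basis <- function(n = 12, seed = 0) make_basis_spectra(toy_grid(n), seed)

# Cohort records built directly (no generator) for threshold/dichotomy tests.
manual_records <- function() {
  data.frame(
    patient_id = paste0("M", 1:6),
    area_fraction = c(0.30, 0.10, 0.50, 0.22, 0.219, 0.80),
    thrombus_score = c(5L, 5L, 3L, 4L, 4L, 0L),
    imr = c(50, 40, 10, 70, NA, 39.9),
    mvo = c(2.0, 1.55, NA, 0.4, 3.2, 1.56))
}
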