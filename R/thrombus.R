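#' Identify which clusters represent thrombus
#'
#' With an explicit `override`, returns it verbatim (mirroring assignment by
#' visual inspection, e.g. clusters 9 and 11 in a K = 11 model). Otherwise a
#' cluster is selected automatically when its centroid has cosine similarity
#' at least `sim_threshold` to its best non-negative mixture of the RBC and
#' plasma basis spectra, and is not closer (in cosine) to the filter or ice
#' spectrum than to that mixture. Note contaminating whole blood is itself
#' an RBC/plasma mixture, so automated selection cannot spectrally separate
#' blood from erythrocyte-rich thrombus; use `override` when that matters.
#'
#' @param model a `cluster_model`.
#' @param basis a `basis_spectra` set on the model grid (resampled if the
#'   model records a different grid).
#' @param sim_threshold cosine-similarity threshold (default 0.98).
#' @param override optional integer cluster ids returned verbatim.
#' @return integer vector of thrombus cluster ids; attribute `no_match` is
#'   `TRUE` (with a warning) when automated selection found none.
#' @export
identify_thrombus_clusters <- function(model, basis, sim_threshold = 0.98,
                                       override = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  if (!is.null(override)) {
    override <- as.integer(override)
    if (any(override < 1L | override > model$K))
      stop("override ids out of range 1..", model$K, call. = FALSE)
    return(override)
  }
  stopifnot(inherits(basis, "basis_spectra"))
  if (!is.null(model$wavelengths))
    basis <- resample_basis(basis, model$wavelengths)
  X <- cbind(rbc = basis$components$rbc, plasma = basis$components$plasma)
  cos_sim <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  ids <- integer(0)
  for (j in seq_len(model$K)) {
    ctr <- model$centroids[j, ]
    coef <- pracma::lsqnonneg(X, ctr)$x
    mix <- as.vector(X %*% coef)
    s_mix <- cos_sim(ctr, mix)
    s_filter <- cos_sim(ctr, basis$components$filter)
    s_ice <- cos_sim(ctr, basis$components$ice)
    if (s_mix >= sim_threshold && s_filter <= s_mix && s_ice <= s_mix)
      ids <- c(ids, j)
  }
  if (length(ids) == 0) {
    warning("no cluster matched the thrombus spectral signature", call. = FALSE)
    attr(ids, "no_match") <- TRUE
  }
  ids
}

#' Boolean thrombus mask from a label map
#'
#' @param labels a `label_map` (integer matrix of cluster ids).
#' @param thrombus_ids integer cluster ids counted as thrombus.
#' @return logical matrix, `TRUE` where the label is in `thrombus_ids`.
#' @export
mask_thrombus <- function(labels, thrombus_ids) {
  m <- matrix(as.vector(labels) %in% thrombus_ids,
              nrow = nrow(labels), ncol = ncol(labels))
  m
}

#' Thrombus area fraction of an image
#'
#' @param mask logical matrix (thrombus pixels `TRUE`).
#' @return fraction of pixels that are thrombus, in `[0, 1]`.
#' @export
thrombus_area_fraction <- function(mask) {
  if (length(mask) == 0) stop("empty mask", call. = FALSE)
  mean(mask)
}

#' k-fraction profile of a sample's thrombus pixels
#'
#' Runs (or applies) a K2-means model on the thrombus pixels only and
#' reports the fraction of thrombus pixels in each cluster — the sample's
#' compositional spectral signature. When a pooled, pre-fitted `model` is
#' supplied its centroids are applied without refitting, which keeps
#' fractions comparable across samples.
#'
#' @param cube a `spectral_cube`.
#' @param mask logical thrombus mask for the cube.
#' @param K2 number of thrombus sub-clusters (default 7).
#' @param model optional pre-fitted pooled `cluster_model` with `K2` clusters.
#' @param seed,n_restarts,max_iter,tol passed to [fit_kmeans()] when no
#'   model is supplied.
#' @return a `kfraction_profile`: list with `sample_id`, `fractions`
#'   (length `K2`, sums to 1), `n_thrombus_pixels`, `area_fraction`,
#'   `degenerate` (`TRUE`, with `NA` fractions, when fewer than `K2`
#'   thrombus pixels exist).
#' @export
kfractions <- function(cube, mask, K2 = 7L, model = NULL, seed = 0L,
                       n_restarts = 25L, max_iter = 300L, tol = 1e-6) {
  stopifnot(inherits(cube, "spectral_cube"), is.logical(mask),
            all(dim(mask) == dim(cube)[1:2]))
  n_px <- sum(mask)
  area <- thrombus_area_fraction(mask)
  if (!is.null(model)) K2 <- model$K
  if (n_px < K2) {
    return(structure(list(sample_id = cube$sample_id,
                          fractions = rep(NA_real_, K2),
                          n_thrombus_pixels = n_px,
                          area_fraction = area, degenerate = TRUE),
                     class = "kfraction_profile"))
  }
  px <- as_pixel_matrix(cube)[as.vector(t(mask)), , drop = FALSE]
  if (is.null(model))
    model <- fit_kmeans(px, K2, seed = seed, n_restarts = n_restarts,
                        max_iter = max_iter, tol = tol,
                        wavelengths = cube$wavelengths)
  lab <- nearest_center(px, model$centroids)
  f <- tabulate(lab, nbins = model$K) / n_px
  structure(list(sample_id = cube$sample_id, fractions = f,
                 n_thrombus_pixels = n_px, area_fraction = area,
                 degenerate = FALSE),
            class = "kfraction_profile")
}

#' @export
print.kfraction_profile <- function(x, ...) {
  cat(sprintf("<kfraction_profile> %s: %d thrombus pixels (area %.3f)%s\n",
              x$sample_id, x$n_thrombus_pixels, x$area_fraction,
              if (x$degenerate) " [degenerate]" else ""))
  if (!x$degenerate)
    cat("  f:", paste(sprintf("%.3f", x$fractions), collapse = " "), "\n")
  invisible(x)
}
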