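#' Fit a k-means model to pixel spectra
#'
#' Lloyd's algorithm with k-means++ seeding, run `n_restarts` times and
#' keeping the restart with the lowest within-cluster sum of squared
#' Euclidean distances (SSE). Convergence is declared when the largest
#' centroid shift falls below `tol` or after `max_iter` iterations. Empty
#' clusters are re-seeded at the point currently farthest from its centroid.
#' Deterministic given `seed`.
#'
#' @param x numeric matrix, one row per pixel spectrum (or a
#'   `spectral_cube`, flattened via [as_pixel_matrix()]).
#' @param K number of clusters.
#' @param seed integer seed.
#' @param n_restarts independent k-means++ restarts (default 25).
#' @param max_iter maximum Lloyd iterations per restart (default 300).
#' @param tol convergence tolerance on the maximum centroid shift.
#' @param wavelengths optional wavelength grid recorded in the model (taken
#'   from the cube when `x` is one); used to check grid compatibility when
#'   assigning new cubes.
#' @return a `cluster_model`: list with `K`, `centroids` (K x B),
#'   `final_sse`, `sse_trace` (SSE after each assignment step of the best
#'   restart, non-increasing), `converged`, and the fitting metadata
#'   (`seed`, `n_restarts`, `max_iter`, `tol`, `wavelengths`).
#' @export
fit_kmeans <- function(x, K, seed = 0L, n_restarts = 25L, max_iter = 300L,
                       tol = 1e-6, wavelengths = NULL) {
  if (inherits(x, "spectral_cube")) {
    wavelengths <- x$wavelengths
    x <- as_pixel_matrix(x)
  }
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("no pixels to cluster", call. = FALSE)
  n_distinct <- nrow(unique(x))
  if (K > n_distinct)
    stop("K (", K, ") exceeds number of distinct pixels (", n_distinct, ")",
         call. = FALSE)
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      run <- lloyd_once(x, K, max_iter, tol)
      if (is.null(best) || run$sse < best$sse) best <- run
    }
  })
  structure(list(K = as.integer(K), centroids = best$centers,
                 final_sse = best$sse, sse_trace = best$trace,
                 converged = best$converged, n_iter = best$n_iter,
                 seed = as.integer(seed), n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 wavelengths = wavelengths),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K = %d on %d bands; SSE = %.6g (%s after %d iter)\n",
              x$K, ncol(x$centroids), x$final_sse,
              if (x$converged) "converged" else "max_iter reached", x$n_iter))
  invisible(x)
}

# Squared Euclidean distances, n x K.
dist2_to_centers <- function(x, centers) {
  d2 <- matrix(rowSums(x^2), nrow(x), nrow(centers)) -
    2 * x %*% t(centers) +
    matrix(rowSums(centers^2), nrow(x), nrow(centers), byrow = TRUE)
  pmax(d2, 0)
}

# Nearest centroid per row; exact ties go to the lowest cluster id.
nearest_center <- function(x, centers) {
  max.col(-dist2_to_centers(x, centers), ties.method = "first")
}

kmeanspp_init <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(NA_real_, K, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (K > 1) {
    d2 <- dist2_to_centers(x, centers[1, , drop = FALSE])[, 1]
    for (j in 2:K) {
      if (all(d2 <= 0)) idx <- sample.int(n, 1)
      else idx <- sample.int(n, 1, prob = d2)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, dist2_to_centers(x, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

lloyd_once <- function(x, K, max_iter, tol) {
  centers <- kmeanspp_init(x, K)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  labels <- nearest_center(x, centers)
  repeat {
    iter <- iter + 1L
    d2 <- dist2_to_centers(x, centers)
    sse <- sum(d2[cbind(seq_len(nrow(x)), labels)])
    trace <- c(trace, sse)
    new_centers <- centers
    for (j in seq_len(K)) {
      in_j <- labels == j
      if (any(in_j)) {
        new_centers[j, ] <- colMeans(x[in_j, , drop = FALSE])
      } else {
        # re-seed an empty cluster at the worst-fit point (deterministic)
        worst <- which.max(d2[cbind(seq_len(nrow(x)), labels)])
        new_centers[j, ] <- x[worst, ]
      }
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    labels <- nearest_center(x, centers)
    if (shift < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  d2 <- dist2_to_centers(x, centers)
  sse <- sum(d2[cbind(seq_len(nrow(x)), labels)])
  trace <- c(trace, sse)
  list(centers = centers, labels = labels, sse = sse, trace = trace,
       converged = converged, n_iter = iter)
}

#' Assign cube pixels to the nearest cluster centroid
#'
#' Euclidean nearest-centroid labelling; exact distance ties break to the
#' lowest cluster id.
#'
#' @param model a `cluster_model`.
#' @param cube a `spectral_cube` on the model's wavelength grid.
#' @return a `label_map`: integer height x width matrix of cluster ids in
#'   `1..K`, with attributes `K` and `sample_id`.
#' @export
assign_pixels <- function(model, cube) {
  stopifnot(inherits(model, "cluster_model"), inherits(cube, "spectral_cube"))
  if (!is.null(model$wavelengths) &&
      !isTRUE(all.equal(model$wavelengths, cube$wavelengths)))
    stop("cube wavelength grid does not match the grid the model was fitted on",
         call. = FALSE)
  if (dim(cube)[3] != ncol(model$centroids))
    stop("cube band count does not match model centroids", call. = FALSE)
  px <- as_pixel_matrix(cube)
  lab <- nearest_center(px, model$centroids)
  out <- pixel_vector_to_map(lab, dim(cube)[1], dim(cube)[2])
  attr(out, "K") <- model$K
  attr(out, "sample_id") <- cube$sample_id
  class(out) <- c("label_map", class(out))
  out
}
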