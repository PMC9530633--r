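#' Decompose one pixel spectrum into basis-spectrum contributions
#'
#' Least-squares fit of the model
#' `S(lambda) = c0 + c_plasma S_plasma + c_rbc S_rbc + c_filter S_filter +
#' c_ice S_ice`, minimising the sum of squared residuals over bands. The
#' offset `c0` is unconstrained in both modes; `"nnls"` (default)
#' additionally constrains the four component weights to be non-negative,
#' reflecting additive reflectance contributions. `"ols"` leaves all
#' coefficients free. A rank-deficient design (e.g. proportional basis
#' spectra) yields the minimum-norm pseudo-inverse solution with a warning
#' and a flag, not an error.
#'
#' @param spectrum numeric vector on the basis grid (>= 5 bands).
#' @param basis a `basis_spectra` set on the same grid (same length).
#' @param mode `"nnls"` (default) or `"ols"`.
#' @return a `pixel_fit`: list with `coefficients` (named `c0`, `plasma`,
#'   `rbc`, `filter`, `ice`), `chi2` (residual sum of squares), `dof`
#'   (`bands - 5`), `rank_deficient`.
#' @export
fit_pixel <- function(spectrum, basis, mode = c("nnls", "ols")) {
  mode <- match.arg(mode)
  X <- unmix_design(basis)
  if (length(spectrum) != nrow(X))
    stop("spectrum length (", length(spectrum),
         ") does not match basis grid (", nrow(X), ")", call. = FALSE)
  if (nrow(X) < ncol(X))
    stop("need at least ", ncol(X), " bands for the fit", call. = FALSE)
  fit <- unmix_solve(X, matrix(spectrum, ncol = 1), mode)
  structure(list(coefficients = stats::setNames(fit$coef[, 1], colnames(X)),
                 chi2 = fit$chi2[1], dof = nrow(X) - ncol(X),
                 rank_deficient = fit$rank_deficient),
            class = "pixel_fit")
}

unmix_design <- function(basis) {
  stopifnot(inherits(basis, "basis_spectra"))
  cbind(c0 = 1,
        plasma = basis$components$plasma,
        rbc = basis$components$rbc,
        filter = basis$components$filter,
        ice = basis$components$ice)
}

# Solve min ||Y - X C|| column-wise. Returns coefficients (p x m), chi2 (m),
# rank_deficient flag. NNLS constrains all but the first (offset) column to
# be >= 0; the free offset is handled by splitting it into +/- parts.
unmix_solve <- function(X, Y, mode) {
  p <- ncol(X)
  rank_def <- FALSE
  if (mode == "ols") {
    qx <- qr(X)
    if (qx$rank < p) {
      warning("rank-deficient basis design; minimum-norm solution returned",
              call. = FALSE)
      rank_def <- TRUE
      coef <- MASS::ginv(X) %*% Y
    } else {
      coef <- qr.coef(qx, Y)
    }
  } else {
    Xn <- cbind(X[, 1], -X[, 1], X[, -1, drop = FALSE])
    if (qr(X)$rank < p) {
      warning("rank-deficient basis design; NNLS solution not unique",
              call. = FALSE)
      rank_def <- TRUE
    }
    coef <- matrix(NA_real_, p, ncol(Y))
    for (j in seq_len(ncol(Y))) {
      s <- pracma::lsqnonneg(Xn, Y[, j])$x
      coef[, j] <- c(s[1] - s[2], s[-(1:2)])
    }
  }
  resid <- Y - X %*% coef
  list(coef = coef, chi2 = colSums(resid^2), rank_deficient = rank_def)
}

#' Unmix every pixel of a cube
#'
#' Applies [fit_pixel()] to each pixel (the OLS path is solved for all
#' pixels in one factorisation) and assembles per-coefficient maps plus a
#' chi-squared map.
#'
#' @param cube a `spectral_cube`.
#' @param basis a `basis_spectra` set; resampled to the cube grid first.
#' @param mode `"nnls"` (default) or `"ols"`.
#' @return a `coefficient_maps` object: list with `maps` (named list of
#'   height x width matrices `c0`, `plasma`, `rbc`, `filter`, `ice`,
#'   `chi2`), `dof`, `mode`, `rank_deficient`.
#' @export
fit_cube <- function(cube, basis, mode = c("nnls", "ols")) {
  mode <- match.arg(mode)
  validate_cube(cube)
  basis <- resample_basis(basis, cube$wavelengths)
  X <- unmix_design(basis)
  d <- dim(cube)
  Y <- t(as_pixel_matrix(cube))          # bands x pixels
  fit <- unmix_solve(X, Y, mode)
  maps <- lapply(seq_len(ncol(X)), function(j)
    pixel_vector_to_map(fit$coef[j, ], d[1], d[2]))
  names(maps) <- colnames(X)
  maps$chi2 <- pixel_vector_to_map(fit$chi2, d[1], d[2])
  structure(list(maps = maps, dof = nrow(X) - ncol(X), mode = mode,
                 rank_deficient = fit$rank_deficient,
                 sample_id = cube$sample_id),
            class = "coefficient_maps")
}

#' @export
print.coefficient_maps <- function(x, ...) {
  cat(sprintf("<coefficient_maps> %s (%s): %d x %d, mean chi2/dof = %.4g\n",
              x$sample_id, x$mode, nrow(x$maps$chi2), ncol(x$maps$chi2),
              mean(x$maps$chi2) / max(x$dof, 1)))
  invisible(x)
}
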