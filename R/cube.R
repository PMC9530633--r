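#' Construct a hyperspectral reflectance cube
#'
#' A `spectral_cube` holds an H x W x B array of non-negative reflectance
#' intensities together with its wavelength axis (nm, strictly increasing)
#' and a sample identifier. The default acquisition grid used throughout the
#' package spans 470-900 nm at 150 bands (see [default_wavelengths()]).
#'
#' @param values numeric array of dimension height x width x bands; finite,
#'   non-negative reflectance in arbitrary units.
#' @param wavelengths numeric vector of band-centre wavelengths in nm,
#'   strictly increasing, length equal to `dim(values)[3]`.
#' @param sample_id single string naming the sample.
#' @return An object of class `spectral_cube` with fields `values`,
#'   `wavelengths`, `sample_id`.
#' @export
spectral_cube <- function(values, wavelengths, sample_id = "sample") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-d array (height x width x bands)", call. = FALSE)
  wavelengths <- as.numeric(wavelengths)
  cube <- structure(
    list(values = values, wavelengths = wavelengths,
         sample_id = as.character(sample_id)[1]),
    class = "spectral_cube")
  validate_cube(cube)
  cube
}

#' Validate a spectral cube's invariants
#'
#' Checks band/wavelength consistency, monotone wavelengths, and that all
#' reflectance values are finite and non-negative.
#'
#' @param cube a `spectral_cube`.
#' @return `cube`, invisibly; errors on violation.
#' @export
validate_cube <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$values)
  if (any(d < 1L))
    stop("cube has an empty dimension: ", paste(d, collapse = " x "), call. = FALSE)
  if (d[3] != length(cube$wavelengths))
    stop("band count (", d[3], ") does not match wavelength count (",
         length(cube$wavelengths), ")", call. = FALSE)
  if (length(cube$wavelengths) > 1 && any(diff(cube$wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (!all(is.finite(cube$values)))
    stop("cube values must be finite", call. = FALSE)
  if (any(cube$values < 0))
    stop("cube values must be non-negative", call. = FALSE)
  invisible(cube)
}

#' Default acquisition wavelength grid
#'
#' @param n number of bands (default 150).
#' @param from,to wavelength range in nm (default 470-900).
#' @return numeric vector of `n` equally spaced wavelengths.
#' @export
default_wavelengths <- function(n = 150L, from = 470, to = 900) {
  seq(from, to, length.out = n)
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_cube> %s: %d x %d pixels, %d bands (%.1f-%.1f nm)\n",
              x$sample_id, d[1], d[2], d[3],
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

#' Flatten a cube to a pixel-by-band matrix
#'
#' Pixels are ordered row-major: pixel index `(r - 1) * width + c` for
#' 1-based row `r`, column `c`. This ordering is shared by label maps and
#' masks so flat indices line up across the package.
#'
#' @param cube a `spectral_cube`.
#' @return numeric matrix with `height * width` rows and one column per band.
#' @export
as_pixel_matrix <- function(cube) {
  d <- dim(cube$values)
  m <- matrix(aperm(cube$values, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- NULL
  m
}

#' Reshape a per-pixel vector back to image layout
#'
#' Inverse of the pixel ordering used by [as_pixel_matrix()].
#'
#' @param x vector of length `height * width` in row-major pixel order.
#' @param height,width image dimensions.
#' @return `height` x `width` matrix.
#' @export
pixel_vector_to_map <- function(x, height, width) {
  matrix(x, nrow = height, ncol = width, byrow = TRUE)
}
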