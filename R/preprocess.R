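#' Optional cube preprocessing
#'
#' `mode = "none"` returns the cube unchanged. `mode = "per_pixel_norm"`
#' divides each pixel spectrum by its mean intensity, decoupling brightness
#' from spectral shape; pixels with zero mean are left unchanged and counted
#' in the `n_flagged` attribute.
#'
#' @param cube a `spectral_cube`.
#' @param mode `"none"` (default) or `"per_pixel_norm"`.
#' @return a `spectral_cube`; for `per_pixel_norm` with attribute
#'   `n_flagged` giving the number of zero-mean pixels left untouched.
#' @export
preprocess_cube <- function(cube, mode = c("none", "per_pixel_norm")) {
  validate_cube(cube)
  mode <- match.arg(mode)
  if (mode == "none") return(cube)
  d <- dim(cube$values)
  px <- as_pixel_matrix(cube)
  m <- rowMeans(px)
  zero <- m == 0
  px[!zero, ] <- px[!zero, , drop = FALSE] / m[!zero]
  vals <- array(NA_real_, d)
  for (b in seq_len(d[3]))
    vals[, , b] <- pixel_vector_to_map(px[, b], d[1], d[2])
  out <- spectral_cube(vals, cube$wavelengths, cube$sample_id)
  attr(out, "n_flagged") <- sum(zero)
  out
}
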