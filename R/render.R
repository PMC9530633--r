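#' Default qualitative palette for cluster rendering
#'
#' @param K number of colours.
#' @return character vector of `K` hex colours.
#' @export
default_cluster_palette <- function(K) {
  grDevices::hcl.colors(max(K, 2L), palette = "Dark 3")[seq_len(K)]
}

#' Render a label map as a false-colour raster
#'
#' One colour per cluster id; masked-out pixels (label 0) are black.
#'
#' @param labels integer label matrix (a `label_map`), ids in `0..K`.
#' @param palette character vector of at least `K` colours (default
#'   [default_cluster_palette()]).
#' @return height x width x 3 array of RGB values in `[0, 1]`.
#' @export
render_false_colour <- function(labels, palette = NULL) {
  K <- max(attr(labels, "K"), max(labels), 1L)
  if (is.null(palette)) palette <- default_cluster_palette(K)
  if (length(palette) < K)
    stop("palette has ", length(palette), " colours but ", K,
         " clusters are present", call. = FALSE)
  rgb <- grDevices::col2rgb(palette) / 255
  img <- array(0, c(nrow(labels), ncol(labels), 3))
  lab <- as.vector(labels)
  pos <- lab > 0
  for (ch in 1:3) {
    m <- matrix(0, nrow(labels), ncol(labels))
    m[pos] <- rgb[ch, lab[pos]]
    img[, , ch] <- m
  }
  img
}

#' Render unmixing coefficient maps as false-colour rasters
#'
#' Maps each coefficient map through a black-red-yellow-white ramp. With
#' `shared_scale = TRUE` all maps share one intensity scale (useful for
#' comparing component contributions); otherwise each map is scaled to its
#' own range. Constant maps render uniformly.
#'
#' @param maps a `coefficient_maps` object (see [fit_cube()]) or a named
#'   list of numeric matrices.
#' @param shared_scale logical; one common scale across maps.
#' @return named list of height x width x 3 RGB arrays in `[0, 1]`.
#' @export
render_coefficient_maps <- function(maps, shared_scale = FALSE) {
  mats <- if (inherits(maps, "coefficient_maps")) maps$maps else maps
  ramp <- grDevices::colorRamp(c("black", "red", "yellow", "white"))
  rng <- if (shared_scale) range(unlist(mats), finite = TRUE) else NULL
  lapply(mats, function(m) {
    r <- if (is.null(rng)) range(m, finite = TRUE) else rng
    z <- if (diff(r) == 0) matrix(0, nrow(m), ncol(m)) else (m - r[1]) / diff(r)
    cols <- ramp(pmin(pmax(as.vector(z), 0), 1)) / 255
    img <- array(0, c(nrow(m), ncol(m), 3))
    for (ch in 1:3) img[, , ch] <- matrix(cols[, ch], nrow(m), ncol(m))
    img
  })
}

#' Write an RGB raster to a PNG file
#'
#' @param img height x width x 3 array in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
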