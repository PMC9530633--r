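#' Define one scene region
#'
#' @param kind one of `"filter_background"`, `"ice"`, `"blood"`, `"thrombus"`.
#' @param mask logical height x width matrix selecting the region's pixels.
#' @param weights named non-negative composition weights over
#'   `plasma`, `rbc`, `filter`, `ice`; must sum to 1.
#' @return a `scene_region` list.
#' @export
scene_region <- function(kind, mask, weights) {
  kind <- match.arg(kind, c("filter_background", "ice", "blood", "thrombus"))
  stopifnot(is.logical(mask), is.matrix(mask))
  w <- rep(0, 4); names(w) <- c("plasma", "rbc", "filter", "ice")
  if (is.null(names(weights)) || !all(names(weights) %in% names(w)))
    stop("weights must be named over plasma, rbc, filter, ice", call. = FALSE)
  w[names(weights)] <- as.numeric(weights)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("region weights must be non-negative and sum to 1", call. = FALSE)
  structure(list(kind = kind, mask = mask, weights = w), class = "scene_region")
}

#' Define a synthetic scene
#'
#' A scene is a set of disjoint regions (each a material kind with a fixed
#' composition over the four basis components) plus an additive Gaussian
#' noise level and a seed. Pixels not covered by any region default to pure
#' filter background.
#'
#' @param height,width image dimensions in pixels.
#' @param regions list of [scene_region()] objects with pairwise-disjoint
#'   masks of matching dimension.
#' @param noise_sd additive Gaussian noise s.d. in reflectance units
#'   (truncated at zero when the cube is rendered); must be >= 0.
#' @param seed integer seed controlling the noise draw.
#' @return a `scene_spec`.
#' @export
scene_spec <- function(height, width, regions, noise_sd = 0, seed = 0L) {
  stopifnot(height >= 1, width >= 1, noise_sd >= 0)
  cover <- matrix(0L, height, width)
  for (r in regions) {
    stopifnot(inherits(r, "scene_region"))
    if (!all(dim(r$mask) == c(height, width)))
      stop("region mask dimensions do not match scene", call. = FALSE)
    cover <- cover + r$mask
  }
  if (any(cover > 1L))
    stop("region masks overlap (", sum(cover > 1L), " pixels)", call. = FALSE)
  structure(list(height = height, width = width, regions = regions,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Rectangular region mask
#'
#' @param height,width scene dimensions.
#' @param rows,cols integer ranges of rows/columns covered (1-based, inclusive).
#' @return logical matrix.
#' @export
rect_mask <- function(height, width, rows, cols) {
  m <- matrix(FALSE, height, width)
  m[rows, cols] <- TRUE
  m
}

#' Disc region mask
#'
#' @param height,width scene dimensions.
#' @param centre numeric `(row, col)` centre.
#' @param radius radius in pixels.
#' @return logical matrix.
#' @export
disc_mask <- function(height, width, centre, radius) {
  r <- matrix(seq_len(height), height, width)
  c <- matrix(seq_len(width), height, width, byrow = TRUE)
  (r - centre[1])^2 + (c - centre[2])^2 <= radius^2
}

#' Canonical demonstration scene
#'
#' Emulates a thrombus aspirate photographed on its cell-strainer filter:
#' filter background everywhere not otherwise covered, an ice strip along
#' the top, a contaminating blood patch (pure RBC), and three thrombus blobs
#' of differing RBC/plasma composition (erythrocyte-rich to platelet-rich).
#'
#' @param height,width image size (default 64 x 64).
#' @param noise_sd additive noise s.d. (reflectance units).
#' @param seed integer seed.
#' @return a `scene_spec`.
#' @export
demo_scene <- function(height = 64L, width = 64L, noise_sd = 0, seed = 0L) {
  h <- height; w <- width
  ice <- rect_mask(h, w, seq_len(max(1L, round(h * 0.12))), seq_len(w))
  blood <- disc_mask(h, w, centre = c(h * 0.28, w * 0.82), radius = min(h, w) * 0.10)
  blood <- blood & !ice
  th1 <- disc_mask(h, w, centre = c(h * 0.55, w * 0.32), radius = min(h, w) * 0.18)
  th2 <- disc_mask(h, w, centre = c(h * 0.72, w * 0.65), radius = min(h, w) * 0.14)
  th3 <- disc_mask(h, w, centre = c(h * 0.38, w * 0.55), radius = min(h, w) * 0.09)
  th1 <- th1 & !ice & !blood
  th2 <- th2 & !ice & !blood & !th1
  th3 <- th3 & !ice & !blood & !th1 & !th2
  bg <- !(ice | blood | th1 | th2 | th3)
  scene_spec(h, w, list(
    scene_region("filter_background", bg, c(filter = 1)),
    scene_region("ice", ice, c(ice = 0.9, filter = 0.1)),
    scene_region("blood", blood, c(rbc = 1)),
    scene_region("thrombus", th1, c(rbc = 0.75, plasma = 0.25)),
    scene_region("thrombus", th2, c(rbc = 0.5, plasma = 0.5)),
    scene_region("thrombus", th3, c(rbc = 0.3, plasma = 0.7))
  ), noise_sd = noise_sd, seed = seed)
}

#' Render a scene into a cube with ground truth
#'
#' Each pixel spectrum is the weighted sum of the basis spectra for its
#' region's composition, plus additive Gaussian noise truncated at zero.
#' Deterministic given the scene's seed.
#'
#' @param scene a `scene_spec`.
#' @param basis a `basis_spectra` set (any grid; used as-is).
#' @param sample_id id stored in the cube.
#' @return list with `cube` (a `spectral_cube`) and `truth`, a list holding
#'   `label_map` (character matrix of region kinds), `coefficient_maps`
#'   (height x width x 4 array of true weights, plasma/rbc/filter/ice),
#'   `thrombus_mask` (logical matrix) and `true_area_fraction`.
#' @export
make_cube <- function(scene, basis, sample_id = "synthetic") {
  stopifnot(inherits(scene, "scene_spec"), inherits(basis, "basis_spectra"))
  h <- scene$height; w <- scene$width
  B <- length(basis$wavelengths)
  comp_names <- c("plasma", "rbc", "filter", "ice")
  S <- sapply(comp_names, function(nm) basis$components[[nm]])  # B x 4
  label <- matrix("filter_background", h, w)
  wmaps <- array(0, c(h, w, 4), dimnames = list(NULL, NULL, comp_names))
  wmaps[, , "filter"] <- 1
  for (r in scene$regions) {
    label[r$mask] <- r$kind
    for (j in seq_along(comp_names)) {
      m <- wmaps[, , j]
      m[r$mask] <- r$weights[comp_names[j]]
      wmaps[, , j] <- m
    }
  }
  vals <- array(0, c(h, w, B))
  wflat <- matrix(wmaps, nrow = h * w, ncol = 4)  # column-major pixel order
  clean <- wflat %*% t(S)                         # (h*w) x B
  noisy <- withr::with_seed(scene$seed, {
    if (scene$noise_sd > 0)
      pmax(clean + stats::rnorm(length(clean), sd = scene$noise_sd), 0)
    else clean
  })
  for (b in seq_len(B)) vals[, , b] <- matrix(noisy[, b], h, w)
  thrombus_mask <- label == "thrombus"
  list(
    cube = spectral_cube(vals, basis$wavelengths, sample_id),
    truth = list(label_map = label,
                 coefficient_maps = wmaps,
                 thrombus_mask = thrombus_mask,
                 true_area_fraction = mean(thrombus_mask)))
}
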