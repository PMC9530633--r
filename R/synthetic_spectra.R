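#' Generate synthetic basis spectra for the four scene components
#'
#' Builds smooth reflectance spectra in (0, 1] emulating the materials seen
#' in thrombus aspirate images:
#' \itemize{
#'   \item `rbc`: broadband reflectance with two Gaussian absorption dips
#'     centred at 542 and 577 nm (the oxyhaemoglobin alpha/beta bands) and a
#'     steep reflectance rise above 600 nm, the shape that makes red thrombus
#'     and blood look red;
#'   \item `plasma`: high, gently sloped reflectance;
#'   \item `filter`: near-flat substrate reflectance with a slight slope;
#'   \item `ice`: flat with mild blue-end elevation.
#' }
#' The seed adds small smooth Gaussian bumps to each component so different
#' seeds give distinguishable but physically similar libraries; output is
#' deterministic given `(grid, seed)`.
#'
#' @param grid wavelength grid in nm, within 470-900.
#' @param seed integer seed for the shape perturbations.
#' @return a `basis_spectra` set on `grid`.
#' @export
make_basis_spectra <- function(grid = default_wavelengths(), seed = 0L) {
  grid <- as.numeric(grid)
  if (min(grid) < 470 || max(grid) > 900)
    stop("grid must lie within 470-900 nm", call. = FALSE)
  lam <- grid
  rbc <- 0.15 +
    0.55 / (1 + exp(-(lam - 600) / 12)) -
    0.10 * exp(-((lam - 542) / 12)^2) -
    0.12 * exp(-((lam - 577) / 10)^2)
  plasma <- 0.55 + 0.25 / (1 + exp(-(lam - 510) / 25))
  filt <- 0.62 + 5e-5 * (lam - 685) + 0.02 * ((lam - 685) / 215)^2
  ice <- 0.50 + 0.10 * exp(-(lam - 470) / 60)
  comps <- list(plasma = plasma, rbc = rbc, filter = filt, ice = ice)
  comps <- withr::with_seed(seed, {
    lapply(comps, function(s) {
      amp <- stats::runif(1, -0.01, 0.01)
      mu <- stats::runif(1, 500, 850)
      sg <- stats::runif(1, 30, 80)
      s + amp * exp(-((lam - mu) / sg)^2)
    })
  })
  comps <- lapply(comps, function(s) pmin(pmax(s, 1e-6), 1))
  basis_spectra(grid, comps)
}
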