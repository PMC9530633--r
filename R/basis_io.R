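#' Construct a basis-spectra set
#'
#' Reference reflectance spectra of the pure scene components used as
#' regressors in per-pixel unmixing: blood plasma, red blood cells (RBC,
#' haemoglobin-dominated), the empty filter substrate, and water ice.
#'
#' @param wavelengths numeric nm grid, strictly increasing.
#' @param components named list of numeric spectra, one per component; must
#'   include `plasma`, `rbc`, `filter`, `ice`; extra components are kept.
#' @return object of class `basis_spectra`.
#' @export
basis_spectra <- function(wavelengths, components) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  req <- c("plasma", "rbc", "filter", "ice")
  miss <- setdiff(req, names(components))
  if (length(miss))
    stop("missing component: ", paste(miss, collapse = ", "), call. = FALSE)
  for (nm in names(components)) {
    v <- as.numeric(components[[nm]])
    if (length(v) != length(wavelengths))
      stop("component '", nm, "' length (", length(v),
           ") does not match wavelength grid (", length(wavelengths), ")",
           call. = FALSE)
    if (!all(is.finite(v)) || any(v < 0))
      stop("component '", nm, "' must be finite and non-negative", call. = FALSE)
    components[[nm]] <- v
  }
  structure(list(wavelengths = wavelengths, components = components),
            class = "basis_spectra")
}

#' @export
print.basis_spectra <- function(x, ...) {
  cat(sprintf("<basis_spectra> %d components on %d bands (%.1f-%.1f nm): %s\n",
              length(x$components), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              paste(names(x$components), collapse = ", ")))
  invisible(x)
}

#' Read a basis-spectra library from CSV
#'
#' Expects a header row with a `wavelength` column plus one column per
#' component; `plasma`, `rbc`, `filter` and `ice` are required, extra columns
#' are carried along as additional components.
#'
#' @param path CSV file path.
#' @return a `basis_spectra` set.
#' @export
read_basis_library <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl_col <- which(tolower(names(df)) == "wavelength")
  if (length(wl_col) != 1)
    stop("basis CSV must have exactly one 'wavelength' column", call. = FALSE)
  comps <- as.list(df[-wl_col])
  basis_spectra(df[[wl_col]], comps)
}

#' Write a basis-spectra library to CSV
#'
#' @param basis a `basis_spectra` set.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_basis_library <- function(basis, path) {
  df <- data.frame(wavelength = basis$wavelengths, check.names = FALSE)
  for (nm in names(basis$components)) df[[nm]] <- basis$components[[nm]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Piecewise-linear interpolation; exact at shared grid points and on
#' spectra that are linear in wavelength. Extrapolation is refused.
#'
#' @param spectrum numeric values on `wavelengths`.
#' @param wavelengths source grid (strictly increasing).
#' @param target target grid; must lie within the source range.
#' @return numeric vector on `target`.
#' @export
resample_spectrum <- function(spectrum, wavelengths, target) {
  stopifnot(length(spectrum) == length(wavelengths))
  if (min(target) < min(wavelengths) || max(target) > max(wavelengths))
    stop("target grid [", min(target), ", ", max(target),
         "] extends outside source range [", min(wavelengths), ", ",
         max(wavelengths), "]; extrapolation not supported", call. = FALSE)
  stats::approx(wavelengths, spectrum, xout = target, method = "linear")$y
}

#' Resample every component of a basis set onto a grid
#'
#' @param basis a `basis_spectra` set.
#' @param target target wavelength grid within the basis range.
#' @return a `basis_spectra` set on `target`.
#' @export
resample_basis <- function(basis, target) {
  if (isTRUE(all.equal(basis$wavelengths, as.numeric(target)))) return(basis)
  comps <- lapply(basis$components, resample_spectrum,
                  wavelengths = basis$wavelengths, target = target)
  basis_spectra(target, comps)
}
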