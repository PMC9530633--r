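#' Write a spectral cube as an ENVI header/binary pair
#'
#' Writes the band-sequential (BSQ) dialect: an ASCII `.hdr` carrying
#' dimensions, the wavelength list and the sample id (in `description`),
#' plus a little-endian binary `.bsq`. Data type 4 (32-bit float) is the
#' hyperspectral lingua franca and the default; type 5 (64-bit float)
#' round-trips any double bit-exactly.
#'
#' @param cube a `spectral_cube`.
#' @param path base path, or a path ending in `.hdr`/`.bsq`; both files are
#'   written next to each other.
#' @param data_type ENVI data type code: 4 (float32, default) or 5 (float64).
#' @return the base path, invisibly.
#' @export
write_cube <- function(cube, path, data_type = 4L) {
  validate_cube(cube)
  if (!data_type %in% c(4L, 5L))
    stop("unsupported ENVI data type: ", data_type, " (supported: 4, 5)", call. = FALSE)
  base <- sub("\\.(hdr|bsq)$", "", path)
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    sprintf("description = {%s}", cube$sample_id),
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(sprintf("%.17g", cube$wavelengths), collapse = ", "), "}"))
  writeLines(hdr, paste0(base, ".hdr"))
  con <- file(paste0(base, ".bsq"), "wb")
  on.exit(close(con))
  # BSQ: band-major, within a band line-major with sample (column) fastest
  for (b in seq_len(d[3]))
    writeBin(as.vector(t(cube$values[, , b])), con,
             size = if (data_type == 4L) 4L else 8L, endian = "little")
  invisible(base)
}

#' Read a spectral cube from an ENVI header/binary pair
#'
#' @param path base path or path to the `.hdr`/`.bsq` file.
#' @return a `spectral_cube`.
#' @export
read_cube <- function(path) {
  base <- sub("\\.(hdr|bsq)$", "", path)
  hdr_path <- paste0(base, ".hdr")
  bin_path <- paste0(base, ".bsq")
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path, call. = FALSE)
  if (!file.exists(bin_path)) stop("missing ENVI binary: ", bin_path, call. = FALSE)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  for (k in need)
    if (is.null(h[[k]]))
      stop("ill-formed ENVI header: missing key '", k, "'", call. = FALSE)
  W <- as.integer(h[["samples"]]); H <- as.integer(h[["lines"]])
  B <- as.integer(h[["bands"]])
  dt <- as.integer(h[["data type"]])
  if (!dt %in% c(4L, 5L))
    stop("unsupported ENVI data type: ", dt, call. = FALSE)
  if (tolower(h[["interleave"]]) != "bsq")
    stop("unsupported interleave '", h[["interleave"]], "' (only bsq)", call. = FALSE)
  if (is.null(h[["wavelength"]]))
    stop("ill-formed ENVI header: missing key 'wavelength'", call. = FALSE)
  wl <- as.numeric(strsplit(h[["wavelength"]], ",")[[1]])
  if (length(wl) != B)
    stop("header declares ", B, " bands but ", length(wl), " wavelengths",
         call. = FALSE)
  sample_id <- if (is.null(h[["description"]])) basename(base) else trimws(h[["description"]])
  con <- file(bin_path, "rb")
  on.exit(close(con))
  n <- H * W * B
  raw_vals <- readBin(con, what = "double", n = n,
                      size = if (dt == 4L) 4L else 8L, endian = "little")
  if (length(raw_vals) != n)
    stop("binary file shorter than header declares", call. = FALSE)
  vals <- array(NA_real_, dim = c(H, W, B))
  per_band <- H * W
  for (b in seq_len(B))
    vals[, , b] <- matrix(raw_vals[((b - 1) * per_band + 1):(b * per_band)],
                          nrow = H, ncol = W, byrow = TRUE)
  spectral_cube(vals, wl, sample_id)
}

# Parse "key = value" ENVI header lines; brace-delimited values may span lines.
parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || toupper(trimws(lines[1])) != "ENVI")
    stop("ill-formed ENVI header: missing ENVI magic line", call. = FALSE)
  txt <- paste(lines[-1], collapse = "\n")
  out <- list()
  i <- 1L
  n <- nchar(txt)
  while (i <= n) {
    rest <- substr(txt, i, n)
    eq <- regexpr("=", rest, fixed = TRUE)
    if (eq < 0) break
    key <- tolower(trimws(substr(rest, 1, eq - 1)))
    after <- substr(rest, eq + 1, nchar(rest))
    after_trim <- sub("^[ \t\n]*", "", after)
    consumed_ws <- nchar(after) - nchar(after_trim)
    if (substr(after_trim, 1, 1) == "{") {
      close_pos <- regexpr("}", after_trim, fixed = TRUE)
      if (close_pos < 0)
        stop("ill-formed ENVI header: unterminated brace for key '", key, "'",
             call. = FALSE)
      val <- gsub("\n", " ", substr(after_trim, 2, close_pos - 1))
      advance <- eq + consumed_ws + close_pos
    } else {
      nl <- regexpr("\n", after_trim, fixed = TRUE)
      if (nl < 0) nl <- nchar(after_trim) + 1L
      val <- trimws(substr(after_trim, 1, nl - 1))
      advance <- eq + consumed_ws + nl
    }
    if (nzchar(key)) out[[key]] <- val
    i <- i + advance
  }
  out
}
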