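#' Hypercube: a spectral image with a wavelength axis
#'
#' A hypercube is a 3-D array (rows x cols x bands) together with the
#' wavelength (nm) of each band and a `kind` tag recording which physical
#' quantity the values represent: raw camera counts, reflectance (after
#' dark/white calibration), or absorbance.
#'
#' @param data numeric 3-D array, rows x cols x bands.
#' @param wavelengths numeric vector of band centre wavelengths in nm,
#'   strictly increasing, one per band.
#' @param kind one of `"raw"`, `"reflectance"`, `"absorbance"`.
#' @return An object of class `hypercube`.
#' @examples
#' cube <- hypercube(array(0.5, c(4, 5, 3)), c(450, 550, 650), "reflectance")
#' dim(cube)
#' @export
hypercube <- function(data, wavelengths,
                      kind = c("raw", "reflectance", "absorbance")) {
  kind <- match.arg(kind)
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows x cols x bands)")
  wavelengths <- as.numeric(wavelengths)
  if (dim(data)[3] != length(wavelengths))
    stop("number of bands (", dim(data)[3], ") does not match ",
         "length of `wavelengths` (", length(wavelengths), ")")
  if (length(wavelengths) && any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  if (kind != "raw" && !all(is.finite(data)))
    stop("a ", kind, " hypercube must contain only finite values")
  structure(list(data = data, wavelengths = wavelengths, kind = kind),
            class = "hypercube")
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube [%s]> %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              x$kind, d[1], d[2], d[3],
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Index of the band nearest to a wavelength
#'
#' Named wavelengths (695 nm for segmentation, 600/550/450 nm for RGB
#' reconstruction) are looked up as the nearest band centre; the requested
#' wavelength must lie inside the axis range.
#'
#' @param cube a [hypercube].
#' @param nm requested wavelength in nm.
#' @return Integer band index.
#' @export
nearest_band <- function(cube, nm) {
  wl <- cube$wavelengths
  if (nm < min(wl) || nm > max(wl))
    stop("wavelength ", nm, " nm is outside the axis range [",
         min(wl), ", ", max(wl), "] nm")
  which.min(abs(wl - nm))
}

# ---- ENVI I/O --------------------------------------------------------------
# Minimal ENVI support: band-sequential (BSQ) binary with a plain-text .hdr.
# Data type 4 (float32) or 5 (float64), little endian.

#' Write a hypercube as an ENVI file pair
#'
#' Writes `<path>.hdr` (plain-text header including the wavelength list)
#' and `<path>.dat` (band-sequential float32, little endian).
#'
#' @param cube a [hypercube].
#' @param path file path without extension.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = { hsiATP hypercube }",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    paste0("data kind = ", cube$kind),
    paste0("wavelength units = nm"),
    paste0("wavelength = { ",
           paste(format(cube$wavelengths, trim = TRUE), collapse = ", "),
           " }")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  # BSQ: for each band, lines in order, samples across a line
  for (b in seq_len(d[3]))
    writeBin(as.numeric(t(cube$data[, , b])), con,
             size = 4L, endian = "little")
  invisible(path)
}

#' Read an ENVI file pair into a hypercube
#'
#' Supports BSQ interleave, data types 4 (float32) and 5 (float64),
#' little-endian byte order, as written by [write_envi()] or compatible
#' exporters.
#'
#' @param path file path without extension (expects `<path>.hdr` and
#'   `<path>.dat`).
#' @return A [hypercube].
#' @export
read_envi <- function(path) {
  hdr_lines <- readLines(paste0(path, ".hdr"), warn = FALSE)
  hdr <- paste(hdr_lines, collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "\\s*=\\s*[0-9]+"), hdr))
    if (!length(m)) stop("ENVI header missing field: ", key)
    as.integer(sub(".*=\\s*", "", m))
  }
  samples <- get_num("samples"); lines <- get_num("lines")
  bands <- get_num("bands"); dtype <- get_num("data type")
  interleave <- regmatches(hdr, regexpr("interleave\\s*=\\s*\\w+", hdr))
  interleave <- tolower(sub(".*=\\s*", "", interleave))
  if (!identical(interleave, "bsq"))
    stop("only BSQ interleave is supported, got: ", interleave)
  if (!dtype %in% c(4L, 5L))
    stop("only ENVI data types 4 (float32) and 5 (float64) are supported")
  kind_m <- regmatches(hdr, regexpr("data kind\\s*=\\s*\\w+", hdr))
  kind <- if (length(kind_m)) sub(".*=\\s*", "", kind_m) else "raw"
  wl_m <- regmatches(hdr, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", hdr))
  if (!length(wl_m)) stop("ENVI header missing wavelength list")
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}", "", wl_m), ",")[[1]])
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  n <- samples * lines * bands
  vals <- readBin(con, "numeric", n = n, size = if (dtype == 4L) 4L else 8L,
                  endian = "little")
  if (length(vals) != n) stop("ENVI binary shorter than header promises")
  data <- array(NA_real_, c(lines, samples, bands))
  for (b in seq_len(bands)) {
    block <- vals[((b - 1) * samples * lines + 1):(b * samples * lines)]
    data[, , b] <- matrix(block, nrow = lines, ncol = samples, byrow = TRUE)
  }
  hypercube(data, wl, kind)
}
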