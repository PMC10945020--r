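#' Reflectance calibration against dark and white references
#'
#' Converts raw camera counts to relative reflectance band by band:
#' `R = (raw - dark) / (white - dark)`, where `dark` is the closed-lens
#' dark-current image and `white` a 100% white reference. Values are not
#' clipped to \[0, 1\]: specular pixels can legitimately exceed 1, and
#' clipping would bias downstream scatter corrections.
#'
#' @param raw a raw [hypercube].
#' @param dark,white reference frames: either a numeric vector with one
#'   value per band (broadcast over pixels), a rows x cols x bands array,
#'   or a [hypercube] of the same dimensions.
#' @return A [hypercube] of kind `"reflectance"`.
#' @export
calibrate <- function(raw, dark, white) {
  stopifnot(inherits(raw, "hypercube"))
  d <- dim(raw$data)
  expand <- function(ref, name) {
    if (inherits(ref, "hypercube")) ref <- ref$data
    if (is.null(dim(ref))) {
      if (length(ref) != d[3])
        stop("`", name, "` vector must have one value per band")
      aperm(array(rep(ref, each = d[1] * d[2]), d), c(1, 2, 3))
    } else {
      if (!identical(dim(ref), d))
        stop("`", name, "` dimensions do not match the raw cube")
      ref
    }
  }
  dk <- expand(dark, "dark"); wt <- expand(white, "white")
  denom <- wt - dk
  bad <- which(vapply(seq_len(d[3]), function(b) any(denom[, , b] == 0),
                      logical(1)))
  if (length(bad))
    stop("white == dark at band(s) ",
         paste(round(raw$wavelengths[bad]), collapse = ", "),
         " nm; cannot calibrate")
  hypercube((raw$data - dk) / denom, raw$wavelengths, "reflectance")
}

#' Threshold segmentation of the sausage foreground
#'
#' A pixel belongs to the foreground when its reflectance at the band
#' nearest to `wavelength_nm` is strictly greater than `threshold`. On a
#' black background the sausages are well separated at 695 nm with a 0.075
#' cut-off.
#'
#' @param cube a reflectance [hypercube].
#' @param wavelength_nm segmentation wavelength in nm (default 695).
#' @param threshold reflectance cut-off (default 0.075); strictly greater
#'   selects foreground.
#' @return A logical matrix (rows x cols), `TRUE` on foreground.
#' @export
segment_foreground <- function(cube, wavelength_nm = 695, threshold = 0.075) {
  stopifnot(inherits(cube, "hypercube"))
  b <- nearest_band(cube, wavelength_nm)
  cube$data[, , b] > threshold
}

#' Partition each sausage into equal-area cross-sections
#'
#' Each connected foreground component is sliced perpendicular to its major
#' axis (the first principal component of its pixel coordinates) into
#' `n_segments` contiguous segments whose pixel counts are equal within one
#' pixel. Slicing by equal count rather than equal length implements
#' "cross-sections of the same area" for non-rectangular outlines.
#'
#' @param mask logical foreground matrix, as from [segment_foreground()].
#' @param n_segments number of cross-sections per sausage (default 15).
#' @return An object of class `segment_labels`: list with `segment` (integer
#'   matrix, 0 = background, 1..n_segments within each sausage), `sausage`
#'   (integer matrix of connected-component ids) and `n_segments`.
#' @export
partition_segments <- function(mask, n_segments = 15) {
  stopifnot(is.matrix(mask), is.logical(mask))
  comp <- EBImage::bwlabel(mask * 1L)
  comp <- matrix(as.integer(comp), nrow = nrow(mask))
  # relabel components in reading order (centroid row, then column) so ids
  # are spatially meaningful and reproducible across labelling backends
  if (max(comp) > 1) {
    cent <- t(vapply(seq_len(max(comp)), function(id) {
      idx <- which(comp == id)
      c(mean((idx - 1L) %% nrow(mask)), mean((idx - 1L) %/% nrow(mask)))
    }, numeric(2)))
    remap <- integer(max(comp))
    remap[order(cent[, 1], cent[, 2])] <- seq_len(max(comp))
    comp[comp > 0] <- remap[comp[comp > 0]]
  }
  seg <- matrix(0L, nrow(mask), ncol(mask))
  for (id in seq_len(max(comp))) {
    idx <- which(comp == id)
    n <- length(idx)
    if (n < n_segments)
      stop("connected component ", id, " has ", n,
           " pixels; cannot partition into ", n_segments, " segments")
    coords <- cbind(row = (idx - 1L) %% nrow(mask) + 1L,
                    col = (idx - 1L) %/% nrow(mask) + 1L)
    cc <- scale(coords, center = TRUE, scale = FALSE)
    ev <- eigen(crossprod(cc) / n, symmetric = TRUE)$vectors[, 1]
    # pin the sign so the labelling direction is deterministic
    pivot <- which.max(abs(ev))
    if (ev[pivot] < 0) ev <- -ev
    proj <- drop(cc %*% ev)
    ord <- order(proj, seq_along(proj))    # stable ties
    base <- n %/% n_segments; extra <- n %% n_segments
    sizes <- rep(base, n_segments) + c(rep(1L, extra),
                                       rep(0L, n_segments - extra))
    seg[idx[ord]] <- rep(seq_len(n_segments), times = sizes)
  }
  structure(list(segment = seg, sausage = comp, n_segments = n_segments),
            class = "segment_labels")
}

#' @export
print.segment_labels <- function(x, ...) {
  cat(sprintf("<segment_labels> %d sausage(s), %d segments each, %d fg px\n",
              max(x$sausage), x$n_segments, sum(x$segment > 0)))
  invisible(x)
}

#' Per-segment mean spectra with reference ATP
#'
#' Extracts the mean spectrum of every cross-section segment and attaches
#' the sausage-level reference ATP value to each of its segments — every
#' section of a sausage shares that sausage's measured reference, which
#' multiplies the effective sample count for model building.
#'
#' @param cube a [hypercube] aligned with `labels`.
#' @param labels a `segment_labels` object from [partition_segments()].
#' @param reference data.frame with columns `sausage_id` and
#'   `atp_log10_molL` (optionally `treatment_id`), one row per sausage.
#' @return A `spectra_table`: list with `spectra` (segments x bands matrix),
#'   `wavelengths`, and `meta` (data.frame with sausage_id, segment_id,
#'   atp_log10_molL and any extra reference columns).
#' @export
extract_mean_spectra <- function(cube, labels, reference) {
  stopifnot(inherits(cube, "hypercube"), inherits(labels, "segment_labels"))
  d <- dim(cube$data)
  if (!identical(dim(labels$segment), d[1:2]))
    stop("labels do not align with the cube's spatial dimensions")
  if (!all(c("sausage_id", "atp_log10_molL") %in% names(reference)))
    stop("`reference` needs columns sausage_id and atp_log10_molL")
  ids <- sort(unique(labels$sausage[labels$sausage > 0]))
  missing_ids <- setdiff(ids, reference$sausage_id)
  if (length(missing_ids))
    stop("sausage id(s) missing from reference table: ",
         paste(missing_ids, collapse = ", "))
  # row i of X is pixel i in column-major image order
  X <- unfold_cube(cube)
  rows <- list(); meta <- list(); k <- 0L
  for (id in ids) {
    ref_row <- reference[match(id, reference$sausage_id), , drop = FALSE]
    for (s in seq_len(labels$n_segments)) {
      pix <- which(labels$sausage == id & labels$segment == s)
      k <- k + 1L
      rows[[k]] <- colMeans(X[pix, , drop = FALSE])
      meta[[k]] <- data.frame(sausage_id = id, segment_id = s,
                              atp_log10_molL = ref_row$atp_log10_molL)
      extra <- setdiff(names(ref_row), c("sausage_id", "atp_log10_molL"))
      if (length(extra)) meta[[k]] <- cbind(meta[[k]], ref_row[extra])
    }
  }
  spectra_table(do.call(rbind, rows), cube$wavelengths,
                do.call(rbind, meta))
}

#' Unfold a hypercube to a pixels x bands matrix
#'
#' Rows follow column-major image order, so `which(mask)` indexes the same
#' pixels in the matrix as in the image — the contract the distribution-map
#' refolding relies on.
#'
#' @param cube a [hypercube].
#' @return Numeric matrix with `prod(dim(cube)[1:2])` rows.
#' @export
unfold_cube <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  matrix(aperm(cube$data, c(3, 1, 2)), ncol = d[3], byrow = TRUE)
}

#' Construct a spectra table
#'
#' @param spectra numeric matrix, one row per observation, one column per
#'   band.
#' @param wavelengths numeric band axis (nm).
#' @param meta data.frame of per-row metadata.
#' @return An object of class `spectra_table`.
#' @export
spectra_table <- function(spectra, wavelengths, meta) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavelengths))
    stop("spectra columns must match wavelength axis length")
  if (nrow(spectra) != nrow(meta))
    stop("metadata rows must match spectra rows")
  colnames(spectra) <- format(wavelengths, trim = TRUE)
  structure(list(spectra = spectra, wavelengths = as.numeric(wavelengths),
                 meta = meta),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> %d spectra x %d bands (%.0f-%.0f nm)\n",
              nrow(x$spectra), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Write / read a spectra table as CSV
#'
#' The CSV layout is metadata columns first (sausage_id, segment_id,
#' atp_log10_molL, ...) followed by one column per wavelength named
#' `wl_<nm>`.
#'
#' @param x a `spectra_table`.
#' @param path CSV file path.
#' @return `write_spectra_csv`: `path` invisibly; `read_spectra_csv`: a
#'   `spectra_table`.
#' @export
write_spectra_csv <- function(x, path) {
  stopifnot(inherits(x, "spectra_table"))
  spec <- as.data.frame(x$spectra)
  names(spec) <- paste0("wl_", format(x$wavelengths, trim = TRUE))
  utils::write.csv(cbind(x$meta, spec), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl_cols <- grep("^wl_", names(df))
  if (!length(wl_cols)) stop("no wl_<nm> columns found in ", path)
  wl <- as.numeric(sub("^wl_", "", names(df)[wl_cols]))
  spectra_table(as.matrix(df[wl_cols]), wl, df[-wl_cols])
}

#' RGB reconstruction from the 600/550/450 nm bands
#'
#' Builds a colour preview of the scene from the bands nearest to 600 nm
#' (red), 550 nm (green) and 450 nm (blue). Each channel is min-max scaled
#' to \[0, 1\] over the foreground and clamped elsewhere; a channel that is
#' constant over the foreground renders mid-grey.
#'
#' @param cube a reflectance [hypercube] whose axis covers 450-600 nm.
#' @param mask optional logical foreground matrix; defaults to
#'   [segment_foreground()] on `cube`.
#' @return A rows x cols x 3 array with values in \[0, 1\].
#' @export
reconstruct_rgb <- function(cube, mask = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  if (is.null(mask)) mask <- segment_foreground(cube)
  bands <- vapply(c(600, 550, 450), function(nm) nearest_band(cube, nm), 1L)
  d <- dim(cube$data)
  out <- array(0, c(d[1], d[2], 3))
  for (ch in 1:3) {
    plane <- cube$data[, , bands[ch]]
    lo <- min(plane[mask]); hi <- max(plane[mask])
    out[, , ch] <- if (hi > lo)
      pmin(pmax((plane - lo) / (hi - lo), 0), 1)
    else matrix(0.5, d[1], d[2])
  }
  out
}
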