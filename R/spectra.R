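#' Construct a UV-Vis spectrum
#'
#' A spectrum is a strictly increasing wavelength grid (nm) paired with a
#' vector of dimensionless absorbance (optical density) values. Negative
#' absorbances are permitted: they arise legitimately after blank
#' subtraction and clipping them would bias low-concentration regressions.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly
#'   increasing (unsorted input is sorted, carrying absorbance along).
#' @param absorbance Numeric vector of optical densities, same length.
#' @param replicate_id Optional label identifying the replicate.
#' @param blank_corrected Logical; has the solvent blank been subtracted?
#' @return An object of class \code{"spectrum"}.
#' @examples
#' s <- spectrum(c(440, 441, 442), c(0.65, 0.64, 0.66))
#' od_at(s, 440.5)
#' @export
spectrum <- function(wavelength, absorbance, replicate_id = NA_character_,
                     blank_corrected = FALSE) {
  if (!is.numeric(wavelength) || !is.numeric(absorbance))
    stop("wavelength and absorbance must be numeric")
  if (length(wavelength) != length(absorbance))
    stop("wavelength and absorbance must have the same length")
  if (length(wavelength) == 0L)
    stop("empty spectrum")
  if (anyNA(wavelength) || any(!is.finite(absorbance)))
    stop("wavelengths must be non-missing and absorbances finite")
  o <- order(wavelength)
  wavelength <- wavelength[o]
  absorbance <- absorbance[o]
  if (any(diff(wavelength) == 0))
    stop("duplicate wavelengths are not allowed")
  structure(
    list(wavelength = as.numeric(wavelength),
         absorbance = as.numeric(absorbance),
         replicate_id = replicate_id,
         blank_corrected = isTRUE(blank_corrected)),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("UV-Vis spectrum: %d points, %.0f-%.0f nm%s%s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              if (x$blank_corrected) ", blank-corrected" else "",
              if (!is.na(x$replicate_id))
                paste0(" [", x$replicate_id, "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, absorbance = x$absorbance)
}

#' @export
length.spectrum <- function(x) length(x$wavelength)

#' Read a spectrum from a delimited text file
#'
#' Expects a header row; the wavelength and absorbance column names are
#' configurable. Rows are sorted by wavelength; duplicate wavelengths and
#' non-numeric cells are errors.
#'
#' @param path Path to a CSV (or TSV, see \code{sep}) file.
#' @param wavelength_col,absorbance_col Column names to use.
#' @param sep Field separator; default \code{","}, use \code{"\t"} for TSV.
#' @inheritParams spectrum
#' @return A \code{spectrum}.
#' @export
read_spectrum <- function(path, wavelength_col = "wavelength_nm",
                          absorbance_col = "absorbance", sep = ",",
                          replicate_id = NA_character_,
                          blank_corrected = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(wavelength_col, absorbance_col))
    if (!col %in% names(df))
      stop(sprintf("column '%s' not found in %s", col, path))
  wl <- suppressWarnings(as.numeric(df[[wavelength_col]]))
  ab <- suppressWarnings(as.numeric(df[[absorbance_col]]))
  if (anyNA(wl) || anyNA(ab))
    stop(sprintf("non-numeric cells in %s", path))
  spectrum(wl, ab, replicate_id = replicate_id,
           blank_corrected = blank_corrected)
}

grids_identical <- function(a, b) {
  length(a$wavelength) == length(b$wavelength) &&
    all(a$wavelength == b$wavelength)
}

#' Average replicate spectra pointwise
#'
#' All spectra must share one wavelength grid. The result is marked
#' blank-corrected only if every input is.
#'
#' @param spectra A non-empty list of \code{spectrum} objects on a common grid.
#' @return A \code{spectrum} holding the pointwise arithmetic mean.
#' @export
average_replicates <- function(spectra) {
  if (!is.list(spectra) || length(spectra) == 0L)
    stop("need at least one spectrum")
  if (!all(vapply(spectra, inherits, logical(1), "spectrum")))
    stop("all elements must be spectrum objects")
  ref <- spectra[[1L]]
  for (s in spectra[-1L])
    if (!grids_identical(ref, s))
      stop("replicate spectra are on different wavelength grids")
  ab <- rowMeans(vapply(spectra, function(s) s$absorbance,
                        numeric(length(ref$wavelength))))
  spectrum(ref$wavelength, ab,
           replicate_id = "mean",
           blank_corrected = all(vapply(spectra, function(s)
             s$blank_corrected, logical(1))))
}

#' Subtract a solvent blank from a sample spectrum
#'
#' @param sample A \code{spectrum}, not yet blank-corrected.
#' @param blank The solvent (e.g. distilled water) \code{spectrum} on the
#'   same grid.
#' @return The pointwise difference, flagged as blank-corrected.
#' @export
blank_correct <- function(sample, blank) {
  stopifnot(inherits(sample, "spectrum"), inherits(blank, "spectrum"))
  if (sample$blank_corrected)
    stop("spectrum is already blank-corrected")
  if (!grids_identical(sample, blank))
    stop("sample and blank are on different wavelength grids")
  spectrum(sample$wavelength, sample$absorbance - blank$absorbance,
           replicate_id = sample$replicate_id, blank_corrected = TRUE)
}

#' Restrict a spectrum to a wavelength window
#'
#' @param s A \code{spectrum}.
#' @param lo,hi Window bounds in nm (inclusive), \code{lo < hi}.
#' @return The restricted \code{spectrum}; empty results are an error.
#' @export
restrict_range <- function(s, lo, hi) {
  stopifnot(inherits(s, "spectrum"))
  if (!(is.numeric(lo) && is.numeric(hi) && lo < hi))
    stop("need lo < hi")
  keep <- s$wavelength >= lo & s$wavelength <= hi
  if (!any(keep))
    stop(sprintf("no wavelengths in [%g, %g] nm", lo, hi))
  spectrum(s$wavelength[keep], s$absorbance[keep],
           replicate_id = s$replicate_id,
           blank_corrected = s$blank_corrected)
}

#' Optical density at a wavelength
#'
#' Returns the stored value for on-grid queries and linearly interpolates
#' between the neighbouring grid points otherwise. Queries outside the grid
#' span are an error (no extrapolation).
#'
#' @param s A \code{spectrum}.
#' @param wavelength Query wavelength(s) in nm.
#' @return Numeric vector of optical densities.
#' @export
od_at <- function(s, wavelength) {
  stopifnot(inherits(s, "spectrum"))
  if (any(wavelength < min(s$wavelength) | wavelength > max(s$wavelength)))
    stop("query wavelength outside the spectrum span")
  stats::approx(s$wavelength, s$absorbance, xout = wavelength,
                method = "linear", ties = "ordered")$y
}

#' Regrid a spectrum onto a new wavelength grid
#'
#' Linear interpolation; the new grid must lie within the spectrum span.
#'
#' @param s A \code{spectrum}.
#' @param grid Strictly increasing numeric vector of target wavelengths (nm).
#' @return A \code{spectrum} on \code{grid}.
#' @export
regrid_spectrum <- function(s, grid) {
  spectrum(grid, od_at(s, grid), replicate_id = s$replicate_id,
           blank_corrected = s$blank_corrected)
}

#' Bundle sample spectra for a dilution series
#'
#' Members are keyed by (dilution factor, replicate) and regridded to a
#' common 1 nm grid (the largest grid covered by every member and the
#' blank), so that downstream per-wavelength operations see aligned values.
#'
#' @param spectra List of \code{spectrum} objects.
#' @param dilution Numeric vector of dilution factors, one per spectrum.
#' @param blank The shared solvent blank \code{spectrum}.
#' @param replicate Optional replicate labels (defaults to running numbers
#'   within each dilution).
#' @param step Grid step in nm for the common grid (default 1).
#' @return An object of class \code{"spectra_set"}.
#' @export
spectra_set <- function(spectra, dilution, blank, replicate = NULL,
                        step = 1) {
  if (!is.list(spectra) || length(spectra) == 0L)
    stop("need at least one spectrum")
  if (length(dilution) != length(spectra))
    stop("dilution must have one entry per spectrum")
  if (any(dilution <= 0)) stop("dilution factors must be positive")
  stopifnot(inherits(blank, "spectrum"))
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(dilution), dilution, FUN = seq_along)
  }
  all_s <- c(spectra, list(blank))
  lo <- max(vapply(all_s, function(s) min(s$wavelength), numeric(1)))
  hi <- min(vapply(all_s, function(s) max(s$wavelength), numeric(1)))
  if (lo >= hi) stop("spectra have no common wavelength range")
  grid <- seq(ceiling(lo), floor(hi), by = step)
  structure(
    list(spectra = lapply(spectra, regrid_spectrum, grid = grid),
         dilution = as.numeric(dilution),
         replicate = replicate,
         blank = regrid_spectrum(blank, grid),
         grid = grid),
    class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf(
    "Spectra set: %d spectra, %d dilutions, grid %g-%g nm (%d points)\n",
    length(x$spectra), length(unique(x$dilution)),
    min(x$grid), max(x$grid), length(x$grid)))
  invisible(x)
}

#' Per-dilution blank-corrected mean absorbance matrix
#'
#' Replicates are averaged first and the blank is subtracted from the
#' average (numerically identical to per-replicate subtraction for means,
#' but the order is fixed for reproducibility). Spectra already flagged as
#' blank-corrected are used as they are.
#'
#' @param set A \code{spectra_set}.
#' @return A matrix with one row per grid wavelength and one column per
#'   unique dilution factor (ascending), with the grid in
#'   \code{attr(, "wavelength")} and dilutions as column names.
#' @export
set_od_matrix <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  dils <- sort(unique(set$dilution))
  m <- vapply(dils, function(d) {
    avg <- average_replicates(set$spectra[set$dilution == d])
    if (!avg$blank_corrected) avg <- blank_correct(avg, set$blank)
    avg$absorbance
  }, numeric(length(set$grid)))
  m <- matrix(m, nrow = length(set$grid),
              dimnames = list(NULL, as.character(dils)))
  attr(m, "wavelength") <- set$grid
  m
}

#' Read a spectra set from a manifest file
#'
#' The manifest is a CSV with columns \code{role} (\code{sample} or
#' \code{blank}), \code{dilution}, \code{replicate} and \code{file};
#' \code{file} paths are resolved relative to the manifest location.
#' Exactly one blank row is required.
#'
#' @param path Manifest CSV path.
#' @param wavelength_col,absorbance_col,sep Passed to
#'   \code{\link{read_spectrum}} for each member file.
#' @return A \code{\link{spectra_set}}.
#' @export
read_spectra_set <- function(path, wavelength_col = "wavelength_nm",
                             absorbance_col = "absorbance", sep = ",") {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("role", "dilution", "replicate", "file"))
    if (!col %in% names(man))
      stop(sprintf("manifest misses column '%s'", col))
  dir <- dirname(path)
  rd <- function(f, id) read_spectrum(
    file.path(dir, f), wavelength_col = wavelength_col,
    absorbance_col = absorbance_col, sep = sep, replicate_id = id)
  bl <- man[man$role == "blank", , drop = FALSE]
  if (nrow(bl) != 1L) stop("manifest must contain exactly one blank row")
  sm <- man[man$role == "sample", , drop = FALSE]
  if (nrow(sm) == 0L) stop("manifest contains no sample rows")
  spectra_set(
    spectra = Map(rd, sm$file, as.character(sm$replicate)),
    dilution = as.numeric(sm$dilution),
    replicate = as.character(sm$replicate),
    blank = rd(bl$file[1L], "blank"))
}
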