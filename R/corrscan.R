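#' Simple linear regression with coefficient of determination
#'
#' Ordinary least squares of \code{y} on \code{x}; \code{r2} is the squared
#' Pearson correlation, so it is invariant to exchanging the two axes. A
#' constant response is degenerate: the slope is 0 and \code{r2} is defined
#' as 0.
#'
#' @param x Predictor vector (must not be constant, length >= 3).
#' @param y Response vector, same length.
#' @return List with \code{slope}, \code{intercept}, \code{r2}, \code{n}.
#' @export
simple_linreg <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) stop("x is constant")
  syy <- sum((y - ybar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  r2 <- if (syy == 0) 0 else (sxy * sxy) / (sxx * syy)
  list(slope = slope, intercept = ybar - slope * xbar, r2 = r2,
       n = length(x))
}

#' Per-wavelength correlation scan of a dilution series
#'
#' The core band-selection step: at every wavelength of a 1 nm grid the
#' blank-corrected mean absorbance of each dilution is regressed on a
#' laboratory density parameter (biomass, chlorophyll a, cell number, ...)
#' and the slope, intercept and R-squared are tabulated as a function of
#' wavelength. Absorbance is the response ("concentration-absorbance
#' function"), but R-squared -- the quantity used downstream -- is
#' orientation-free.
#'
#' Dilutions whose parameter value is missing or flagged below the limit of
#' detection are excluded for that parameter. Wavelengths where the
#' absorbance is constant across the usable dilutions get \code{r2 = 0}
#' (with one warning for the whole scan) so that the table is always
#' complete.
#'
#' @param set A \code{\link{spectra_set}} covering the scan range.
#' @param series A \code{\link{dilution_series}} with matching dilution
#'   factors.
#' @param parameter Column of \code{series} to scan against (e.g.
#'   \code{"bmf"}), or \code{"ratio"}.
#' @param range Wavelength range in nm, default \code{c(300, 1100)}.
#' @param step Grid step in nm, default 1.
#' @return A data frame of class \code{"scan_table"} with columns
#'   \code{wavelength}, \code{slope}, \code{intercept}, \code{r2}, \code{n}.
#' @examples
#' sim <- synth_dilution_series(noise_sd = 0, seed = 1)
#' tab <- scan_wavelengths(sim$set, sim$series, "bme")
#' best_wavelength(tab)
#' @export
scan_wavelengths <- function(set, series, parameter,
                             range = c(300, 1100), step = 1) {
  stopifnot(inherits(set, "spectra_set"),
            inherits(series, "dilution_series"))
  grid <- seq(range[1L], range[2L], by = step)
  if (min(grid) < min(set$grid) || max(grid) > max(set$grid))
    stop("scan range not covered by the spectra set")
  vals <- series_values(series, parameter)
  dils <- sort(unique(set$dilution))
  vals <- vals[vals$dilution %in% dils, , drop = FALSE]
  if (nrow(vals) < 3L)
    stop(sprintf("fewer than 3 usable dilutions for '%s'", parameter))
  m <- set_od_matrix(set)
  keep <- match(as.character(vals$dilution), colnames(m))
  if (anyNA(keep)) stop("series dilutions missing from the spectra set")
  a <- m[, keep, drop = FALSE]
  if (!all(grid %in% attr(m, "wavelength"))) {
    a <- apply(a, 2L, function(col)
      stats::approx(attr(m, "wavelength"), col, xout = grid)$y)
  } else {
    a <- a[match(grid, attr(m, "wavelength")), , drop = FALSE]
  }
  x <- vals$value
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) stop(sprintf("parameter '%s' is constant", parameter))
  ybar <- rowMeans(a)
  sxy <- as.vector(a %*% xc)            # centring x centres the product
  syy <- rowSums((a - ybar)^2)
  slope <- sxy / sxx
  r2 <- ifelse(syy == 0, 0, (sxy * sxy) / (sxx * syy))
  if (any(syy == 0))
    warning(sprintf(
      "%d wavelength(s) with constant absorbance: r2 set to 0",
      sum(syy == 0)))
  structure(
    data.frame(wavelength = grid, slope = slope,
               intercept = ybar - slope * mean(x), r2 = r2, n = n),
    parameter_name = parameter,
    class = c("scan_table", "data.frame"))
}

#' @export
print.scan_table <- function(x, ...) {
  bw <- best_wavelength(x)
  cat(sprintf(
    "Correlation scan for '%s': %d wavelengths (%g-%g nm), n = %d\n",
    attr(x, "parameter_name"), nrow(x), min(x$wavelength),
    max(x$wavelength), x$n[1L]))
  cat(sprintf("  max R-squared %.4f at %g nm\n", bw$r2, bw$wavelength))
  invisible(x)
}

#' @export
plot.scan_table <- function(x, ...) {
  graphics::plot(x$wavelength, x$r2, type = "l",
                 xlab = "wavelength (nm)", ylab = expression(R^2),
                 main = sprintf("Correlation scan: %s",
                                attr(x, "parameter_name")), ...)
  bw <- best_wavelength(x)
  graphics::abline(v = bw$wavelength, lty = 2, col = "grey50")
  invisible(x)
}

#' Wavelength with the highest scan R-squared
#'
#' @param tab A \code{scan_table}.
#' @param window Optional nm pair restricting the search; must contain at
#'   least one scanned wavelength.
#' @return List with \code{wavelength} and \code{r2}. Ties are broken
#'   towards the lowest wavelength.
#' @export
best_wavelength <- function(tab, window = NULL) {
  stopifnot(inherits(tab, "scan_table"))
  if (nrow(tab) == 0L) stop("empty scan table")
  if (!is.null(window)) {
    tab <- tab[tab$wavelength >= window[1L] & tab$wavelength <= window[2L],
               , drop = FALSE]
    if (nrow(tab) == 0L) stop("no scanned wavelengths inside the window")
  }
  i <- which.max(tab$r2)   # which.max returns the first (lowest) maximum
  list(wavelength = tab$wavelength[i], r2 = tab$r2[i])
}
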