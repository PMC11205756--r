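#' Saturating absorbance of an algal suspension
#'
#' Forward model for the optical density of a cell suspension whose cells
#' increasingly shade one another: \code{A = A_max * (1 - exp(-k * c))}.
#' Strictly increasing and concave in \code{c}, bounded above by
#' \code{A_max}, with initial slope \code{A_max * k} (the dilute
#' Beer-Lambert regime).
#'
#' @param c Concentration in mg dry matter per litre, \code{>= 0}.
#' @param A_max Asymptotic absorbance (dimensionless, > 0). The default
#'   3.29 is the published calibration for a Chlorella vulgaris culture at
#'   440 nm; it is culture- and instrument-specific, so refit for new
#'   systems.
#' @param k Specific light absorption coefficient in L per mg dry matter
#'   (> 0); default 0.0022, same provenance as \code{A_max}.
#' @return Dimensionless optical density, vectorized over \code{c}.
#' @export
saturation_absorbance <- function(c, A_max = 3.29, k = 0.0022) {
  if (any(c < 0)) stop("concentration must be non-negative")
  if (A_max <= 0 || k <= 0) stop("A_max and k must be positive")
  A_max * (1 - exp(-k * c))
}

#' Invert the saturating calibration to estimate biomass
#'
#' Exact inverse of \code{\link{saturation_absorbance}}:
#' \code{biomass = ln(1 - od / A_max) / (-k)}. With the default constants
#' this is the published 440 nm estimator for Chlorella vulgaris dry
#' biomass.
#'
#' @param od Blank-corrected optical density at the calibration wavelength,
#'   \code{0 <= od < A_max}.
#' @inheritParams saturation_absorbance
#' @return Biomass concentration in mg dry matter per litre.
#' @examples
#' estimate_biomass_od440(0.65)            # mg d.m./L
#' @export
estimate_biomass_od440 <- function(od, A_max = 3.29, k = 0.0022) {
  if (A_max <= 0 || k <= 0) stop("A_max and k must be positive")
  if (any(od < 0)) stop("optical density must be non-negative")
  if (any(od >= A_max))
    stop(sprintf(
      "od >= A_max (%g): beyond the calibrated range, dilute the sample",
      A_max))
  log(1 - od / A_max) / (-k)
}

new_calib_model <- function(family, pars, x, y, fitted, r2,
                            wavelength = NA_real_, converged = TRUE) {
  structure(
    list(family = family, coefficients = pars, r2 = r2,
         n = length(x), wavelength = wavelength, x = x, y = y,
         fitted.values = fitted, residuals = y - fitted,
         converged = converged),
    class = "calib_model")
}

#' Fit a linear absorbance-concentration calibration
#'
#' @param x Concentration-like predictor (e.g. mg d.m./L or dilution ratio).
#' @param y Blank-corrected optical density at the calibration wavelength.
#' @param wavelength Optional nm label recorded in the model.
#' @return A \code{"calib_model"} of family \code{"linear"}.
#' @seealso \code{\link{fit_box_lucas}}, \code{\link{compare_models}}
#' @export
fit_linear <- function(x, y, wavelength = NA_real_) {
  fit <- simple_linreg(x, y)
  new_calib_model(
    "linear", c(intercept = fit$intercept, slope = fit$slope),
    x, y, fit$intercept + fit$slope * x, fit$r2, wavelength)
}

#' Fit the saturating (Box-Lucas) absorbance-concentration calibration
#'
#' Nonlinear least squares for \code{y = a * (1 - exp(-b * x))}, the
#' saturating shading model, with \code{a = A_max} and \code{b = k}.
#' Starting values are \code{a0 = 1.05 * max(y)} and \code{b0} from an OLS
#' fit of the linearization \code{-log(1 - y / a0)} on \code{x}. The
#' amplitude is profiled out (given \code{b}, the least-squares \code{a}
#' is closed-form), and the profiled sum of squared errors is minimized
#' over \code{b > 0} by \code{stats::nlminb} (relative tolerance 1e-10, at
#' most 500 iterations) -- a variable-projection scheme that remains
#' stable when the data barely leave the linear regime and only the
#' product \code{a * b} is well identified. Non-convergence is an error,
#' never a silent result. R-squared is \code{1 - SSE/SST} in the original
#' response space so it is comparable with the linear family.
#'
#' @inheritParams fit_linear
#' @return A \code{"calib_model"} of family \code{"saturating"} with
#'   coefficients \code{A_max} and \code{k}.
#' @examples
#' conc <- 1080 * c(1, .5, .2, .1, .05, .02, .01, .005, .002, .001)
#' od <- saturation_absorbance(conc)
#' coef(fit_box_lucas(conc, od))
#' @export
fit_box_lucas <- function(x, y, wavelength = NA_real_) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::var(x) == 0) stop("x is constant")
  if (max(y) <= 0 || stats::var(y) == 0)
    stop("degenerate response: y must vary and reach positive values")
  a0 <- 1.05 * max(y)
  z <- -log(pmax(1 - y / a0, .Machine$double.eps))
  b0 <- simple_linreg(x, z)$slope
  if (!is.finite(b0) || b0 <= 0) b0 <- 1 / max(abs(x))
  prof_a <- function(gb) sum(y * gb) / sum(gb * gb)
  prof_sse <- function(b) {
    gb <- 1 - exp(-b * x)
    out <- sum((y - prof_a(gb) * gb)^2)
    if (!is.finite(out)) .Machine$double.xmax else out
  }
  fit <- stats::nlminb(
    c(b = b0), prof_sse, lower = .Machine$double.xmin,
    control = list(iter.max = 500L, eval.max = 2000L, rel.tol = 1e-10))
  # "false convergence" / "x convergence" arise on exactly flat objectives
  # (zero-residual fits); only running out of iterations is a failure.
  if (fit$convergence != 0 &&
        grepl("limit reached|singular", fit$message))
    stop("Box-Lucas fit did not converge: ", fit$message, call. = FALSE)
  gb <- 1 - exp(-fit$par * x)
  pars <- c(a = prof_a(gb), b = unname(fit$par))
  if (!is.finite(pars[["a"]]) || pars[["a"]] <= 0)
    stop("Box-Lucas fit degenerate: non-positive amplitude", call. = FALSE)
  fitted <- pars[["a"]] * gb
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sum((y - fitted)^2) / sst
  new_calib_model(
    "saturating", c(A_max = pars[["a"]], k = pars[["b"]]),
    x, y, fitted, r2, wavelength, converged = TRUE)
}

#' Compare linear and saturating calibrations on the same data
#'
#' Both families are fitted and the one with the higher R-squared is
#' preferred; when the two agree to within 1e-9 (nested-model limit, e.g.
#' exactly linear data) the tie is resolved to the linear family by
#' parsimony.
#'
#' @inheritParams fit_linear
#' @return A \code{"calib_comparison"}: list with \code{linear},
#'   \code{saturating} (both \code{calib_model}s) and \code{preferred}.
#' @export
compare_models <- function(x, y, wavelength = NA_real_) {
  lin <- fit_linear(x, y, wavelength)
  sat <- fit_box_lucas(x, y, wavelength)
  preferred <- if (sat$r2 - lin$r2 > 1e-9) "saturating" else "linear"
  structure(list(linear = lin, saturating = sat, preferred = preferred),
            class = "calib_comparison")
}

#' @export
print.calib_comparison <- function(x, ...) {
  cat("Calibration model comparison\n")
  cat(sprintf("  linear:     R2 = %.6f\n", x$linear$r2))
  cat(sprintf("  saturating: R2 = %.6f (A_max = %.4g, k = %.4g)\n",
              x$saturating$r2, x$saturating$coefficients[["A_max"]],
              x$saturating$coefficients[["k"]]))
  cat(sprintf("  preferred:  %s\n", x$preferred))
  invisible(x)
}

#' @export
print.calib_model <- function(x, ...) {
  cat(sprintf("%s calibration model (n = %d%s)\n",
              x$family, x$n,
              if (!is.na(x$wavelength))
                sprintf(", %g nm", x$wavelength) else ""))
  print(round(x$coefficients, 6))
  cat(sprintf("R-squared (response space): %.6f\n", x$r2))
  invisible(x)
}

#' @export
summary.calib_model <- function(object, ...) {
  structure(
    list(model = object,
         sigma = sqrt(sum(object$residuals^2) /
                        max(object$n - length(object$coefficients), 1L))),
    class = "summary.calib_model")
}

#' @export
print.summary.calib_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("Residual standard error: %.5g on %d degrees of freedom\n",
              x$sigma, x$model$n - length(x$model$coefficients)))
  qs <- stats::quantile(x$model$residuals)
  names(qs) <- c("Min", "1Q", "Median", "3Q", "Max")
  cat("Residuals:\n"); print(signif(qs, 4))
  invisible(x)
}

#' @export
coef.calib_model <- function(object, ...) object$coefficients

#' Predict optical density from concentration
#'
#' @param object A \code{calib_model}.
#' @param newdata Numeric vector of concentrations (or a data frame with a
#'   column \code{x}). Omitted: returns the fitted values.
#' @param ... Unused.
#' @return Predicted optical densities.
#' @export
predict.calib_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  p <- object$coefficients
  switch(object$family,
         linear = p[["intercept"]] + p[["slope"]] * x,
         saturating = saturation_absorbance(x, p[["A_max"]], p[["k"]]))
}

#' @export
residuals.calib_model <- function(object, ...) object$residuals

#' @export
fitted.calib_model <- function(object, ...) object$fitted.values

#' @export
plot.calib_model <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "concentration (mg d.m./L)",
                 ylab = "optical density",
                 main = sprintf("%s calibration (R2 = %.4f)",
                                x$family, x$r2), ...)
  xx <- seq(min(x$x), max(x$x), length.out = 200L)
  graphics::lines(xx, predict(x, xx), col = "red3")
  invisible(x)
}

#' Estimate biomass concentration from a fitted calibration
#'
#' Inverts a fitted \code{calib_model} at the measured optical density.
#' For the saturating family this is the logarithmic inverse of the
#' shading model; for the linear family it is \code{(od - intercept) /
#' slope}.
#'
#' @param model A \code{calib_model}.
#' @param od Optical density value(s).
#' @return Estimated concentration in the units of the fitted predictor.
#' @export
estimate_biomass <- function(model, od) {
  stopifnot(inherits(model, "calib_model"))
  p <- model$coefficients
  switch(model$family,
         linear = (od - p[["intercept"]]) / p[["slope"]],
         saturating = estimate_biomass_od440(od, p[["A_max"]], p[["k"]]))
}
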