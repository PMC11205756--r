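MEASURED_PARAMS <- c("bme", "bmf", "chla", "mg", "cn", "rfu")

#' Construct a dilution-series parameter table
#'
#' One row per dilution factor of a series prepared from an algal stock
#' culture, holding whichever laboratory density parameters were measured:
#' \code{bme}/\code{bmf} biomass by evaporation/filtration (mg dry matter
#' per L), \code{chla} chlorophyll a (ug/L), \code{mg} magnesium (ug/L),
#' \code{cn} cell number (10^6 cells/L), \code{rfu} relative fluorescence
#' units. \code{ratio} is always \code{1/dilution}. A parallel logical
#' below-LOD flag per value marks measurements under the limit of
#' detection; flagged values are excluded from fits.
#'
#' @param dilution Positive, unique dilution factors.
#' @param bme,bmf,chla,mg,cn,rfu Optional numeric parameter vectors
#'   (\code{NA} = not measured / below LOD without a reading).
#' @param lod Optional logical matrix or data frame (rows = dilutions,
#'   columns named after parameters) flagging below-LOD values; defaults to
#'   flagging exactly the \code{NA} cells.
#' @return A data frame of class \code{"dilution_series"} with an
#'   \code{attr(, "lod")} flag matrix.
#' @examples
#' chlorella_series()   # the packaged Chlorella vulgaris reference series
#' @export
dilution_series <- function(dilution, bme = NULL, bmf = NULL, chla = NULL,
                            mg = NULL, cn = NULL, rfu = NULL, lod = NULL) {
  if (any(dilution <= 0)) stop("dilution factors must be positive")
  if (anyDuplicated(dilution)) stop("dilution factors must be unique")
  df <- data.frame(dilution = as.numeric(dilution),
                   ratio = 1 / as.numeric(dilution))
  supplied <- list(bme = bme, bmf = bmf, chla = chla, mg = mg,
                   cn = cn, rfu = rfu)
  for (p in names(supplied)) {
    v <- supplied[[p]]
    if (is.null(v)) next
    if (length(v) != nrow(df))
      stop(sprintf("'%s' must have one value per dilution", p))
    if (any(v < 0, na.rm = TRUE))
      stop(sprintf("'%s' must be non-negative", p))
    df[[p]] <- as.numeric(v)
  }
  params <- setdiff(names(df), c("dilution", "ratio"))
  flags <- matrix(FALSE, nrow(df), length(params),
                  dimnames = list(NULL, params))
  for (p in params) flags[, p] <- is.na(df[[p]])
  if (!is.null(lod)) {
    lod <- as.matrix(lod)
    for (p in intersect(colnames(lod), params))
      flags[, p] <- flags[, p] | (lod[, p] %in% TRUE)
  }
  structure(df, lod = flags,
            class = c("dilution_series", "data.frame"))
}

#' @export
print.dilution_series <- function(x, ...) {
  out <- as.data.frame(x)
  flags <- attr(x, "lod")
  for (p in colnames(flags)) {
    col <- format(out[[p]])
    col[flags[, p] & is.na(out[[p]])] <- "<LOD"
    col[flags[, p] & !is.na(out[[p]])] <-
      paste0(format(out[[p]][flags[, p] & !is.na(out[[p]])]), "*")
    out[[p]] <- col
  }
  cat(sprintf("Dilution series: %d dilutions (%s measured)\n",
              nrow(x), paste(colnames(flags), collapse = ", ")))
  print(out, row.names = FALSE)
  if (any(flags & !is.na(as.matrix(as.data.frame(x)[, colnames(flags),
                                                    drop = FALSE]))))
    cat("* value recorded but flagged below the limit of detection\n")
  invisible(x)
}

#' Usable values of one parameter of a dilution series
#'
#' Drops rows whose value is missing or flagged below the limit of
#' detection (the flag policy: below-LOD readings never enter fits).
#'
#' @param series A \code{dilution_series}.
#' @param parameter A measured parameter name, or \code{"ratio"} /
#'   \code{"dilution"} (never flagged).
#' @param drop_lod Exclude flagged values (default \code{TRUE}).
#' @return Data frame with columns \code{dilution} and \code{value}.
#' @export
series_values <- function(series, parameter, drop_lod = TRUE) {
  stopifnot(inherits(series, "dilution_series"))
  if (!parameter %in% names(series))
    stop(sprintf("parameter '%s' not present in the series", parameter))
  v <- series[[parameter]]
  keep <- !is.na(v)
  flags <- attr(series, "lod")
  if (drop_lod && parameter %in% colnames(flags))
    keep <- keep & !flags[, parameter]
  data.frame(dilution = series$dilution[keep], value = v[keep])
}

#' Read a dilution series from CSV
#'
#' Columns: \code{dilution, ratio, bme, bmf, chla, mg, cn, rfu} (any subset
#' of the parameter columns). Empty cells are missing; the literal token
#' \code{<LOD} marks a below-detection value with no reading.
#'
#' @param path CSV path.
#' @return A \code{\link{dilution_series}}.
#' @export
read_dilution_series <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE)
  if (!"dilution" %in% names(raw)) stop("missing 'dilution' column")
  parse_col <- function(s) {
    v <- rep(NA_real_, length(s))
    num <- !(s == "" | s == "<LOD" | is.na(s))
    v[num] <- suppressWarnings(as.numeric(s[num]))
    if (anyNA(v[num])) stop("non-numeric cell in ", path)
    list(value = v, lod = s == "<LOD" & !is.na(s))
  }
  cols <- intersect(MEASURED_PARAMS, names(raw))
  parsed <- lapply(raw[cols], parse_col)
  args <- c(list(dilution = as.numeric(raw$dilution)),
            lapply(parsed, `[[`, "value"))
  series <- do.call(dilution_series, args)
  flags <- attr(series, "lod")
  for (p in cols) flags[, p] <- flags[, p] | parsed[[p]]$lod
  attr(series, "lod") <- flags
  series
}

#' The packaged Chlorella vulgaris reference dilution series
#'
#' Ten dilutions (1x to 1000x) of a dense Chlorella vulgaris stock with
#' biomass by evaporation and filtration, chlorophyll a, magnesium, cell
#' number and fluorescence readings; evaporation biomass is below the
#' detection limit from 200x and filtration biomass at 1000x. The stock
#' cell concentration is 1.08e11 cells/L.
#'
#' @return A \code{\link{dilution_series}}.
#' @export
chlorella_series <- function() {
  read_dilution_series(system.file("extdata", "chlorella_series.csv",
                                   package = "algadens", mustWork = TRUE))
}

family_r2 <- function(x, y, family) {
  ok <- switch(family,
               linear = TRUE,
               logarithmic = all(x > 0),
               exponential = all(y > 0))
  if (!isTRUE(ok)) return(NA_real_)
  tx <- if (family == "logarithmic") log(x) else x
  ty <- if (family == "exponential") log(y) else y
  if (stats::var(tx) == 0 || stats::var(ty) == 0) return(0)
  stats::cor(tx, ty)^2
}

#' Pairwise best-trendline correlations of a dilution series
#'
#' For every pair of parameters, fits each candidate trendline family --
#' linear (\code{y ~ x}), logarithmic (\code{y ~ log x}), exponential
#' (\code{log y ~ x}) -- on the rows where both values are usable, and
#' reports the family with the highest R-squared. R-squared for the
#' transformed families is computed in the transformed space, which is how
#' spreadsheet trendlines report it; pass \code{families = "linear"} for a
#' plain linear correlation matrix.
#'
#' @param series A \code{\link{dilution_series}}.
#' @param parameters Parameters to include; defaults to \code{"ratio"} plus
#'   every measured column.
#' @param families Candidate families.
#' @return A \code{"correlation_matrix"}: list of matrices \code{r2},
#'   \code{family}, \code{n}.
#' @export
pairwise_correlations <- function(series,
                                  parameters = NULL,
                                  families = c("linear", "logarithmic",
                                               "exponential")) {
  stopifnot(inherits(series, "dilution_series"))
  families <- match.arg(families, several.ok = TRUE)
  if (is.null(parameters))
    parameters <- c("ratio", intersect(MEASURED_PARAMS, names(series)))
  p <- length(parameters)
  r2 <- matrix(NA_real_, p, p, dimnames = list(parameters, parameters))
  fam <- matrix(NA_character_, p, p, dimnames = dimnames(r2))
  n <- matrix(NA_integer_, p, p, dimnames = dimnames(r2))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    vx <- series_values(series, parameters[i])
    vy <- series_values(series, parameters[j])
    m <- merge(vx, vy, by = "dilution")
    if (nrow(m) < 3L)
      stop(sprintf("fewer than 3 complete pairs for (%s, %s)",
                   parameters[i], parameters[j]))
    scores <- vapply(families, function(f)
      family_r2(m$value.x, m$value.y, f), numeric(1))
    if (all(is.na(scores)))
      stop(sprintf("no admissible trendline family for (%s, %s)",
                   parameters[i], parameters[j]))
    best <- which.max(scores)
    r2[i, j] <- scores[best]
    fam[i, j] <- families[best]
    n[i, j] <- nrow(m)
  }
  structure(list(r2 = r2, family = fam, n = n, parameters = parameters),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  abb <- c(linear = "L", logarithmic = "Lg", exponential = "Ep")
  cells <- matrix("-", nrow(x$r2), ncol(x$r2), dimnames = dimnames(x$r2))
  up <- upper.tri(cells)
  cells[up] <- sprintf("%.*f (%s)", digits, x$r2[up], abb[x$family[up]])
  cat("Best-trendline correlations (upper triangle):\n")
  print(as.data.frame(cells), right = TRUE)
  invisible(x)
}

#' Chlorophyll a by the trichromatic (Felfoldy-type) formula
#'
#' Turbidity-corrected linear combination of extract absorbances:
#' \code{chla = (c1 * (a666 - a750) - c2 * (a653 - a750)) * factor}.
#' The coefficients are method- and pathlength-specific and must be
#' supplied by the user; none are hard-coded because shipping invented
#' constants would misattribute them.
#'
#' @param a750,a666,a653 Extract absorbances at 750 (turbidity), 666 and
#'   653 nm.
#' @param coeffs List with elements \code{c1}, \code{c2} and \code{factor}
#'   (pathlength/volume scaling).
#' @return Chlorophyll a concentration in the units implied by
#'   \code{coeffs} (conventionally ug/L).
#' @export
felfoldy_chla <- function(a750, a666, a653, coeffs) {
  if (missing(coeffs) || is.null(coeffs))
    stop("Felfoldy coefficients must be supplied (c1, c2, factor)")
  for (nm in c("c1", "c2", "factor"))
    if (is.null(coeffs[[nm]]))
      stop(sprintf("coefficient '%s' is missing", nm))
  if (any(!is.finite(c(a750, a666, a653))))
    stop("absorbances must be finite")
  (coeffs$c1 * (a666 - a750) - coeffs$c2 * (a653 - a750)) * coeffs$factor
}

#' Molar mass ratio converting magnesium to chlorophyll a
#'
#' Chlorophyll a carries one central Mg atom per molecule, so the
#' conversion is the ratio of the molar masses of chlorophyll a
#' (893.5 g/mol) and Mg (24.3 g/mol), rounded to two decimals: 36.77.
#'
#' @return The ratio 36.77.
#' @export
mg_chla_ratio <- function() round(893.5 / 24.3, 2)

#' Chlorophyll a estimated from magnesium concentration
#'
#' @param mg_conc Magnesium concentration, ug/L, \code{>= 0}.
#' @param ratio Mass conversion ratio; default \code{\link{mg_chla_ratio}()}.
#' @return Chlorophyll a concentration, ug/L.
#' @export
chla_from_mg <- function(mg_conc, ratio = mg_chla_ratio()) {
  if (any(mg_conc < 0)) stop("magnesium concentration must be non-negative")
  mg_conc * ratio
}

#' Magnesium content per 100 g of dry biomass
#'
#' \code{mg_conc [ug/L] / biomass [mg/L] * 100} gives mg Mg per 100 g dry
#' matter (the unit factors of ug/mg and g/100 g cancel).
#'
#' @param mg_conc Magnesium concentration, ug/L.
#' @param biomass Dry biomass concentration, mg/L, \code{> 0}.
#' @return Magnesium content in mg per 100 g dry matter.
#' @export
mg_per_100g <- function(mg_conc, biomass) {
  if (any(mg_conc < 0)) stop("magnesium concentration must be non-negative")
  if (any(biomass <= 0)) stop("biomass must be positive")
  mg_conc / biomass * 100
}

#' Average single-cell weight
#'
#' @param biomass Dry biomass concentration, mg/L.
#' @param cells Cell concentration in 10^6 cells/L, \code{> 0}.
#' @return Weight of one million cells in ug (equivalently pg per cell).
#' @export
cell_weight <- function(biomass, cells) {
  if (any(biomass < 0)) stop("biomass must be non-negative")
  if (any(cells <= 0)) stop("cell number must be positive")
  biomass * 1000 / cells
}

#' Derived per-cell and composition quantities of a dilution series
#'
#' Computes, for the low-dilution rows where the laboratory values are
#' still reliable, the magnesium content of the dry biomass, the
#' chlorophyll a implied by the magnesium reading, and the average
#' single-cell weight, plus their means and sample standard deviations.
#' Rows above \code{max_dilution} are excluded (measurement error dominates
#' the small readings at strong dilution).
#'
#' @param series A \code{\link{dilution_series}} with \code{bme},
#'   \code{mg} and \code{cn} columns.
#' @param max_dilution Largest dilution factor included; default 10.
#' @return A \code{"derived_summary"}: list with a per-row \code{table} and
#'   \code{mg_per_100g} / \code{cell_weight} mean-and-sd vectors.
#' @examples
#' summarize_derived(chlorella_series())
#' @export
summarize_derived <- function(series, max_dilution = 10) {
  stopifnot(inherits(series, "dilution_series"))
  for (col in c("bme", "mg", "cn"))
    if (!col %in% names(series))
      stop(sprintf("series misses required column '%s'", col))
  rows <- series$dilution <= max_dilution &
    !is.na(series$bme) & !is.na(series$mg) & !is.na(series$cn)
  if (!any(rows)) stop("no usable rows at or below max_dilution")
  d <- as.data.frame(series)[rows, , drop = FALSE]
  tab <- data.frame(
    dilution = d$dilution,
    bme = d$bme,
    mg = d$mg,
    mg_per_100g = mg_per_100g(d$mg, d$bme),
    chla_from_mg = chla_from_mg(d$mg),
    chla = if ("chla" %in% names(d)) d$chla else NA_real_,
    cn = d$cn,
    cell_weight = cell_weight(d$bme, d$cn))
  if (nrow(tab) == 1L)
    warning("single included row: standard deviations reported as 0")
  msd <- function(v) {
    if (length(v) == 1L) c(mean = v, sd = 0)
    else c(mean = mean(v), sd = stats::sd(v))
  }
  structure(list(table = tab,
                 mg_per_100g = msd(tab$mg_per_100g),
                 cell_weight = msd(tab$cell_weight),
                 max_dilution = max_dilution),
            class = "derived_summary")
}

#' @export
print.derived_summary <- function(x, ...) {
  cat(sprintf("Derived quantities (dilutions up to %gx):\n",
              x$max_dilution))
  tab <- x$table
  tab$mg_per_100g <- round(tab$mg_per_100g, 2)
  tab$chla_from_mg <- round(tab$chla_from_mg)
  tab$cell_weight <- round(tab$cell_weight, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Mg content:  %.2f +/- %.2f mg/100 g d.m.\n",
              x$mg_per_100g["mean"], x$mg_per_100g["sd"]))
  cat(sprintf("Cell weight: %.3f +/- %.3f ug/10^6 cells\n",
              x$cell_weight["mean"], x$cell_weight["sd"]))
  invisible(x)
}
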