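#' Counting-chamber configuration
#'
#' Parameters of the semiautomated counting-chamber pipeline: rolling-ball
#' style background subtraction, 8-bit conversion, fixed-range threshold,
#' size-filtered particle analysis, and the chamber geometry converting a
#' count into cells per litre.
#'
#' The size filter defaults (6-150 px) and the 0-200 threshold follow the
#' reference workflow for Chlorella-sized cells in a Buerker chamber; the
#' analyzed area default is 0.64 mm^2 and the chamber depth 0.1 mm
#' (standard Buerker geometry). All of them are magnification- and
#' chamber-specific and should be set for other optics.
#'
#' @param background_radius Structuring-element radius in px for background
#'   subtraction (default 50).
#' @param light_background Dark cells on a light background (default
#'   \code{TRUE}).
#' @param threshold_lo,threshold_hi 8-bit threshold bounds (defaults 0 and
#'   200).
#' @param min_area,max_area Particle area bounds in px (defaults 6 and 150).
#' @param exclude_border Drop particles touching the image border (default
#'   \code{FALSE}).
#' @param analyzed_area Analyzed chamber area in mm^2 (default 0.64).
#' @param chamber_depth Chamber depth in mm (default 0.1).
#' @param dilution_factor Dilution of the counted sample (default 1).
#' @return A list of class \code{"counting_config"}.
#' @export
counting_config <- function(background_radius = 50,
                            light_background = TRUE,
                            threshold_lo = 0, threshold_hi = 200,
                            min_area = 6, max_area = 150,
                            exclude_border = FALSE,
                            analyzed_area = 0.64, chamber_depth = 0.1,
                            dilution_factor = 1) {
  if (!(threshold_lo >= 0 && threshold_lo <= threshold_hi &&
          threshold_hi <= 255))
    stop("need 0 <= threshold_lo <= threshold_hi <= 255")
  if (!(min_area > 0 && min_area <= max_area))
    stop("need 0 < min_area <= max_area")
  if (analyzed_area <= 0 || chamber_depth <= 0)
    stop("analyzed_area and chamber_depth must be positive")
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  if (background_radius < 1) stop("background_radius must be >= 1")
  structure(list(background_radius = background_radius,
                 light_background = isTRUE(light_background),
                 threshold_lo = threshold_lo,
                 threshold_hi = threshold_hi,
                 min_area = min_area, max_area = max_area,
                 exclude_border = isTRUE(exclude_border),
                 analyzed_area = analyzed_area,
                 chamber_depth = chamber_depth,
                 dilution_factor = dilution_factor),
            class = "counting_config")
}

check_gray <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2-D single-channel numeric matrix")
  invisible(image)
}

#' Remove slowly varying illumination from a brightfield image
#'
#' Rolling-ball-equivalent background subtraction by grayscale morphology
#' with a disc structuring element: for a light background the background
#' is estimated by closing (which erases dark features smaller than the
#' disc) and subtracted, leaving dark cells dark on a near-flat residual
#' background; for a dark background, opening is used symmetrically.
#'
#' @param image 2-D numeric matrix (any intensity scale).
#' @param radius Disc radius in px; must exceed the largest cell radius.
#' @param light_background Logical, see above.
#' @return Background-subtracted matrix (same shape; values centred near
#'   zero for background pixels).
#' @export
subtract_background <- function(image, radius = 50,
                                light_background = TRUE) {
  check_gray(image)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  bg <- if (light_background) EBImage::closing(image, brush)
        else EBImage::opening(image, brush)
  image - as.matrix(bg)
}

#' Convert an image to 8-bit grayscale
#'
#' Linear min-max rescale to 0..255, rounded to integers. A constant image
#' has no contrast to stretch: it maps to all zeros with a warning.
#'
#' @param image 2-D numeric matrix.
#' @return Integer-valued matrix in 0..255.
#' @export
to_8bit <- function(image) {
  check_gray(image)
  rng <- range(image)
  if (diff(rng) == 0) {
    warning("constant image: mapped to all zeros")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  matrix(as.integer(round((image - rng[1L]) / diff(rng) * 255)),
         nrow(image), ncol(image))
}

#' Fixed-range intensity threshold
#'
#' @param image 8-bit matrix (values 0..255).
#' @param lo,hi Inclusive foreground bounds, \code{0 <= lo <= hi <= 255}.
#' @return Logical foreground mask.
#' @export
threshold_mask <- function(image, lo = 0, hi = 200) {
  check_gray(image)
  if (!(lo >= 0 && lo <= hi && hi <= 255))
    stop("need 0 <= lo <= hi <= 255")
  image >= lo & image <= hi
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged with a union-find pass.
label8 <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))
  pairs <- pairs[pairs[, 1L] > 0 & pairs[, 2L] > 0 &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Size-filtered connected-particle analysis
#'
#' Labels 8-connected foreground components and keeps those whose pixel
#' area lies within \code{[min_area, max_area]}. Particles touching the
#' border are kept unless \code{exclude_border}.
#'
#' @param mask Logical (or 0/1) foreground mask.
#' @param min_area,max_area Inclusive area bounds in px.
#' @param exclude_border Drop border-touching particles.
#' @return Data frame with one row per retained particle -- \code{area},
#'   centroid (\code{row}, \code{col}) and bounding box -- sorted by
#'   centroid row then column. Zero rows when nothing is retained.
#' @export
analyze_particles <- function(mask, min_area = 6, max_area = 150,
                              exclude_border = FALSE) {
  check_gray(mask * 1)
  if (!(min_area > 0 && min_area <= max_area))
    stop("need 0 < min_area <= max_area")
  lab <- label8(mask)
  empty <- data.frame(area = numeric(0), row = numeric(0),
                      col = numeric(0), row_min = integer(0),
                      row_max = integer(0), col_min = integer(0),
                      col_max = integer(0))
  if (max(lab) == 0L) return(empty)
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  area <- as.vector(table(factor(lv, levels = seq_len(max(lab)))))
  agg <- function(v, f) as.vector(tapply(v, lv, f))
  df <- data.frame(area = area,
                   row = agg(idx[, 1L], mean),
                   col = agg(idx[, 2L], mean),
                   row_min = agg(idx[, 1L], min),
                   row_max = agg(idx[, 1L], max),
                   col_min = agg(idx[, 2L], min),
                   col_max = agg(idx[, 2L], max))
  keep <- df$area >= min_area & df$area <= max_area
  if (exclude_border)
    keep <- keep & df$row_min > 1 & df$col_min > 1 &
      df$row_max < nrow(mask) & df$col_max < ncol(mask)
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$row, df$col), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Convert a chamber count to cells per litre
#'
#' \code{cells/L = count / (analyzed_area [mm^2] * chamber_depth [mm] *
#' 1e-6 L/mm^3) * dilution_factor}.
#'
#' @param count Non-negative particle count.
#' @param config A \code{\link{counting_config}} (chamber geometry and
#'   dilution).
#' @return Cell concentration in cells per litre.
#' @export
counts_to_concentration <- function(count, config = counting_config()) {
  stopifnot(inherits(config, "counting_config"))
  if (count < 0) stop("count must be non-negative")
  volume_l <- config$analyzed_area * config$chamber_depth * 1e-6
  count / volume_l * config$dilution_factor
}

#' Full counting-chamber pipeline
#'
#' Composition \code{subtract_background -> to_8bit -> threshold_mask ->
#' analyze_particles -> counts_to_concentration}; the intermediate images
#' are retained in the result for audit (the background-subtracted image,
#' the 8-bit conversion, and the binary mask).
#'
#' @param image 2-D numeric matrix (brightfield chamber image).
#' @param config A \code{\link{counting_config}}.
#' @param keep_intermediates Retain intermediate images (default
#'   \code{TRUE}).
#' @return An object of class \code{"cell_count"}: \code{count},
#'   \code{particle_areas}, \code{particles} (full table),
#'   \code{cells_per_liter}, \code{config}, and \code{intermediates}.
#' @examples
#' scene <- synth_scene(scene_config(n_cells = 20), seed = 7)
#' res <- count_pipeline(scene$image)
#' res$count
#' @export
count_pipeline <- function(image, config = counting_config(),
                           keep_intermediates = TRUE) {
  stopifnot(inherits(config, "counting_config"))
  check_gray(image)
  sub <- subtract_background(image, config$background_radius,
                             config$light_background)
  eight <- to_8bit(sub)
  mask <- threshold_mask(eight, config$threshold_lo, config$threshold_hi)
  particles <- analyze_particles(mask, config$min_area, config$max_area,
                                 config$exclude_border)
  structure(
    list(count = nrow(particles),
         particle_areas = particles$area,
         particles = particles,
         cells_per_liter = counts_to_concentration(nrow(particles),
                                                   config),
         config = config,
         intermediates = if (keep_intermediates)
           list(background_subtracted = sub, eightbit = eight,
                mask = mask)),
    class = "cell_count")
}

#' @export
print.cell_count <- function(x, ...) {
  cat(sprintf(
    "Cell count: %d particles on %.2f mm^2 (depth %.2f mm, dilution %gx)\n",
    x$count, x$config$analyzed_area, x$config$chamber_depth,
    x$config$dilution_factor))
  cat(sprintf("  %.4g cells/L\n", x$cells_per_liter))
  if (x$count > 0)
    cat(sprintf("  particle area: median %.0f px (range %d-%d)\n",
                stats::median(x$particle_areas),
                min(x$particle_areas), max(x$particle_areas)))
  invisible(x)
}

#' Read a single-channel microscope image
#'
#' Reads a grayscale PNG or TIFF into a plain numeric matrix (intensities
#' in 0..1 as stored). Multi-channel images are rejected: the counting
#' pipeline is defined on single-channel brightfield data.
#'
#' @param path Image path.
#' @return Numeric matrix.
#' @export
read_cell_image <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) != 2L)
    stop("expected a single-channel image; got ",
         paste(dim(dat), collapse = "x"))
  as.matrix(dat)
}
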