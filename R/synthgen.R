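#' Configuration for the synthetic spectrum generator
#'
#' The generator applies the saturating shading model independently at each
#' wavelength: \code{A(lambda) = A_max(lambda) * (1 - exp(-k(lambda) * c))},
#' optionally perturbed by noise. The default maximum-absorbance profile is
#' an illustrative chlorophyll-like landscape -- a flat scattering baseline
#' plus Gaussian bands at 440 nm (Soret) and 680 nm (red) -- and the
#' default absorption coefficient profile is flat at 0.0022 L/mg, treating
#' the shading rate as wavelength-common. Spectral noise is multiplicative
#' by default (residual spread grows with signal); switch to
#' \code{"additive"} for instrument-floor noise.
#'
#' @param peaks Data frame with columns \code{center} (nm), \code{width}
#'   (Gaussian sd, nm) and \code{height} (added A_max at the peak).
#' @param baseline Wavelength-flat A_max contribution (cell scattering).
#' @param k0 Base specific absorption coefficient, L per mg d.m.
#' @param k_profile Optional function of wavelength returning a positive
#'   multiplier for \code{k0} (default flat).
#' @param noise_sd Noise standard deviation (relative for multiplicative,
#'   absorbance units for additive).
#' @param noise_type \code{"multiplicative"} or \code{"additive"}.
#' @param grid Wavelength grid, default \code{seq(300, 1100, 1)}.
#' @return A list of class \code{"spectrum_generator_config"} with the
#'   evaluated \code{A_max} and \code{k} profiles.
#' @export
spectrum_generator_config <- function(
    peaks = data.frame(center = c(440, 680), width = c(30, 20),
                       height = c(1.8, 1.0)),
    baseline = 1.5, k0 = 0.0022, k_profile = NULL,
    noise_sd = 0.01, noise_type = c("multiplicative", "additive"),
    grid = seq(300, 1100, by = 1)) {
  noise_type <- match.arg(noise_type)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (baseline < 0 || any(peaks$height < 0) || any(peaks$width <= 0))
    stop("profile parameters must be non-negative (widths positive)")
  A_max <- rep(baseline, length(grid))
  for (i in seq_len(nrow(peaks)))
    A_max <- A_max + peaks$height[i] *
      exp(-0.5 * ((grid - peaks$center[i]) / peaks$width[i])^2)
  k <- if (is.null(k_profile)) rep(k0, length(grid))
       else k0 * k_profile(grid)
  if (any(A_max <= 0) || any(k <= 0))
    stop("A_max and k profiles must be positive on the grid")
  structure(list(grid = grid, A_max = A_max, k = k,
                 noise_sd = noise_sd, noise_type = noise_type),
            class = "spectrum_generator_config")
}

#' Generate a synthetic absorbance spectrum
#'
#' @param concentration Biomass concentration in mg d.m./L, \code{>= 0}.
#' @param cfg A \code{\link{spectrum_generator_config}}.
#' @param seed Optional integer seed (bit-reproducible output); omit to use
#'   the current RNG stream.
#' @param replicate_id Label stored on the spectrum.
#' @return A \code{\link{spectrum}} (marked not blank-corrected, so the
#'   standard averaging/blank pipeline applies; the implied blank is zero).
#' @export
synth_spectrum <- function(concentration, cfg = spectrum_generator_config(),
                           seed = NULL, replicate_id = NA_character_) {
  stopifnot(inherits(cfg, "spectrum_generator_config"))
  if (concentration < 0) stop("concentration must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  a <- cfg$A_max * (1 - exp(-cfg$k * concentration))
  if (cfg$noise_sd > 0) {
    eps <- stats::rnorm(length(a), 0, cfg$noise_sd)
    a <- if (cfg$noise_type == "multiplicative") a * (1 + eps) else a + eps
  }
  spectrum(cfg$grid, a, replicate_id = replicate_id)
}

#' Ground-truth maximum-sensitivity wavelength of the generator
#'
#' The concentration sensitivity of the forward model at wavelength
#' \code{lambda}, averaged over a concentration series, is
#' \code{mean_i A_max(lambda) k(lambda) exp(-k(lambda) c_i)}. Returns the
#' grid wavelength maximizing it (ties towards the lowest wavelength),
#' which is where a calibration scan has the most signal to work with.
#'
#' @param cfg A \code{\link{spectrum_generator_config}}.
#' @param concentrations Concentration series, mg d.m./L.
#' @return Wavelength in nm.
#' @export
max_sensitivity_wavelength <- function(cfg, concentrations) {
  stopifnot(inherits(cfg, "spectrum_generator_config"))
  sens <- vapply(seq_along(cfg$grid), function(i)
    mean(cfg$A_max[i] * cfg$k[i] * exp(-cfg$k[i] * concentrations)),
    numeric(1))
  cfg$grid[which.max(sens)]
}

#' Generate a synthetic dilution series with paired spectra
#'
#' Emulates the bench workflow: a dense stock with known parameter values
#' is diluted by a ratio list, every parameter scales proportionally with
#' the ratio (before noise), readings below a per-parameter detection limit
#' are flagged, and each dilution gets replicate spectra from
#' \code{\link{synth_spectrum}} at the implied biomass. Defaults reproduce
#' the packaged reference series' stock values and the standard ratio list
#' of a 1000-fold series.
#'
#' @param stock Named list of stock (undiluted) parameter values.
#' @param ratios Dilution ratios (1/dilution factor), distinct, positive.
#' @param noise_sd Relative measurement noise per parameter: scalar or
#'   named vector (0 = noiseless).
#' @param lod Optional named vector of detection limits; readings at or
#'   below the limit are flagged below-LOD (and thereby excluded from
#'   fits).
#' @param n_replicates Spectra per dilution (default 2).
#' @param spectra_cfg A \code{\link{spectrum_generator_config}} for the
#'   paired spectra.
#' @param biomass_param Which stock parameter is the biomass driving the
#'   spectra (default \code{"bme"}).
#' @param seed Optional integer seed.
#' @return List with \code{series} (a \code{\link{dilution_series}}) and
#'   \code{set} (a \code{\link{spectra_set}}).
#' @export
synth_dilution_series <- function(
    stock = list(bme = 960, bmf = 770, chla = 7515.6, mg = 204.5,
                 cn = 108222.7, rfu = 1689562),
    ratios = c(1, 0.5, 0.2, 0.1, 0.05, 0.02, 0.01, 0.005, 0.002, 0.001),
    noise_sd = 0.01, lod = NULL, n_replicates = 2L,
    spectra_cfg = spectrum_generator_config(),
    biomass_param = "bme", seed = NULL) {
  if (any(ratios <= 0) || anyDuplicated(ratios))
    stop("ratios must be positive and distinct")
  if (!biomass_param %in% names(stock))
    stop(sprintf("stock has no '%s' entry", biomass_param))
  if (!is.null(seed)) set.seed(seed)
  ratios <- sort(ratios, decreasing = TRUE)
  dilution <- 1 / ratios
  params <- names(stock)
  sd_of <- function(p) {
    if (length(noise_sd) == 1L && is.null(names(noise_sd)))
      return(noise_sd)
    if (!p %in% names(noise_sd)) 0 else noise_sd[[p]]
  }
  vals <- lapply(params, function(p) {
    v <- stock[[p]] * ratios
    s <- sd_of(p)
    if (s > 0) v <- pmax(v * (1 + stats::rnorm(length(v), 0, s)), 0)
    v
  })
  names(vals) <- params
  flags <- NULL
  if (!is.null(lod)) {
    flags <- matrix(FALSE, length(ratios), length(params),
                    dimnames = list(NULL, params))
    for (p in intersect(names(lod), params))
      flags[, p] <- vals[[p]] <= lod[[p]]
  }
  series <- do.call(dilution_series,
                    c(list(dilution = dilution, lod = flags), vals))
  conc <- vals[[biomass_param]]
  spectra <- list(); dil_of <- numeric(0)
  for (i in seq_along(ratios)) for (r in seq_len(n_replicates)) {
    spectra[[length(spectra) + 1L]] <-
      synth_spectrum(conc[i], spectra_cfg,
                     replicate_id = sprintf("d%g_r%d", dilution[i], r))
    dil_of <- c(dil_of, dilution[i])
  }
  blank <- spectrum(spectra_cfg$grid, rep(0, length(spectra_cfg$grid)),
                    replicate_id = "blank")
  list(series = series,
       set = spectra_set(spectra, dil_of, blank))
}

#' Configuration for synthetic counting-chamber scenes
#'
#' Dark, non-overlapping discs (cells) on a light background with a linear
#' illumination ramp and optional additive Gaussian pixel noise --
#' the ground-truth fixture for the counting pipeline. Intensities are on
#' the 0..1 scale. Default cell radii (mean 4 px, sd 1, truncated to
#' 2-6.5 px) give particle areas of roughly 12-130 px, inside the default
#' 6-150 px size filter; the cell depth 0.6 gives the strong brightfield
#' contrast of pigmented cells.
#'
#' @param width,height Image size in px.
#' @param n_cells Number of discs, \code{>= 0}.
#' @param radius_mean,radius_sd Disc radius distribution (px); radii are
#'   truncated to \code{radius_range}.
#' @param radius_range Truncation bounds for radii.
#' @param background Mean background intensity.
#' @param ramp_amplitude Peak-to-peak linear illumination ramp across the
#'   image diagonal.
#' @param cell_depth Intensity drop inside a cell.
#' @param noise_sd Additive Gaussian pixel noise sd.
#' @param margin Minimum distance of a disc centre from the border beyond
#'   its radius (px).
#' @param max_attempts Rejection-sampling attempts per disc before failing.
#' @return A list of class \code{"scene_config"}.
#' @export
scene_config <- function(width = 256, height = 256, n_cells = 50,
                         radius_mean = 4, radius_sd = 1,
                         radius_range = c(2, 6.5),
                         background = 0.85, ramp_amplitude = 0.15,
                         cell_depth = 0.6, noise_sd = 0,
                         margin = 2, max_attempts = 10000L) {
  if (n_cells < 0) stop("n_cells must be non-negative")
  if (radius_mean <= 0 || any(radius_range <= 0))
    stop("radii must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (cell_depth <= 0 || cell_depth > background - ramp_amplitude / 2)
    stop("cell_depth must be positive and keep cells darker than any background")
  structure(list(width = width, height = height, n_cells = n_cells,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 radius_range = radius_range, background = background,
                 ramp_amplitude = ramp_amplitude, cell_depth = cell_depth,
                 noise_sd = noise_sd, margin = margin,
                 max_attempts = max_attempts),
            class = "scene_config")
}

#' Generate a synthetic counting-chamber scene with ground truth
#'
#' Discs are placed by rejection sampling with non-overlap enforced by
#' construction (centre separation exceeds the radius sum plus 2 px);
#' placement failure after the attempt cap is an error.
#'
#' @param cfg A \code{\link{scene_config}}.
#' @param seed Optional integer seed (bit-reproducible scenes).
#' @return List with \code{image} (numeric matrix), \code{n_cells},
#'   \code{centroids} (matrix of disc centres, rows x cols) and
#'   \code{radii}.
#' @export
synth_scene <- function(cfg = scene_config(), seed = NULL) {
  stopifnot(inherits(cfg, "scene_config"))
  if (!is.null(seed)) set.seed(seed)
  nr <- cfg$height; nc <- cfg$width
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  diag_pos <- (rr / nr + cc / nc) / 2
  img <- cfg$background + cfg$ramp_amplitude * (diag_pos - 0.5)
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  for (i in seq_len(cfg$n_cells)) {
    placed <- FALSE
    for (attempt in seq_len(cfg$max_attempts)) {
      r <- min(max(stats::rnorm(1, cfg$radius_mean, cfg$radius_sd),
                   cfg$radius_range[1L]), cfg$radius_range[2L])
      lim <- r + cfg$margin
      y <- stats::runif(1, 1 + lim, nr - lim)
      x <- stats::runif(1, 1 + lim, nc - lim)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1L] - y)^2 + (centers[, 2L] - x)^2) >
                radii + r + 2)) {
        centers <- rbind(centers, c(y, x))
        radii <- c(radii, r)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("could not place disc %d without overlap in %d attempts",
                   i, cfg$max_attempts))
  }
  for (i in seq_along(radii)) {
    inside <- (rr - centers[i, 1L])^2 + (cc - centers[i, 2L])^2 <=
      radii[i]^2
    img[inside] <- img[inside] - cfg$cell_depth
  }
  if (cfg$noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, cfg$noise_sd), nr, nc)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, n_cells = cfg$n_cells,
       centroids = centers, radii = radii)
}
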