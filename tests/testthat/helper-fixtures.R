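# Shared fixtures built in code.

# the standard 1000-fold dilution ratio list of the reference series
paper_ratios <- c(1, 0.5, 0.2, 0.1, 0.05, 0.02, 0.01, 0.005, 0.002, 0.001)

flat_spectrum <- function(value, grid = 300:310, ...) {
  spectrum(grid, rep(value, length(grid)), ...)
}

random_spectrum <- function(grid = 300:310) {
  spectrum(grid, stats::runif(length(grid)))
}

write_spectrum_csv <- function(wl, ab, path = tempfile(fileext = ".csv"),
                               cols = c("wavelength_nm", "absorbance")) {
  df <- data.frame(wl, ab)
  names(df) <- cols
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# flat-profile generator: absorbance identical at every wavelength
flat_cfg <- function(A_max = 3.29, k = 0.0022, noise_sd = 0,
                     grid = seq(300, 1100, 1), ...) {
  spectrum_generator_config(
    peaks = data.frame(center = numeric(0), width = numeric(0),
                       height = numeric(0)),
    baseline = A_max, k0 = k, noise_sd = noise_sd, grid = grid, ...)
}

# generator with a wavelength-dependent absorption coefficient: chlorophyll
# bands plus the green-gap transmission window, over a mild red-ward decline
green_gap_cfg <- function(noise_sd = 0) {
  spectrum_generator_config(
    peaks = data.frame(center = numeric(0), width = numeric(0),
                       height = numeric(0)),
    baseline = 3.29, noise_sd = noise_sd,
    k_profile = function(wl)
      1 + 1.2 * exp(-0.5 * ((wl - 440) / 30)^2) +
        0.7 * exp(-0.5 * ((wl - 680) / 20)^2) -
        0.5 * exp(-0.5 * ((wl - 550) / 40)^2) +
        0.15 * (1100 - wl) / 800)
}

# flat image with dark discs at given centres; for constructed count tests
disc_image <- function(centers, radii, nr = 128, nc = 128,
                       background = 0.85, depth = 0.6) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  img <- matrix(background, nr, nc)
  for (i in seq_len(nrow(centers))) {
    inside <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radii[i]^2
    img[inside] <- img[inside] - depth
  }
  img
}
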