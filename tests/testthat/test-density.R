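test_that("the packaged reference series carries values and LOD flags", {
  s <- chlorella_series()
  expect_s3_class(s, "dilution_series")
  expect_equal(nrow(s), 10L)
  expect_equal(s$ratio, 1 / s$dilution)
  expect_equal(s$bmf[1], 770.0)
  expect_equal(s$cn[1], 108222.7)
  flags <- attr(s, "lod")
  expect_equal(sum(flags[, "bme"]), 3L)   # 200x, 500x, 1000x
  expect_equal(sum(flags[, "bmf"]), 1L)   # 1000x
  expect_equal(sum(flags[, "mg"]), 0L)    # kept despite suspicion
  expect_equal(nrow(series_values(s, "bme")), 7L)
  expect_equal(nrow(series_values(s, "bmf")), 9L)
  expect_equal(nrow(series_values(s, "mg")), 10L)
})

test_that("dilution series constructor validates its invariants", {
  expect_error(dilution_series(c(1, 1, 2), bme = c(1, 2, 3)), "unique")
  expect_error(dilution_series(c(0, 1), bme = c(1, 2)), "positive")
  expect_error(dilution_series(1:3, bme = c(-1, 2, 3)), "non-negative")
  s <- dilution_series(c(1, 2, 4), bme = c(8, 4, 2))
  expect_equal(s$ratio, c(1, 0.5, 0.25))
})

test_that("pairwise correlations pick the best trendline per pair", {
  s <- chlorella_series()
  cm <- pairwise_correlations(s)
  # a parameter against itself would be r2 = 1; nearest equivalent here:
  # proportional columns in a synthetic noiseless series
  sim <- synth_dilution_series(noise_sd = 0, seed = 1)
  cm0 <- pairwise_correlations(sim$series, families = "linear")
  off <- cm0$r2[upper.tri(cm0$r2)]
  expect_equal(off, rep(1, length(off)))

  # linear-family r2 is symmetric in the pair
  expect_equal(cm$r2["bmf", "chla"], cm$r2["chla", "bmf"])
  # filtration biomass and chlorophyll a: strongest pair, linear
  expect_equal(cm$family["bmf", "chla"], "linear")
  bmf <- series_values(s, "bmf"); chla <- series_values(s, "chla")
  m <- merge(bmf, chla, by = "dilution")
  expect_equal(cm$r2["bmf", "chla"], cor(m$value.x, m$value.y)^2)
  expect_equal(cm$n["bmf", "chla"], 9L)

  tiny <- dilution_series(c(1, 2, 5), bme = c(10, 5, NA),
                          mg = c(3, NA, 1))
  expect_error(pairwise_correlations(tiny, parameters = c("bme", "mg")),
               "fewer than 3 complete pairs")
})

test_that("trichromatic chlorophyll formula is linear with injected coefficients", {
  co <- list(c1 = 1, c2 = 0, factor = 1)
  expect_equal(felfoldy_chla(0, 0, 0, coeffs = co), 0)
  expect_equal(felfoldy_chla(0.1, 0.5, 0.3, coeffs = co), 0.4)
  # homogeneity of degree 1
  expect_equal(felfoldy_chla(0.2, 1.0, 0.6,
                             coeffs = list(c1 = 11.85, c2 = 1.54,
                                           factor = 2)),
               2 * felfoldy_chla(0.1, 0.5, 0.3,
                                 coeffs = list(c1 = 11.85, c2 = 1.54,
                                               factor = 2)))
  expect_error(felfoldy_chla(0, 0.5, 0.3), "coefficients")
  expect_error(felfoldy_chla(0, 0.5, 0.3, coeffs = list(c1 = 1)),
               "missing")
})

test_that("magnesium-to-chlorophyll conversion uses the molar mass ratio", {
  expect_identical(mg_chla_ratio(), 36.77)
  expect_equal(chla_from_mg(0), 0)
  expect_equal(chla_from_mg(27.6), 1015, tolerance = 1e-3)
  expect_error(chla_from_mg(-1), "non-negative")
  # homogeneity
  expect_equal(chla_from_mg(2 * 13.7), 2 * chla_from_mg(13.7))
})

test_that("composition ratios reproduce the reference derived cells", {
  expect_equal(mg_per_100g(27.6, 150), 18.40)
  expect_equal(mg_per_100g(204.5, 960), 21.31, tolerance = 0.01)
  expect_equal(mg_per_100g(0, 150), 0)
  expect_error(mg_per_100g(1, 0), "positive")
  # scale invariance of a ratio
  expect_equal(mg_per_100g(3 * 27.6, 3 * 150), mg_per_100g(27.6, 150))

  expect_equal(cell_weight(960, 108222.7), 8.871, tolerance = 2e-4)
  expect_equal(cell_weight(150, 34113.3), 4.397, tolerance = 1e-4)
  expect_equal(cell_weight(0, 100), 0)
  expect_error(cell_weight(1, 0), "positive")
})

test_that("derived summary aggregates the low-dilution rows", {
  ds <- summarize_derived(chlorella_series())
  expect_equal(nrow(ds$table), 4L)
  expect_equal(ds$table$dilution, c(1, 2, 5, 10))
  expect_equal(unname(ds$mg_per_100g["mean"]), 20.17, tolerance = 1e-3)
  expect_equal(unname(ds$cell_weight["mean"]), 6.359, tolerance = 1e-3)
  expect_gt(unname(ds$mg_per_100g["sd"]), 0)

  one <- dilution_series(1, bme = 960, mg = 204.5, cn = 108222.7)
  expect_warning(ds1 <- summarize_derived(one), "single included row")
  expect_equal(unname(ds1$cell_weight["sd"]), 0)

  no_mg <- dilution_series(c(1, 2, 5), bme = c(9, 5, 2),
                           cn = c(9, 5, 2))
  expect_error(summarize_derived(no_mg), "required column 'mg'")
})

test_that("series CSV round-trips values and LOD tokens", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("dilution,ratio,bme,mg",
               "1,1,960.0,204.5",
               "2,0.5,436.7,109.6",
               "5,0.2,<LOD,27.6",
               "10,0.1,,10.6"), p)
  s <- read_dilution_series(p)
  expect_equal(nrow(series_values(s, "bme")), 2L)
  expect_true(attr(s, "lod")[3, "bme"])
  expect_false(attr(s, "lod")[4, "bme"] && !is.na(s$bme[4]))
  expect_equal(nrow(series_values(s, "mg")), 4L)
})
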