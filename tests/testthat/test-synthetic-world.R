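test_that("covariate fields: determinism, zero-sill, unknown names", {
  cfg <- tiny_world_config()
  f1 <- generate_covariate_field(cfg, "annual_precipitation")
  f2 <- generate_covariate_field(cfg, "annual_precipitation")
  expect_identical(f1, f2)
  f3 <- generate_covariate_field(cfg, "gdp_per_capita")
  expect_false(identical(f1, f3))
  cfg0 <- tiny_world_config(covariate_fields = stats::setNames(
    rep(list(list(range = 3, sill = 0)), 9),
    c("annual_precipitation", "vegetation_productivity",
      "temperature_seasonality", "precipitation_seasonality",
      "elevation_range", "habitat_diversity", "population_density",
      "population_change", "gdp_per_capita")))
  expect_equal(generate_covariate_field(cfg0, "elevation_range"),
               rep(0, 12 * 8))
  expect_error(generate_covariate_field(cfg, "unknown_var"), "unknown")
})

test_that("covariate fields carry positive short-range autocorrelation", {
  grid <- build_grid(c(0, 40 * 192972.5, 0, 20 * 192972.5))
  cen <- grid_centroids(grid)
  w1 <- distance_band_neighbors(cen[, c("x", "y")], 200)  # lag-1 rook
  positive <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    f <- glottorisk:::sar_field(cen, range_cells = 5, sill = 1,
                                cell_m = grid$cell_size, seed = s)
    if (morans_i(f, w1, permutations = 0)$i_value > 0)
      positive <- positive + 1
  }
  expect_gte(positive, ceiling(0.95 * n_seeds))
})

test_that("language generation: counts, zero-variance ranges, location check", {
  cfg0 <- tiny_world_config(n_languages = 0L)
  expect_length(generate_languages(cfg0)$records, 0)
  ## sigma = 0: all realized areas equal up to one-cell discretization
  cfgc <- tiny_world_config(n_languages = 40L,
                            range_lognormal = c(mu = 4.8, sigma = 0))
  lg <- generate_languages(cfgc)
  cell_km2 <- 192.9725^2
  expect_lt(diff(range(lg$truth$realized_area_km2)), cell_km2 + 1e-6)
  ## location check at n = 500: sample mean of log10 area within 3 SE of mu
  cfg5 <- synthetic_config(seed = 23, n_languages = 500L, grid_cols = 40L,
                           grid_rows = 30L)
  lg5 <- generate_languages(cfg5)
  m <- mean(log10(lg5$truth$target_area_km2))
  se <- 1 / sqrt(500)          # sigma = 1 by default
  expect_lt(abs(m - 3), 3 * se)
  mp <- mean(log10(lg5$truth$population))
  expect_lt(abs(mp - 3.5), 3 * (1.2 / sqrt(500)) + 0.01)  # rounding slack
  ## unique ids, one record per language
  expect_equal(anyDuplicated(lg5$truth$language_id), 0)
})

test_that("speaker series: decline regime, zero-growth limit, absorbing zero", {
  ## below-threshold language with no noise: fitted rate equals the
  ## generating decline rate (the trajectory is noise-free by construction)
  s <- speaker_series("x", c(1950, 1970, 1990, 2005),
                      round(300 * exp(-0.03 * c(0, 20, 40, 55))))
  g <- fit_growth_rate(s)
  expect_equal(g$rate, -0.03, tolerance = 2e-3)  # rounding to integer counts
  ## exact counts: agreement to GLM tolerance
  s2 <- speaker_series("y", c(1950, 1975, 2000), c(800, 400, 200))
  expect_equal(fit_growth_rate(s2)$rate, log(0.5) / 25, tolerance = 1e-8)
  ## baseline 0, gdp effect 0, noise 0: expected counts constant
  cfg <- tiny_world_config(baseline_log_growth = 0, growth_sd = 0,
                           gdp_effect_on_growth = 0,
                           decline_regime = list(threshold_speakers = 1e-9,
                                                 decline_log_rate = -0.03,
                                                 sd = 0))
  lg <- generate_languages(cfg)
  ser <- generate_speaker_series(cfg, lg)
  expect_true(all(abs(ser$truth$r_true) < 1e-12))
  ## zero is absorbing in every generated series
  w <- generate_world(tiny_world_config(seed = 3, extinct_fraction = 0.5))
  for (s in w$series) {
    p <- s$records$population
    z <- which(p == 0)
    if (length(z)) expect_true(all(p[min(z):length(p)] == 0))
  }
})

test_that("mean fitted growth of healthy languages matches the baseline", {
  cfg <- synthetic_config(seed = 31, n_languages = 400L, grid_cols = 20L,
                          grid_rows = 15L, gdp_effect_on_growth = 0,
                          extinct_fraction = 0)
  w <- generate_world(cfg)
  comp <- compute_risk_components(w$records, w$series, w$grid)
  m <- merge(comp, w$truth, by = "language_id")
  above <- m[!m$declining & m$eligible & m$converged %in% TRUE, ]
  expect_gt(nrow(above), 200)
  se <- sd(above$rate) / sqrt(nrow(above))
  expect_lt(abs(mean(above$rate) - log(1.016)), 3 * se + 1e-3)
})

test_that("world assembly: determinism, ledger sufficiency, extinct points", {
  cfg <- tiny_world_config(seed = 4)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$covariates, w2$covariates)
  expect_identical(lapply(w1$series, `[[`, "records"),
                   lapply(w2$series, `[[`, "records"))
  ## ledger sufficiency: every language has truth fields used downstream
  expect_setequal(w1$truth$language_id,
                  vapply(w1$records, `[[`, character(1), "language_id"))
  expect_true(all(c("r_true", "declining", "extinct", "realized_area_km2",
                    "population") %in% names(w1$truth)))
  ## covariate table covers every cell
  expect_equal(nrow(w1$covariates), 12 * 8)
  ## extinct fraction zero: no extinct points
  w0 <- generate_world(tiny_world_config(seed = 5, extinct_fraction = 0))
  expect_equal(nrow(w0$extinct_points), 0)
  ## extinct points correspond exactly to the extinct ledger entries
  expect_setequal(w1$extinct_points$language_id,
                  w1$truth$language_id[w1$truth$extinct])
})

test_that("written worlds are byte-identical under identical config + seed", {
  cfg <- tiny_world_config(seed = 6)
  d1 <- file.path(tempdir(), "w1"); d2 <- file.path(tempdir(), "w2")
  write_world(generate_world(cfg), d1)
  write_world(generate_world(cfg), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_setequal(f1, f2)
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("sar_truth mode attaches a recoverable spatial response", {
  cfg <- synthetic_config(seed = 8, grid_cols = 15L, grid_rows = 15L,
                          n_languages = 50L,
                          sar_truth = list(lambda = 0.5,
                                           beta = c("(Intercept)" = 0,
                                                    gdp_per_capita = -0.01),
                                           sigma2 = 1e-4, neighbor_km = 300))
  w <- generate_world(cfg)
  expect_length(w$sar_response, 15 * 15)
  cen <- grid_centroids(w$grid)
  wts <- distance_band_neighbors(cen[, c("x", "y")], 300)
  X <- cbind(1, w$covariates$gdp_per_capita)
  f <- fit_sar_error(w$sar_response, X, wts)
  expect_lt(abs(f$lambda - 0.5), 0.25)
  expect_lt(abs(f$beta[2] - (-0.01)), 0.005)
})
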