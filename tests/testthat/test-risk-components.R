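grid0 <- build_grid(c(-2e6, 2e6, -2e6, 2e6))

## helper: a square of given side (km) centred at projected (cx, cy),
## expressed in geographic coordinates
geo_square <- function(side_km, cx = 0, cy = 0) {
  h <- side_km * 1000 / 2
  xy <- cbind(c(cx - h, cx + h, cx + h, cx - h),
              c(cy - h, cy - h, cy + h, cy + h))
  ll <- behrmann_unproject(xy[, 1], xy[, 2])
  cbind(ll[, "lon"], ll[, "lat"])
}

test_that("range area: empty list, exact square, union of overlapping parts", {
  expect_equal(language_range_area(language_record("a", list()), grid0), 0)
  sq <- language_record("b", list(geo_square(10)))
  expect_equal(language_range_area(sq, grid0), 100, tolerance = 1e-9)
  ## two disjoint ~50 km2 squares sum; two coincident ones union to 50
  s50a <- geo_square(sqrt(50), cx = -5e5)
  s50b <- geo_square(sqrt(50), cx = 5e5)
  expect_equal(language_range_area(language_record("c", list(s50a, s50b)),
                                   grid0), 100, tolerance = 1e-9)
  expect_equal(language_range_area(language_record("d", list(s50a, s50a)),
                                   grid0), 50, tolerance = 1e-9)
  ## partial overlap, cross-checked against a rasterized area count
  sa <- geo_square(10, cx = 0)
  sb <- geo_square(10, cx = 5000)   # overlaps half of sa
  rec <- language_record("e", list(sa, sb))
  got <- language_range_area(rec, grid0)
  rings <- glottorisk:::projected_rings(rec, grid0)
  pts <- expand.grid(x = seq(-5100, 10100, by = 100),
                     y = seq(-5100, 5100, by = 100))
  inside <- mapply(function(px, py)
    any(vapply(rings, function(r) point_in_ring(px, py, r), logical(1))),
    pts$x + 50, pts$y + 50)
  raster_km2 <- sum(inside) * 0.1 * 0.1
  expect_equal(got, 150, tolerance = 1e-6)
  expect_equal(got, raster_km2, tolerance = 0.02 * got)
})

test_that("series eligibility requires three records and a non-zero count", {
  expect_false(eligible_series(speaker_series("x", c(1950, 1980), c(100, 50))))
  expect_false(eligible_series(
    speaker_series("x", c(1950, 1970, 1990), c(0, 0, 0))))
  expect_true(eligible_series(
    speaker_series("x", c(1950, 1970, 1990), c(0, 5, 0))))
})

test_that("Poisson growth rate: constant and exact geometric series", {
  g0 <- fit_growth_rate(speaker_series("c", c(1960, 1980, 2000),
                                       c(100, 100, 100)))
  expect_equal(g0$rate, 0, tolerance = 1e-10)
  g2 <- fit_growth_rate(speaker_series("d", c(1950, 1975, 2000),
                                       c(100, 200, 400)))
  expect_equal(g2$rate, log(2) / 25, tolerance = 1e-8)
  expect_equal(g2$initial_population, 100)
  expect_equal(g2$oldest_year, 1950)
})

test_that("growth rate agrees with an independent IRLS oracle", {
  yrs <- c(1950, 1980, 2005)
  cnt <- c(1000, 500, 120)
  g <- fit_growth_rate(speaker_series("e", yrs, cnt))
  oracle <- irls_poisson(cnt, yrs - mean(range(yrs)))
  expect_equal(g$rate, oracle[2], tolerance = 1e-8)
  set.seed(42)
  for (i in 1:10) {
    yrs <- sort(sample(1949:2005, 5))
    cnt <- rpois(5, 300 * exp(0.01 * (yrs - yrs[1])))
    g <- fit_growth_rate(speaker_series("f", yrs, cnt))
    expect_equal(g$rate, irls_poisson(cnt, yrs - mean(range(yrs)))[2],
                 tolerance = 1e-8)
  }
})

test_that("growth slope is invariant to year shifts and count scaling", {
  yrs <- c(1955, 1970, 1990, 2002)
  cnt <- c(800, 640, 410, 300)
  r1 <- fit_growth_rate(speaker_series("g", yrs, cnt))$rate
  r2 <- fit_growth_rate(speaker_series("g", yrs + 500, cnt))$rate
  expect_equal(r1, r2, tolerance = 1e-9)
  ## exact geometric data: scaling counts shifts the intercept only
  r3 <- fit_growth_rate(speaker_series("h", c(1950, 1975, 2000),
                                       c(100, 200, 400)))$rate
  r4 <- fit_growth_rate(speaker_series("h", c(1950, 1975, 2000),
                                       c(300, 600, 1200)))$rate
  expect_equal(r3, r4, tolerance = 1e-9)
})

test_that("survey-timing bias check matches brute-force Kendall tau", {
  b1 <- growth_rate_survey_bias(data.frame(rate = c(-0.01, 0, 0.01),
                                           oldest_year = c(1950, 1960, 1970)))
  expect_equal(b1$tau, 1)
  b2 <- growth_rate_survey_bias(data.frame(rate = c(0.01, 0, -0.01),
                                           oldest_year = c(1950, 1960, 1970)))
  expect_equal(b2$tau, -1)
  ## tie case against explicit pair counting
  r <- c(0.02, 0.01, 0.01, -0.03)
  y <- c(1950, 1950, 1970, 1990)
  b3 <- growth_rate_survey_bias(data.frame(rate = r, oldest_year = y))
  expect_equal(b3$tau, kendall_tau_brute(r, y), tolerance = 1e-12)
  ## property: tau-b equals pair enumeration on random small instances
  set.seed(7)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    r <- round(rnorm(n), 2)
    y <- sample(seq(1950, 1990, 10), n, replace = TRUE)
    if (length(unique(y)) < 2 || length(unique(r)) < 2) next
    got <- growth_rate_survey_bias(data.frame(rate = r, oldest_year = y))
    expect_equal(got$tau, kendall_tau_brute(r, y), tolerance = 1e-12)
  }
  ## identical oldest years: undefined, flagged
  b4 <- growth_rate_survey_bias(data.frame(rate = c(1, 2, 3),
                                           oldest_year = c(1950, 1950, 1950)))
  expect_false(b4$defined)
})

test_that("transmission scores map labels and reject unknowns", {
  expect_identical(transmission_score("severely endangered"), 3L)
  expect_identical(transmission_score("safe/other"), 0L)
  expect_identical(transmission_score("critically_endangered"), 4L)
  expect_identical(transmission_score(NA), NA_integer_)
  expect_error(transmission_score("moribund"), "unknown")
})

test_that("component table applies eligibility and flags non-convergence", {
  cfg <- tiny_world_config()
  w <- generate_world(cfg)
  comp <- compute_risk_components(w$records, w$series, w$grid)
  expect_equal(nrow(comp), length(w$records))
  expect_true(all(comp$area_km2 >= 0))
  ## ineligible or non-converged languages carry NA rates
  expect_true(all(is.na(comp$rate[!comp$eligible])))
  expect_true(all(!is.na(comp$rate[comp$eligible & comp$converged %in% TRUE])))
  ## initial population is the count at the oldest survey year
  s1 <- w$series[[1]]
  row <- comp[comp$language_id == s1$language_id, ]
  if (row$eligible)
    expect_equal(row$initial_population, s1$records$population[1])
})
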