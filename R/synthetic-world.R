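.covariate_names <- c("annual_precipitation", "vegetation_productivity",
                      "temperature_seasonality", "precipitation_seasonality",
                      "elevation_range", "habitat_diversity",
                      "population_density", "population_change",
                      "gdp_per_capita")

#' Configuration of the synthetic language world
#'
#' The generator emulates the structure of a global language-range /
#' speaker-survey dataset: lognormal range-size and population-size
#' distributions, a speaker growth-rate distribution centred near the
#' global human population growth ratio (1.016 per year) with a long left
#' tail produced by a decline regime below a minimum-viable-population
#' threshold, spatially autocorrelated environmental/socioeconomic
#' covariate fields on an equal-area grid, and irregular survey series
#' (3-8 records per language between 1949 and 2005).
#'
#' @param seed integer seed; identical config + seed yields an identical
#'   world.
#' @param grid_cols,grid_rows grid dimensions in cells.
#' @param cell_km cell side in km (default 192.9725).
#' @param n_languages number of languages.
#' @param range_lognormal `c(mu, sigma)` of log10 range size (km^2).
#' @param pop_lognormal `c(mu, sigma)` of log10 speaker population.
#' @param range_pop_coupling `NULL`, or a list
#'   `(threshold, base_log10_area, slope_below, slope_above, sd)` giving a
#'   continuous two-segment dependence of log10 range on log10 population
#'   around the log10 of `threshold` (makes the range-population
#'   breakpoint recoverable); when supplied it replaces `range_lognormal`.
#' @param baseline_log_growth per-year log-scale growth of healthy
#'   languages (default `log(1.016)`).
#' @param growth_sd between-language SD of the healthy growth rate.
#' @param gdp_effect_on_growth shift in expected growth per standard
#'   deviation of the cell GDP covariate (negative: declines concentrate
#'   in high-GDP cells).
#' @param decline_regime list `(threshold_speakers, decline_log_rate, sd)`:
#'   languages whose initial population is below the threshold grow at
#'   `decline_log_rate` (default -0.03/yr, threshold 334 speakers).
#' @param covariate_fields named list per covariate with elements `range`
#'   (autocorrelation range, in cells) and `sill` (marginal variance).
#' @param sar_truth `NULL`, or list `(lambda, beta, sigma2)` with `beta` a
#'   named vector over covariates (plus `"(Intercept)"`): attaches a
#'   per-cell response with known SAR-error structure for
#'   regression-recovery checks.
#' @param survey_years list `(min_n, max_n, span)`.
#' @param extinct_fraction fraction of decline-regime languages whose
#'   series is driven to zero speakers (extinction is absorbing).
#' @param water_fraction approximate fraction of cells with land fraction
#'   below 0.5 (excluded from analyses, emulating ocean cells).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             grid_cols = 30L, grid_rows = 20L,
                             cell_km = 192.9725,
                             n_languages = 600L,
                             range_lognormal = c(mu = 3, sigma = 1),
                             pop_lognormal = c(mu = 3.5, sigma = 1.2),
                             range_pop_coupling = NULL,
                             baseline_log_growth = log(1.016),
                             growth_sd = 0.01,
                             gdp_effect_on_growth = -0.01,
                             decline_regime = list(threshold_speakers = 334,
                                                   decline_log_rate = -0.03,
                                                   sd = 0.01),
                             covariate_fields = NULL,
                             sar_truth = NULL,
                             survey_years = list(min_n = 3L, max_n = 8L,
                                                 span = c(1949L, 2005L)),
                             extinct_fraction = 0.12,
                             water_fraction = 0.1) {
  if (is.null(covariate_fields))
    covariate_fields <- stats::setNames(
      rep(list(list(range = 3, sill = 1)), length(.covariate_names)),
      .covariate_names)
  stopifnot(all(names(covariate_fields) %in% .covariate_names))
  if (any(vapply(covariate_fields, `[[`, numeric(1), "sill") < 0))
    stop("sill must be >= 0")
  stopifnot(range_lognormal[["sigma"]] >= 0, pop_lognormal[["sigma"]] >= 0,
            growth_sd >= 0, decline_regime$sd >= 0,
            decline_regime$threshold_speakers > 0,
            extinct_fraction >= 0, extinct_fraction < 1,
            survey_years$min_n >= 2, survey_years$max_n >= survey_years$min_n)
  structure(list(seed = as.integer(seed), grid_cols = as.integer(grid_cols),
                 grid_rows = as.integer(grid_rows), cell_km = cell_km,
                 n_languages = as.integer(n_languages),
                 range_lognormal = range_lognormal,
                 pop_lognormal = pop_lognormal,
                 range_pop_coupling = range_pop_coupling,
                 baseline_log_growth = baseline_log_growth,
                 growth_sd = growth_sd,
                 gdp_effect_on_growth = gdp_effect_on_growth,
                 decline_regime = decline_regime,
                 covariate_fields = covariate_fields,
                 sar_truth = sar_truth,
                 survey_years = survey_years,
                 extinct_fraction = extinct_fraction,
                 water_fraction = water_fraction),
            class = "synthetic_config")
}

## grid centred on the projected origin (equatorial band)
world_grid <- function(config) {
  cs <- config$cell_km * 1000
  build_grid(c(-config$grid_cols / 2 * cs, config$grid_cols / 2 * cs,
               -config$grid_rows / 2 * cs, config$grid_rows / 2 * cs),
             cell_size = cs)
}

#' Generate one spatially autocorrelated covariate field
#'
#' Fields are drawn from a SAR process on the grid: neighbours within the
#' configured autocorrelation range (in cells) are averaged with
#' autoregression 0.9 and the resulting field is rescaled to mean 0 and
#' variance `sill`. A zero sill yields a constant field. The per-variable
#' seed is derived from the config seed and the variable's position, so
#' fields are deterministic and mutually independent.
#'
#' @param config a [synthetic_config()].
#' @param variable_name one of the nine configured covariates.
#' @return numeric vector over cells (row-major from the lower-left cell).
#' @export
generate_covariate_field <- function(config, variable_name) {
  fld <- config$covariate_fields[[variable_name]]
  if (is.null(fld)) stop("unknown covariate: ", variable_name)
  grid <- world_grid(config)
  cen <- grid_centroids(grid)
  seed_off <- match(variable_name, names(config$covariate_fields))
  sar_field(cen, range_cells = fld$range, sill = fld$sill,
            cell_m = grid$cell_size,
            seed = config$seed * 131L + seed_off)
}

sar_field <- function(centroids, range_cells, sill, cell_m, seed, rho = 0.9) {
  n <- nrow(centroids)
  set.seed(seed)
  eps <- stats::rnorm(n)
  if (sill == 0) return(rep(0, n))
  if (range_cells > 0) {
    w <- distance_band_neighbors(centroids[, c("x", "y")],
                                 threshold_km = range_cells * cell_m / 1000)
    f <- as.numeric(Matrix::solve(Matrix::Diagonal(n) - rho * w$W, eps))
  } else f <- eps
  f <- f - mean(f)
  f * sqrt(sill) / stats::sd(f)
}

## greedy random blob of n_cells contiguous cells (rook adjacency)
grow_blob <- function(grid, seed_cell, target_cells) {
  nc <- grid$n_cols; nr <- grid$n_rows
  cells <- seed_cell
  frontier <- seed_cell
  neighbours <- function(id) {
    col <- ((id - 1L) %% nc) + 1L; row <- ((id - 1L) %/% nc) + 1L
    out <- c(if (col > 1) id - 1L, if (col < nc) id + 1L,
             if (row > 1) id - nc, if (row < nr) id + nc)
    out
  }
  while (length(cells) < target_cells) {
    cand <- setdiff(unique(unlist(lapply(cells, neighbours))), cells)
    if (!length(cand)) {
      warning("blob growth exhausted the grid; range capped")
      break
    }
    add <- if (length(cand) == 1) cand else sample(cand, 1)
    cells <- c(cells, add)
  }
  cells
}

## maximal per-row runs of a cell set, as axis-aligned rectangles (rings)
blob_rectangles <- function(grid, cells) {
  nc <- grid$n_cols
  col <- ((cells - 1L) %% nc) + 1L
  row <- ((cells - 1L) %/% nc) + 1L
  rects <- list()
  for (r in sort(unique(row))) {
    cs <- sort(col[row == r])
    runs <- split(cs, cumsum(c(1, diff(cs) != 1)))
    for (run in runs) {
      x0 <- grid$x0 + (min(run) - 1) * grid$cell_size
      x1 <- grid$x0 + max(run) * grid$cell_size
      y0 <- grid$y0 + (r - 1) * grid$cell_size
      y1 <- grid$y0 + r * grid$cell_size
      rects[[length(rects) + 1L]] <-
        cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
    }
  }
  rects
}

#' Generate language records
#'
#' Each language receives a speaker population (lognormal) and a range: a
#' contiguous blob of grid cells grown from a random seed cell when the
#' target area exceeds one cell, or a square placed inside the seed cell
#' for sub-cell ranges (so very small ranges, relevant to the IUCN D2
#' criterion, exist in the world). Range polygons are emitted in
#' geographic coordinates as the rectangles covering the blob, whose union
#' equals the blob exactly. Transmission status worsens stochastically
#' with decreasing population.
#'
#' @param config a [synthetic_config()].
#' @return list with `records` (list of [language_record()]s) and `truth`
#'   (data.frame: language_id, population, target_area_km2,
#'   realized_area_km2, seed_cell, n_cells).
#' @export
generate_languages <- function(config) {
  grid <- world_grid(config)
  n <- config$n_languages
  if (n == 0) return(list(records = list(),
                          truth = data.frame(language_id = character(0))))
  set.seed(config$seed * 1009L + 1L)
  cell_km2 <- (grid$cell_size / 1000)^2
  pop <- pmax(1, round(10^stats::rnorm(n, config$pop_lognormal[["mu"]],
                                       config$pop_lognormal[["sigma"]])))
  cp <- config$range_pop_coupling
  log10_area <- if (is.null(cp)) {
    stats::rnorm(n, config$range_lognormal[["mu"]],
                 config$range_lognormal[["sigma"]])
  } else {
    l <- log10(pop) - log10(cp$threshold)
    cp$base_log10_area + ifelse(l <= 0, cp$slope_below * l,
                                cp$slope_above * l) +
      stats::rnorm(n, 0, cp$sd)
  }
  area <- 10^log10_area
  seed_cell <- sample.int(n_cells(grid), n, replace = TRUE)
  ## transmission worsens as population shrinks
  latent <- (3 - log10(pop)) / 1.2 + stats::rnorm(n, 0, 0.7)
  score <- pmin(4L, pmax(0L, as.integer(round(latent))))
  status <- names(.transmission_levels)[score + 1L]
  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("lang%04d", i)
    if (area[i] < cell_km2) {
      b <- cell_bounds(grid, seed_cell[i])
      side <- sqrt(area[i] * 1e6)
      ox <- stats::runif(1, b["xmin"], b["xmax"] - side)
      oy <- stats::runif(1, b["ymin"], b["ymax"] - side)
      rings <- list(cbind(c(ox, ox + side, ox + side, ox),
                          c(oy, oy, oy + side, oy + side)))
      nc_i <- 0L
      realized <- area[i]
    } else {
      target <- min(round(area[i] / cell_km2), n_cells(grid))
      cells <- grow_blob(grid, seed_cell[i], target)
      rings <- blob_rectangles(grid, cells)
      nc_i <- length(cells)
      realized <- nc_i * cell_km2
    }
    ## rings to geographic coordinates
    geo <- lapply(rings, function(rg) {
      ll <- behrmann_unproject(rg[, 1], rg[, 2], grid$sphere_radius)
      cbind(ll[, "lon"], ll[, "lat"])
    })
    records[[i]] <- language_record(id, geo, population = pop[i],
                                    transmission_status = status[i])
    truth[[i]] <- data.frame(language_id = id, population = pop[i],
                             target_area_km2 = area[i],
                             realized_area_km2 = realized,
                             seed_cell = seed_cell[i], n_cells = nc_i)
  }
  list(records = records, truth = do.call(rbind, truth))
}

#' Generate speaker survey series
#'
#' Every language receives `k` survey years drawn uniformly from the span
#' (`k` uniform between `min_n` and `max_n`), and Poisson counts around
#' the exponential trajectory `N0 exp(r (t - t0))` where `N0` is the
#' language's population. The true rate `r` is the baseline growth plus
#' the GDP effect (standardized GDP of the language's seed cell) plus
#' noise, replaced by the decline rate when `N0` is below the
#' minimum-viable-population threshold. A configured fraction of declining
#' languages is driven extinct (their final survey records are zero), and
#' a zero count is absorbing.
#'
#' @param config a [synthetic_config()].
#' @param languages output of [generate_languages()].
#' @param gdp_z standardized per-cell GDP covariate (defaults to the
#'   configured GDP field).
#' @return list with `series` (list of [speaker_series()]) and `truth`
#'   (data.frame: language_id, r_true, declining, extinct, cell_id).
#' @export
generate_speaker_series <- function(config, languages, gdp_z = NULL) {
  stopifnot(length(languages$records) > 0)
  if (is.null(gdp_z)) {
    g <- generate_covariate_field(config, "gdp_per_capita")
    gdp_z <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else g * 0
  }
  set.seed(config$seed * 2003L + 2L)
  sv <- config$survey_years
  dr <- config$decline_regime
  tr <- languages$truth
  n <- nrow(tr)
  declining <- tr$population < dr$threshold_speakers
  extinct <- declining & stats::runif(n) < config$extinct_fraction
  r_true <- ifelse(declining,
                   dr$decline_log_rate + stats::rnorm(n, 0, dr$sd),
                   config$baseline_log_growth +
                     config$gdp_effect_on_growth * gdp_z[tr$seed_cell] +
                     stats::rnorm(n, 0, config$growth_sd))
  series <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(seq(sv$min_n, sv$max_n), 1)
    years <- sort(sample(seq(sv$span[1], sv$span[2]), k))
    mu <- tr$population[i] * exp(r_true[i] * (years - years[1]))
    counts <- stats::rpois(k, mu)
    if (extinct[i]) counts[k] <- 0L
    ## extinction is absorbing: once zero, stays zero
    z <- which(counts == 0)
    if (length(z)) counts[seq(min(z), k)] <- 0L
    series[[i]] <- speaker_series(tr$language_id[i], years, counts)
  }
  list(series = series,
       truth = data.frame(language_id = tr$language_id, r_true = r_true,
                          declining = declining, extinct = extinct,
                          cell_id = tr$seed_cell))
}

#' Generate the full synthetic world
#'
#' Assembles grid, covariate fields (plus a spatially autocorrelated land
#' fraction), language records, speaker series, extinct-language points
#' (the range-blob seed-cell centre of each extinct language), an optional
#' SAR-error response with known coefficients, and the ground-truth ledger
#' containing every generated parameter.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_world`: `config`, `grid`, `records`,
#'   `series`, `covariates` (per-cell data.frame with `land_fraction`),
#'   `extinct_points`, `sar_response` (or `NULL`), `truth` (per-language
#'   ledger).
#' @export
generate_world <- function(config) {
  grid <- world_grid(config)
  cen <- grid_centroids(grid)
  cov <- data.frame(cell_id = cen$cell_id)
  for (nm in names(config$covariate_fields))
    cov[[nm]] <- generate_covariate_field(config, nm)
  ## land fraction: autocorrelated field pushed towards 1, with about
  ## `water_fraction` of cells below 0.5
  lf <- sar_field(cen, range_cells = 4, sill = 1, cell_m = grid$cell_size,
                  seed = config$seed * 131L + 100L)
  cut <- stats::quantile(lf, config$water_fraction)
  cov$land_fraction <- pmin(1, pmax(0, 0.75 + 0.35 * (lf - cut)))
  langs <- generate_languages(config)
  g <- cov$gdp_per_capita
  gdp_z <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else g * 0
  ser <- generate_speaker_series(config, langs, gdp_z)
  truth <- merge(langs$truth, ser$truth[c("language_id", "r_true",
                                          "declining", "extinct")],
                 by = "language_id")
  ## extinct points at the seed-cell centre of extinct languages
  ext <- truth[truth$extinct, , drop = FALSE]
  if (nrow(ext)) {
    ll <- behrmann_unproject(cen$x[ext$seed_cell], cen$y[ext$seed_cell],
                             grid$sphere_radius)
    extinct_points <- data.frame(language_id = ext$language_id,
                                 lon = ll[, "lon"], lat = ll[, "lat"])
  } else {
    extinct_points <- data.frame(language_id = character(0),
                                 lon = numeric(0), lat = numeric(0))
  }
  sar_response <- NULL
  if (!is.null(config$sar_truth)) {
    st <- config$sar_truth
    vars <- setdiff(names(st$beta), "(Intercept)")
    X <- cbind("(Intercept)" = rep(1, nrow(cov)),
               as.matrix(cov[vars]))
    w <- distance_band_neighbors(cen[, c("x", "y")],
                                 threshold_km = st$neighbor_km %||% 300)
    sar_response <- simulate_sar(X, st$beta[c("(Intercept)", vars)],
                                 st$lambda, st$sigma2, w,
                                 seed = config$seed * 4001L + 3L)
  }
  structure(list(config = config, grid = grid, records = langs$records,
                 series = ser$series, covariates = cov,
                 extinct_points = extinct_points,
                 sar_response = sar_response, truth = truth),
            class = "synthetic_world")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d languages on a %d x %d grid (%d extinct)\n",
              length(x$records), x$config$grid_cols, x$config$grid_rows,
              sum(x$truth$extinct)))
  invisible(x)
}
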