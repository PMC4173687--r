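#' Construct a language record
#'
#' @param language_id unique identifier.
#' @param polygons list of polygon rings, each a two-column matrix of
#'   `(lon, lat)` vertices (unclosed). A language range may consist of
#'   several rings; overlapping rings are unioned before area computation.
#' @param population latest total mother-tongue speaker estimate
#'   (nonnegative integer), or `NA`.
#' @param transmission_status one of `"safe/other"`, `"vulnerable"`,
#'   `"definitely_endangered"`, `"severely_endangered"`,
#'   `"critically_endangered"`, or `NA`.
#' @param name optional display name.
#' @return an object of class `language_record`.
#' @export
language_record <- function(language_id, polygons = list(), population = NA,
                            transmission_status = NA_character_,
                            name = language_id) {
  if (!is.na(population) && population < 0) stop("population must be >= 0")
  structure(list(language_id = as.character(language_id),
                 polygons = polygons, population = population,
                 transmission_status = transmission_status, name = name),
            class = "language_record")
}

#' Range size of a language
#'
#' The range size is the total area (km^2) of all range polygons of the
#' language, measured in the grid's equal-area projection; overlapping
#' polygons are unioned first so shared area is not double-counted.
#'
#' @param record a [language_record()].
#' @param grid a `grid_spec` providing the projection authority.
#' @return area in km^2 (0 for an empty polygon list).
#' @export
language_range_area <- function(record, grid) {
  rings <- projected_rings(record, grid)
  rings_union_area(rings) / 1e6
}

#' Speaker survey series
#'
#' @param language_id identifier.
#' @param year integer survey years (strictly increasing after sorting;
#'   duplicated years are an error).
#' @param population nonnegative speaker counts.
#' @return object of class `speaker_series` with a `records` data.frame.
#' @export
speaker_series <- function(language_id, year, population) {
  stopifnot(length(year) == length(population), length(year) >= 1)
  if (anyDuplicated(year)) stop("duplicated survey year for ", language_id)
  if (any(population < 0, na.rm = TRUE)) stop("negative population")
  o <- order(year)
  structure(list(language_id = as.character(language_id),
                 records = data.frame(year = as.integer(year[o]),
                                      population = population[o])),
            class = "speaker_series")
}

#' Eligibility filter for growth-rate estimation
#'
#' A series is eligible when it has at least three records of speaker
#' population size, including at least one non-zero record.
#'
#' @param series a [speaker_series()].
#' @return logical.
#' @export
eligible_series <- function(series) {
  r <- series$records
  nrow(r) >= 3 && any(r$population > 0)
}

#' Speaker growth rate from a survey series
#'
#' Fits a generalized linear model (Poisson distribution, log link) with
#' speaker count as response and survey year as the single explanatory
#' variable. The year coefficient is the per-year log-scale speaker growth
#' rate r; `exp(r)` is the annual growth ratio comparable with the printed
#' global human growth rate of 1.016. Years are centred at the series
#' midpoint for numerical stability, which leaves the slope unchanged.
#'
#' @param series an eligible [speaker_series()].
#' @return object of class `growth_estimate`: `language_id`, `rate`, `se`,
#'   `n_records`, `oldest_year`, `initial_population` (count at the oldest
#'   survey year), `converged`.
#' @export
fit_growth_rate <- function(series) {
  if (!eligible_series(series))
    stop("series not eligible (need >= 3 records, >= 1 non-zero): ",
         series$language_id)
  r <- series$records
  yc <- r$year - mean(range(r$year))
  converged <- TRUE
  fit <- withCallingHandlers(
    stats::glm(r$population ~ yc, family = stats::poisson(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) converged <- FALSE
  structure(list(language_id = series$language_id,
                 rate = unname(stats::coef(fit)[2]),
                 se = unname(sqrt(diag(stats::vcov(fit)))[2]),
                 n_records = nrow(r),
                 oldest_year = r$year[1],
                 initial_population = r$population[1],
                 converged = converged),
            class = "growth_estimate")
}

#' Survey-timing bias check for growth rates
#'
#' When the oldest survey year is systematically later for declining
#' languages, using the count at the oldest year as "initial population"
#' would be circular. This check computes the tie-corrected Kendall rank
#' correlation (tau-b) between the estimated growth rates and the oldest
#' survey years, with a two-sided p-value.
#'
#' @param estimates list of `growth_estimate` objects (or a data.frame with
#'   columns `rate` and `oldest_year`).
#' @return list with `tau`, `p_value`, `n`, and `defined` (`FALSE` when all
#'   oldest years are identical, leaving tau undefined).
#' @export
growth_rate_survey_bias <- function(estimates) {
  d <- if (is.data.frame(estimates)) estimates
       else data.frame(rate = vapply(estimates, `[[`, numeric(1), "rate"),
                       oldest_year = vapply(estimates, `[[`, numeric(1),
                                            "oldest_year"))
  if (nrow(d) < 2) stop("need at least two estimates")
  if (length(unique(d$oldest_year)) < 2 || length(unique(d$rate)) < 2)
    return(list(tau = NA_real_, p_value = NA_real_, n = nrow(d),
                defined = FALSE))
  tau <- stats::cor(d$rate, d$oldest_year, method = "kendall")
  ct <- suppressWarnings(
    stats::cor.test(d$rate, d$oldest_year, method = "kendall",
                    exact = FALSE))
  list(tau = unname(tau), p_value = unname(ct$p.value), n = nrow(d),
       defined = TRUE)
}

.transmission_levels <- c("safe/other" = 0L, "vulnerable" = 1L,
                          "definitely_endangered" = 2L,
                          "severely_endangered" = 3L,
                          "critically_endangered" = 4L)

#' Intergenerational transmission score
#'
#' Maps transmission status labels to the 0-4 risk score: vulnerable = 1,
#' definitely endangered = 2, severely endangered = 3, critically
#' endangered = 4 and all others = 0. A missing status yields `NA` (the
#' language is excluded from transmission analyses, not scored 0).
#'
#' @param status character vector of status labels (underscores or spaces).
#' @return integer vector of scores in 0-4, `NA` for missing status.
#' @export
transmission_score <- function(status) {
  s <- gsub(" ", "_", tolower(as.character(status)))
  out <- .transmission_levels[s]
  bad <- !is.na(s) & is.na(out)
  if (any(bad)) stop("unknown transmission status: ",
                     paste(unique(s[bad]), collapse = ", "))
  unname(out)
}

#' Per-language risk-component table
#'
#' Assembles the three risk components (range size, speaker population
#' size, speaker growth rate) and the transmission score for every
#' language, applying the eligibility filter to the survey series and
#' flagging non-converged growth fits.
#'
#' @param records list of [language_record()]s.
#' @param series list of [speaker_series()] (matched by `language_id`;
#'   languages without an eligible series get `NA` growth fields).
#' @param grid a `grid_spec` for area computation.
#' @return data.frame with one row per language: `language_id`, `area_km2`,
#'   `population`, `rate`, `se`, `n_records`, `oldest_year`,
#'   `initial_population`, `transmission_score`, `eligible`, `converged`.
#' @export
compute_risk_components <- function(records, series, grid) {
  ser_by_id <- stats::setNames(series,
    vapply(series, `[[`, character(1), "language_id"))
  rows <- lapply(records, function(rec) {
    out <- data.frame(language_id = rec$language_id,
                      area_km2 = language_range_area(rec, grid),
                      population = as.numeric(rec$population),
                      rate = NA_real_, se = NA_real_,
                      n_records = NA_integer_, oldest_year = NA_integer_,
                      initial_population = NA_real_,
                      transmission_score =
                        transmission_score(rec$transmission_status),
                      eligible = FALSE, converged = NA,
                      stringsAsFactors = FALSE)
    s <- ser_by_id[[rec$language_id]]
    if (!is.null(s) && eligible_series(s)) {
      g <- fit_growth_rate(s)
      out$eligible <- TRUE
      out$converged <- g$converged
      if (g$converged) {
        out$rate <- g$rate; out$se <- g$se
      }
      out$n_records <- g$n_records
      out$oldest_year <- g$oldest_year
      out$initial_population <- g$initial_population
    }
    out
  })
  do.call(rbind, rows)
}
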