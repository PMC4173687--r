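#' IUCN threshold configuration
#'
#' Default thresholds follow IUCN Red List criteria v3.1 as applied to
#' languages, with range size standing in for extent of occurrence and
#' speaker population for mature individuals. Population and range
#' thresholds are strict ("smaller than"): D2 VU < 20 km^2, D1 VU < 1000
#' speakers. A3 uses a strict "exceeded" rule on the fractional decline
#' over three generations (VU > 30%, EN > 50%, CR > 80%). B1 and C1 combine
#' the size thresholds with decline: B1 requires continuing decline
#' (growth rate < 0); C1 requires the category's decline rate over the
#' longer of the stated year window and the generation window (VU at least
#' 10% in 10 years or 3 generations, EN 20% in 5 years or 2 generations,
#' CR 25% in 3 years or 1 generation).
#'
#' @param generation_years generation length G in years (default 25).
#' @param a3_decline named decline fractions (strict lower bounds).
#' @param b1_range_km2,c1_population,d1_population named CR/EN/VU strict
#'   upper thresholds.
#' @param c1_decline named minimum decline fractions for C1.
#' @param c1_years,c1_generations the year/generation windows for C1.
#' @param d2_range_km2 VU range threshold (strict).
#' @return object of class `iucn_thresholds`.
#' @export
iucn_thresholds <- function(generation_years = 25,
                            a3_decline = c(CR = 0.80, EN = 0.50, VU = 0.30),
                            b1_range_km2 = c(CR = 100, EN = 5000, VU = 20000),
                            c1_population = c(CR = 250, EN = 2500, VU = 10000),
                            c1_decline = c(CR = 0.25, EN = 0.20, VU = 0.10),
                            c1_years = c(CR = 3, EN = 5, VU = 10),
                            c1_generations = c(CR = 1, EN = 2, VU = 3),
                            d1_population = c(CR = 50, EN = 250, VU = 1000),
                            d2_range_km2 = c(VU = 20)) {
  stopifnot(generation_years > 0)
  nested <- function(v) all(diff(v[c("CR", "EN", "VU")]) > 0)
  if (!nested(b1_range_km2) || !nested(c1_population) ||
      !nested(d1_population))
    stop("CR/EN/VU thresholds must be nested (CR < EN < VU)")
  if (!all(diff(a3_decline[c("VU", "EN", "CR")]) > 0))
    stop("A3 decline thresholds must increase VU < EN < CR")
  structure(list(generation_years = generation_years,
                 a3_decline = a3_decline, b1_range_km2 = b1_range_km2,
                 c1_population = c1_population, c1_decline = c1_decline,
                 c1_years = c1_years, c1_generations = c1_generations,
                 d1_population = d1_population, d2_range_km2 = d2_range_km2),
            class = "iucn_thresholds")
}

#' Fractional decline over three generations
#'
#' For a per-year log-scale growth rate `r < 0` the fraction of speakers
#' lost over three generations of `G` years is `1 - exp(3 G r)`; a
#' non-declining language loses nothing.
#'
#' @param rate per-year log-scale growth rate(s); `NA` gives `NA`.
#' @param generation_years generation length G (years).
#' @return fraction(s) in `[0, 1)`.
#' @export
decline_over_3gen <- function(rate, generation_years = 25) {
  if (generation_years <= 0) stop("generation length must be positive")
  ifelse(is.na(rate), NA_real_,
         ifelse(rate < 0, 1 - exp(3 * generation_years * rate), 0))
}

.category_rank <- c(not_threatened = 0L, VU = 1L, EN = 2L, CR = 3L)

#' Classify one language against the IUCN criteria
#'
#' Evaluates criteria D1 and D2 always (given population and range data),
#' and the decline-based criteria A3, B1 and C1 only when a growth
#' estimate exists. "Continuing decline" for B1 and C1 means a negative
#' growth rate. The assigned category is the most severe level triggered
#' by any criterion; a language lacking both range and population data is
#' data deficient.
#'
#' @param area_km2 range size in km^2 (`NA` when unknown).
#' @param population speaker population (`NA` when unknown).
#' @param rate per-year growth rate or `NA`.
#' @param thresholds an [iucn_thresholds()] object.
#' @return list: `category` (`"CR"`, `"EN"`, `"VU"`, `"not_threatened"`,
#'   `"data_deficient"`), `criteria_met` (e.g. `"A3:VU"`),
#'   `decline_3gen`.
#' @export
classify_language <- function(area_km2, population, rate = NA,
                              thresholds = iucn_thresholds()) {
  th <- thresholds
  if (!is.na(area_km2) && area_km2 < 0) stop("negative range area")
  if (!is.na(population) && population < 0) stop("negative population")
  if (is.na(area_km2) && is.na(population))
    return(list(category = "data_deficient", criteria_met = character(0),
                decline_3gen = decline_over_3gen(rate, th$generation_years)))
  G <- th$generation_years
  d3 <- decline_over_3gen(rate, G)
  met <- character(0)
  best <- 0L
  trigger <- function(criterion, level) {
    met <<- c(met, paste0(criterion, ":", level))
    best <<- max(best, .category_rank[[level]])
  }
  ## A3: decline strictly exceeding the level's fraction over 3 generations
  ## (tiny tolerance so an exactly-at-threshold decline is not "exceeded"
  ## through floating-point roundoff)
  if (!is.na(rate) && !is.na(d3)) {
    for (lev in c("CR", "EN", "VU"))
      if (d3 > th$a3_decline[[lev]] + 1e-9) { trigger("A3", lev); break }
  }
  ## B1: small range plus continuing decline
  if (!is.na(rate) && rate < 0 && !is.na(area_km2)) {
    for (lev in c("CR", "EN", "VU"))
      if (area_km2 < th$b1_range_km2[[lev]]) { trigger("B1", lev); break }
  }
  ## C1: small population plus the level's decline rate over the longer of
  ## the year window and the generation window
  if (!is.na(rate) && rate < 0 && !is.na(population)) {
    for (lev in c("CR", "EN", "VU")) {
      window <- max(th$c1_years[[lev]], th$c1_generations[[lev]] * G)
      dec <- 1 - exp(rate * window)
      if (population < th$c1_population[[lev]] &&
          dec >= th$c1_decline[[lev]] - 1e-9) { trigger("C1", lev); break }
    }
  }
  ## D1: very small population
  if (!is.na(population)) {
    for (lev in c("CR", "EN", "VU"))
      if (population < th$d1_population[[lev]]) { trigger("D1", lev); break }
  }
  ## D2: very small range
  if (!is.na(area_km2) && area_km2 < th$d2_range_km2[["VU"]])
    trigger("D2", "VU")
  category <- names(.category_rank)[match(best, .category_rank)]
  list(category = category, criteria_met = met, decline_3gen = d3)
}

#' Assess all languages
#'
#' @param components per-language table from [compute_risk_components()]
#'   (columns `language_id`, `area_km2`, `population`, `rate`).
#' @param thresholds an [iucn_thresholds()].
#' @return list with `assessments` (data.frame: language_id, category,
#'   criteria_met, decline_3gen, threatened) and `summary` (counts per
#'   category and per criterion, plus `n`, `n_threatened`,
#'   `prop_threatened`).
#' @export
assess_all <- function(components, thresholds = iucn_thresholds()) {
  stopifnot(nrow(components) > 0)
  res <- lapply(seq_len(nrow(components)), function(i) {
    cl <- classify_language(components$area_km2[i],
                            components$population[i],
                            components$rate[i], thresholds)
    data.frame(language_id = components$language_id[i],
               category = cl$category,
               criteria_met = paste(cl$criteria_met, collapse = ";"),
               decline_3gen = cl$decline_3gen,
               threatened = cl$category %in% c("CR", "EN", "VU"),
               stringsAsFactors = FALSE)
  })
  a <- do.call(rbind, res)
  crit <- c("A3", "B1", "C1", "D1", "D2")
  per_crit <- vapply(crit, function(cr)
    sum(grepl(paste0("\\b", cr, ":"), a$criteria_met)), integer(1))
  list(assessments = a,
       summary = list(n = nrow(a),
                      n_threatened = sum(a$threatened),
                      prop_threatened = mean(a$threatened),
                      by_category = table(a$category),
                      by_criterion = per_crit))
}

#' Per-cell threat and extinction maps
#'
#' For every grid cell: extant language richness, threatened richness
#' (overall and per criterion; a threatened language counts in every cell
#' its range overlaps), the count of extinct-language points falling in
#' the cell, the two proportions (threatened/extant, extinct/extant), and
#' the extinction-filter class from cutoffs on those proportions --
#' distinguishing cells with many threatened languages but few recorded
#' extinctions (of particular conservation concern) from cells where past
#' extinctions have already filtered out vulnerable languages.
#'
#' @param grid a `grid_spec`.
#' @param membership `(cell_id, language_id)` pairs.
#' @param assessments data.frame from [assess_all()]`$assessments`.
#' @param extinct_points data.frame with `lon`, `lat` of last-known
#'   locations of extinct languages (may be empty).
#' @param cutoffs length-2 numeric: thresholds on the threatened and
#'   extinct proportions (default 0.25, 0.25).
#' @return data.frame per cell: richness counts, `prop_threatened`,
#'   `prop_extinct`, `filter_class`, `undefined_extant` flag.
#' @export
threat_maps <- function(grid, membership, assessments, extinct_points = NULL,
                        cutoffs = c(0.25, 0.25)) {
  cen <- grid_centroids(grid)
  a <- assessments[match(membership$language_id, assessments$language_id), ]
  tab <- function(flag) {
    s <- split(flag, membership$cell_id)
    out <- rep(0L, nrow(cen))
    out[as.integer(names(s))] <- vapply(s, function(z) sum(z, na.rm = TRUE),
                                        integer(1))
    out
  }
  cen$extant_richness <- tab(rep(TRUE, nrow(membership)))
  cen$threatened_richness <- tab(a$threatened)
  for (cr in c("A3", "B1", "C1", "D1", "D2"))
    cen[[paste0("threatened_", cr)]] <-
      tab(grepl(paste0("\\b", cr, ":"), a$criteria_met))
  cen$extinct_richness <- 0L
  if (!is.null(extinct_points) && nrow(extinct_points)) {
    xy <- behrmann_project(extinct_points$lon, extinct_points$lat,
                           grid$sphere_radius)
    col <- 1L + floor((xy[, 1] - grid$x0) / grid$cell_size)
    row <- 1L + floor((xy[, 2] - grid$y0) / grid$cell_size)
    inside <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
    id <- (row[inside] - 1L) * grid$n_cols + col[inside]
    cnt <- table(id)
    cen$extinct_richness[as.integer(names(cnt))] <- as.integer(cnt)
  }
  cen$undefined_extant <- cen$extant_richness == 0 & cen$extinct_richness > 0
  cen$prop_threatened <- ifelse(cen$extant_richness > 0,
                                cen$threatened_richness / cen$extant_richness,
                                NA_real_)
  cen$prop_extinct <- ifelse(cen$extant_richness > 0,
                             cen$extinct_richness / cen$extant_richness,
                             NA_real_)
  ht <- cen$prop_threatened >= cutoffs[1]
  he <- cen$prop_extinct >= cutoffs[2]
  cen$filter_class <- ifelse(is.na(ht) | is.na(he), NA_character_,
    ifelse(ht & he, "high-both",
      ifelse(ht & !he, "high-threat-low-extinction",
        ifelse(!ht & he, "low-threat-high-extinction", "low-both"))))
  cen
}
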