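#' Write language ranges as GeoJSON
#'
#' Each language becomes one Feature with a MultiPolygon geometry (one
#' polygon per ring, no holes) and properties `language_id`, `name`,
#' `population`, `transmission_status`.
#'
#' @param records list of [language_record()]s.
#' @param path output file.
#' @export
write_ranges <- function(records, path) {
  feats <- lapply(records, function(rec) {
    polys <- lapply(rec$polygons, function(ring) {
      m <- as.matrix(ring)
      m <- rbind(m, m[1, ])          # close the ring
      list(lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2])))
    })
    list(type = "Feature",
         properties = list(language_id = rec$language_id, name = rec$name,
                           population = rec$population,
                           transmission_status = rec$transmission_status),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = FALSE)
  invisible(path)
}

#' Read language ranges from GeoJSON
#'
#' Accepts Polygon and MultiPolygon features; any other geometry type is
#' an error naming the offending feature. Holes (rings beyond the first of
#' a polygon) are not supported and rejected.
#'
#' @param path GeoJSON FeatureCollection file.
#' @return list of [language_record()]s.
#' @export
read_ranges <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stop("not a FeatureCollection")
  lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    pr <- f$properties
    geom <- f$geometry
    id <- pr$language_id %||% sprintf("feature%d", i)
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("feature ", i, " (", id, "): unsupported geometry type '",
           geom$type, "' in ranges"))
    poly <- lapply(rings, function(p) {
      if (length(p) > 1)
        stop("feature ", i, " (", id, "): polygon holes are not supported")
      m <- do.call(rbind, lapply(p[[1]], function(pt)
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
      ## drop the closing vertex
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), ]
      m
    })
    language_record(id, poly,
                    population = if (is.null(pr$population)) NA
                                 else as.numeric(pr$population),
                    transmission_status =
                      pr$transmission_status %||% NA_character_,
                    name = pr$name %||% id)
  })
}

#' Write / read speaker series CSV
#'
#' The on-disk format is a CSV with header `language_id,year,population`.
#' Reading validates the schema and rejects duplicated (language, year)
#' rows, naming the row.
#'
#' @param series list of [speaker_series()].
#' @param path CSV file.
#' @export
write_series <- function(series, path) {
  d <- do.call(rbind, lapply(series, function(s)
    data.frame(language_id = s$language_id, year = s$records$year,
               population = s$records$population)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @return `read_series`: list of [speaker_series()].
#' @export
read_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("language_id", "year", "population")
  if (!all(need %in% names(d)))
    stop("series CSV must have columns: ", paste(need, collapse = ", "))
  dup <- duplicated(d[c("language_id", "year")])
  if (any(dup))
    stop("duplicated (language, year) at row ", which(dup)[1] + 1L,
         " of ", path)
  lapply(split(d, d$language_id), function(s)
    speaker_series(s$language_id[1], s$year, s$population))
}

#' Write / read per-cell covariates CSV
#'
#' One row per cell keyed by `cell_id`, one column per covariate plus
#' `land_fraction`.
#'
#' @param covariates per-cell data.frame.
#' @param path CSV file.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(d)) stop("covariate CSV must have cell_id")
  d
}

#' Write / read extinct-language points (GeoJSON)
#'
#' @param points data.frame with `language_id`, `lon`, `lat`.
#' @param path GeoJSON file.
#' @export
write_extinct_points <- function(points, path) {
  feats <- lapply(seq_len(nrow(points)), function(i)
    list(type = "Feature",
         properties = list(language_id = points$language_id[i]),
         geometry = list(type = "Point",
                         coordinates = c(points$lon[i], points$lat[i]))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_extinct_points
#' @export
read_extinct_points <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(gj$features))
    return(data.frame(language_id = character(0), lon = numeric(0),
                      lat = numeric(0)))
  do.call(rbind, lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Point"))
      stop("extinct points must be Point features")
    data.frame(language_id = f$properties$language_id,
               lon = as.numeric(f$geometry$coordinates[[1]]),
               lat = as.numeric(f$geometry$coordinates[[2]]))
  }))
}

#' Write a synthetic world to a directory
#'
#' Emits `ranges.geojson`, `series.csv`, `covariates.csv`,
#' `extinct_points.geojson`, `truth.csv` (the ground-truth ledger) and
#' `world_config.json` (a structured echo of the generating
#' configuration, including the seed). Identical config and seed produce
#' byte-identical files.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ranges(world$records, file.path(dir, "ranges.geojson"))
  write_series(world$series, file.path(dir, "series.csv"))
  cov <- world$covariates
  if (!is.null(world$sar_response)) cov$sar_response <- world$sar_response
  write_covariates(cov, file.path(dir, "covariates.csv"))
  write_extinct_points(world$extinct_points,
                       file.path(dir, "extinct_points.geojson"))
  utils::write.csv(world$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- world$config
  cfg$range_pop_coupling <- cfg$range_pop_coupling %||% NA
  cfg$sar_truth <- if (is.null(cfg$sar_truth)) NA
                   else lapply(cfg$sar_truth, as.list)
  jsonlite::write_json(unclass(cfg), file.path(dir, "world_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
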