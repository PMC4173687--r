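#' Behrmann equal-area projection
#'
#' Forward projection onto the Behrmann equal-area cylindrical projection
#' (standard parallels at 30 degrees N/S) on an authalic sphere. Cells of a
#' grid built in this projection have identical true area, which makes
#' per-cell richness and median comparisons unit-consistent.
#'
#' @param lon,lat numeric vectors of geographic coordinates in degrees;
#'   `lon` in \[-180, 180\], `lat` in \[-90, 90\].
#' @param radius sphere radius in metres (default: authalic radius).
#' @return `behrmann_project`: a two-column matrix of projected `x`, `y` in
#'   metres. `behrmann_unproject`: a two-column matrix of `lon`, `lat`.
#' @examples
#' xy <- behrmann_project(c(0, 180), c(0, 0))
#' behrmann_unproject(xy[, 1], xy[, 2])
#' @export
behrmann_project <- function(lon, lat, radius = 6371007.181) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)))
    stop("non-finite coordinates")
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  k <- cos(30 * pi / 180)
  cbind(x = radius * (lon * pi / 180) * k,
        y = radius * sin(lat * pi / 180) / k)
}

#' @rdname behrmann_project
#' @param x,y projected coordinates in metres.
#' @export
behrmann_unproject <- function(x, y, radius = 6371007.181) {
  k <- cos(30 * pi / 180)
  s <- y * k / radius
  if (any(abs(s) > 1 + 1e-12)) stop("y outside projected extent")
  s <- pmin(1, pmax(-1, s))
  cbind(lon = (x / (radius * k)) * 180 / pi,
        lat = asin(s) * 180 / pi)
}

#' Build an equal-area analysis grid
#'
#' Tiles a projected rectangular extent with square cells of side
#' `cell_size` metres (default 192972.5 m, approximately 2 degrees at
#' 30 N/S on the Behrmann projection), anchored at the lower-left corner of
#' the extent. The number of columns/rows is the ceiling of extent over
#' cell size, so the grid always covers the extent.
#'
#' @param extent numeric vector `c(xmin, xmax, ymin, ymax)` in metres.
#' @param cell_size cell side in metres.
#' @param sphere_radius sphere radius used for geographic conversion.
#' @return an object of class `grid_spec`: cell size, origin, dimensions.
#'   Cells are numbered row-major from the lower-left cell
#'   (`cell_id = (row - 1) * n_cols + col`).
#' @export
build_grid <- function(extent, cell_size = 192972.5,
                       sphere_radius = 6371007.181) {
  stopifnot(length(extent) == 4, cell_size > 0)
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  if (w <= 0 || h <= 0) stop("degenerate extent")
  g <- structure(list(
    cell_size = cell_size,
    x0 = unname(extent[1]), y0 = unname(extent[3]),
    n_cols = as.integer(ceiling(w / cell_size - 1e-9)),
    n_rows = as.integer(ceiling(h / cell_size - 1e-9)),
    sphere_radius = sphere_radius), class = "grid_spec")
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Equal-area grid: %d cols x %d rows, cell %.1f km, origin (%.0f, %.0f) m\n",
              x$n_cols, x$n_rows, x$cell_size / 1000, x$x0, x$y0))
  invisible(x)
}

n_cells <- function(grid) grid$n_cols * grid$n_rows

#' Cell centroids of a grid
#'
#' @param grid a `grid_spec`.
#' @param geographic if `TRUE` also return unprojected lon/lat centroids.
#' @return data.frame with `cell_id`, `col`, `row`, `x`, `y` (and `lon`,
#'   `lat` when requested).
#' @export
grid_centroids <- function(grid, geographic = FALSE) {
  stopifnot(inherits(grid, "grid_spec"))
  id <- seq_len(n_cells(grid))
  col <- ((id - 1L) %% grid$n_cols) + 1L
  row <- ((id - 1L) %/% grid$n_cols) + 1L
  out <- data.frame(cell_id = id, col = col, row = row,
                    x = grid$x0 + (col - 0.5) * grid$cell_size,
                    y = grid$y0 + (row - 0.5) * grid$cell_size)
  if (geographic) {
    ll <- behrmann_unproject(out$x, out$y, grid$sphere_radius)
    out$lon <- ll[, "lon"]; out$lat <- ll[, "lat"]
  }
  out
}

cell_bounds <- function(grid, cell_id) {
  col <- ((cell_id - 1L) %% grid$n_cols)
  row <- ((cell_id - 1L) %/% grid$n_cols)
  c(xmin = grid$x0 + col * grid$cell_size,
    xmax = grid$x0 + (col + 1) * grid$cell_size,
    ymin = grid$y0 + row * grid$cell_size,
    ymax = grid$y0 + (row + 1) * grid$cell_size)
}

## ---- polygon primitives (projected coordinates) -------------------------

## signed shoelace area of a ring given as a 2-column matrix (not closed)
ring_area <- function(ring) {
  n <- nrow(ring)
  if (is.null(n) || n < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

## Sutherland-Hodgman clip of a ring against an axis-aligned rectangle.
## Returns the clipped ring (possibly with 0 rows).
clip_ring_rect <- function(ring, rect) {
  clip_edge <- function(poly, keep, cross) {
    n <- nrow(poly)
    if (n == 0) return(poly)
    out <- vector("list", 2L * n)
    m <- 0L
    prev <- poly[n, ]
    prev_in <- keep(prev)
    for (i in seq_len(n)) {
      cur <- poly[i, ]
      cur_in <- keep(cur)
      if (cur_in) {
        if (!prev_in) { m <- m + 1L; out[[m]] <- cross(prev, cur) }
        m <- m + 1L; out[[m]] <- cur
      } else if (prev_in) {
        m <- m + 1L; out[[m]] <- cross(prev, cur)
      }
      prev <- cur; prev_in <- cur_in
    }
    if (m == 0L) matrix(numeric(0), 0, 2) else do.call(rbind, out[seq_len(m)])
  }
  lerp <- function(p, q, t) p + t * (q - p)
  ring <- clip_edge(ring, function(p) p[1] >= rect["xmin"],
    function(p, q) lerp(p, q, (rect["xmin"] - p[1]) / (q[1] - p[1])))
  ring <- clip_edge(ring, function(p) p[1] <= rect["xmax"],
    function(p, q) lerp(p, q, (rect["xmax"] - p[1]) / (q[1] - p[1])))
  ring <- clip_edge(ring, function(p) p[2] >= rect["ymin"],
    function(p, q) lerp(p, q, (rect["ymin"] - p[2]) / (q[2] - p[2])))
  ring <- clip_edge(ring, function(p) p[2] <= rect["ymax"],
    function(p, q) lerp(p, q, (rect["ymax"] - p[2]) / (q[2] - p[2])))
  ring
}

## area of intersection between a ring and a rectangle
ring_rect_area <- function(ring, rect) ring_area(clip_ring_rect(ring, rect))

ring_bbox <- function(ring)
  c(xmin = min(ring[, 1]), xmax = max(ring[, 1]),
    ymin = min(ring[, 2]), ymax = max(ring[, 2]))

bbox_overlap <- function(a, b)
  a["xmin"] < b["xmax"] && b["xmin"] < a["xmax"] &&
  a["ymin"] < b["ymax"] && b["ymin"] < a["ymax"]

## Sutherland-Hodgman against a convex ring (counter-clockwise); used for
## inclusion-exclusion union areas of convex parts.
clip_ring_convex <- function(ring, clip) {
  n <- nrow(clip)
  ## force counter-clockwise orientation of the clip ring
  x <- clip[, 1]; y <- clip[, 2]
  j <- c(n, seq_len(n - 1L))
  if (sum(x[j] * y - x * y[j]) < 0) clip <- clip[n:1, , drop = FALSE]
  out <- ring
  for (i in seq_len(n)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]; b <- clip[if (i == n) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    inside <- function(p) ex * (p[2] - a[2]) - ey * (p[1] - a[1]) >= -1e-12
    cross <- function(p, q) {
      t <- (ex * (p[2] - a[2]) - ey * (p[1] - a[1])) /
           (ex * (p[2] - q[2]) - ey * (p[1] - q[1]))
      p + t * (q - p)
    }
    m <- nrow(out)
    res <- vector("list", 2L * m); k <- 0L
    prev <- out[m, ]; prev_in <- inside(prev)
    for (ii in seq_len(m)) {
      cur <- out[ii, ]; cur_in <- inside(cur)
      if (cur_in) {
        if (!prev_in) { k <- k + 1L; res[[k]] <- cross(prev, cur) }
        k <- k + 1L; res[[k]] <- cur
      } else if (prev_in) {
        k <- k + 1L; res[[k]] <- cross(prev, cur)
      }
      prev <- cur; prev_in <- cur_in
    }
    out <- if (k == 0L) matrix(numeric(0), 0, 2)
           else do.call(rbind, res[seq_len(k)])
  }
  out
}

## Union area of a list of convex rings via inclusion-exclusion with
## bbox pruning. Ranges produced by the synthetic world are disjoint
## axis-aligned rectangles, for which this reduces to a plain sum; the
## general path handles overlapping convex parts exactly.
rings_union_area <- function(rings) {
  rings <- Filter(function(r) nrow(r) >= 3, rings)
  m <- length(rings)
  if (m == 0) return(0)
  if (m == 1) return(ring_area(rings[[1]]))
  boxes <- lapply(rings, ring_bbox)
  total <- 0
  recurse <- function(start, current, depth) {
    for (i in start:m) {
      inter <- if (is.null(current)) rings[[i]]
               else clip_ring_convex(current, rings[[i]])
      a <- ring_area(inter)
      if (a <= 1e-9) next
      total <<- total + (if (depth %% 2L == 1L) a else -a)
      if (i < m) recurse(i + 1L, inter, depth + 1L)
    }
  }
  recurse(1L, NULL, 1L)
  total
}

#' Assign languages to grid cells by any-overlap membership
#'
#' A cell contains a language when the language's range polygon covers any
#' positive-area portion of the cell; mere boundary touching (zero-area
#' intersection) does not confer membership.
#'
#' @param grid a `grid_spec`.
#' @param records list of language records (see [language_record()]); their
#'   polygons must be in geographic coordinates and are projected here.
#' @return data.frame of `(cell_id, language_id)` membership pairs.
#' @export
assign_languages <- function(grid, records) {
  stopifnot(inherits(grid, "grid_spec"))
  cs <- grid$cell_size
  out_cell <- integer(0); out_lang <- character(0)
  for (rec in records) {
    rings <- projected_rings(rec, grid)
    cells <- integer(0)
    for (ring in rings) {
      bb <- ring_bbox(ring)
      c0 <- max(1L, 1L + floor((bb["xmin"] - grid$x0) / cs))
      c1 <- min(grid$n_cols, 1L + floor((bb["xmax"] - grid$x0) / cs + 1e-9))
      r0 <- max(1L, 1L + floor((bb["ymin"] - grid$y0) / cs))
      r1 <- min(grid$n_rows, 1L + floor((bb["ymax"] - grid$y0) / cs + 1e-9))
      if (c1 < c0 || r1 < r0) next
      for (rr in r0:r1) for (cc in c0:c1) {
        id <- (rr - 1L) * grid$n_cols + cc
        if (id %in% cells) next
        if (ring_rect_area(ring, cell_bounds(grid, id)) > 1e-6)
          cells <- c(cells, id)
      }
    }
    if (length(cells)) {
      out_cell <- c(out_cell, sort(cells))
      out_lang <- c(out_lang, rep(rec$language_id, length(cells)))
    }
  }
  data.frame(cell_id = out_cell, language_id = out_lang,
             stringsAsFactors = FALSE)
}

## project a record's lon/lat rings into grid coordinates
projected_rings <- function(record, grid) {
  lapply(record$polygons, function(p) {
    m <- as.matrix(p)
    if (ncol(m) != 2) stop("polygon ring must have two columns (lon, lat)")
    behrmann_project(m[, 1], m[, 2], grid$sphere_radius)
  })
}

#' Summarize risk components and covariates per grid cell
#'
#' Computes, for every cell, language richness and the median of each
#' per-language risk component over the languages overlapping the cell
#' (median of log10 range, median of log10 population, median growth rate,
#' median transmission score), together with covariate means and the land
#' fraction. Even member counts use the midpoint (mean-of-middle-two)
#' median convention. Cells with land fraction below `min_land` are flagged
#' for exclusion from analysis tables, as are cells with no member carrying
#' a given response.
#'
#' @param grid a `grid_spec`.
#' @param membership `(cell_id, language_id)` pairs from
#'   [assign_languages()].
#' @param components per-language table with columns `language_id`,
#'   `area_km2`, `population`, `rate`, `transmission_score` (any may carry
#'   `NA` for languages lacking that datum).
#' @param covariates per-cell data.frame keyed by `cell_id` with one column
#'   per covariate plus `land_fraction`.
#' @param min_land minimum land fraction for inclusion (default 0.5).
#' @return data.frame with one row per grid cell: medians, richness,
#'   covariate values and an `included_land` flag.
#' @export
summarize_cells <- function(grid, membership, components, covariates,
                            min_land = 0.5) {
  cen <- grid_centroids(grid, geographic = TRUE)
  idx <- split(membership$language_id, membership$cell_id)
  comp <- components[match(membership$language_id, components$language_id), ]
  med_by_cell <- function(v) {
    s <- split(v, membership$cell_id)
    out <- rep(NA_real_, nrow(cen))
    out[as.integer(names(s))] <-
      vapply(s, function(z) if (all(is.na(z))) NA_real_
             else stats::median(z, na.rm = TRUE), numeric(1))
    out
  }
  cen$language_richness <- 0L
  cen$language_richness[as.integer(names(idx))] <-
    vapply(idx, function(z) length(unique(z)), integer(1))
  cen$median_log10_range <-
    med_by_cell(ifelse(comp$area_km2 > 0, log10(comp$area_km2), NA_real_))
  cen$median_log10_population <-
    med_by_cell(ifelse(comp$population > 0, log10(comp$population), NA_real_))
  cen$median_growth_rate <- med_by_cell(comp$rate)
  cen$median_transmission_score <-
    med_by_cell(as.numeric(comp$transmission_score))
  cov <- covariates[match(cen$cell_id, covariates$cell_id), ]
  for (nm in setdiff(names(cov), "cell_id")) cen[[nm]] <- cov[[nm]]
  if (is.null(cen$land_fraction)) cen$land_fraction <- 1
  cen$included_land <- cen$land_fraction >= min_land
  cen
}

#' Extract the analysis table for one response
#'
#' Applies the cell-exclusion rules: cells with less than the minimum land
#' fraction, or lacking any language with data on the response, are dropped.
#'
#' @param summaries output of [summarize_cells()].
#' @param response name of the response column in `summaries`.
#' @return the filtered data.frame.
#' @export
analysis_cells <- function(summaries, response) {
  stopifnot(response %in% names(summaries))
  summaries[summaries$included_land & !is.na(summaries[[response]]), ,
            drop = FALSE]
}

#' Latitudinal band summaries
#'
#' Bands are the grid's rows (constant projected y, hence equal-area),
#' labelled by the central geographic latitude of the row. For each band the
#' median over included cell medians is taken per risk component, and band
#' land area is the summed land fraction times the cell area.
#'
#' @param grid a `grid_spec`.
#' @param summaries output of [summarize_cells()].
#' @return data.frame with one row per grid row: `band_lat`, medians of the
#'   four response medians, `land_area_km2`, `n_cells` included.
#' @export
latitudinal_bands <- function(grid, summaries) {
  rows <- split(summaries, summaries$row)
  cell_km2 <- (grid$cell_size / 1000)^2
  out <- lapply(rows, function(d) {
    inc <- d[d$included_land, , drop = FALSE]
    medoc <- function(v) if (all(is.na(v))) NA_real_
                         else stats::median(v, na.rm = TRUE)
    data.frame(
      row = d$row[1],
      band_lat = stats::median(d$lat),
      median_log10_range = medoc(inc$median_log10_range),
      median_log10_population = medoc(inc$median_log10_population),
      median_growth_rate = medoc(inc$median_growth_rate),
      median_transmission_score = medoc(inc$median_transmission_score),
      land_area_km2 = sum(d$land_fraction, na.rm = TRUE) * cell_km2,
      n_cells = nrow(inc))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$row), ]
}
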