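#' Pipeline configuration
#'
#' A single structured configuration for [run_pipeline()]. Input paths may
#' point at any export with the package's formats (GeoJSON ranges,
#' `language_id,year,population` series CSV, per-cell covariate CSV); when
#' the `simulate` stage runs, the paths are filled in from the generated
#' world automatically.
#'
#' @param out_dir output directory.
#' @param seed integer seed recorded in all outputs and used for every
#'   stochastic step.
#' @param synthetic a [synthetic_config()] for the `simulate` stage
#'   (its seed is overridden by `seed`).
#' @param paths named list of input files (`ranges`, `series`,
#'   `covariates`, `extinct_points`); optional when simulating.
#' @param grid list `(grid_cols, grid_rows, cell_km)`; defaults to the
#'   synthetic config's grid.
#' @param neighbor_km named list of candidate neighbourhood distances (km)
#'   per response.
#' @param variables candidate explanatory variables for driver inference
#'   (default: the nine covariates; language richness is added for the
#'   growth and transmission responses only, and never used for range or
#'   population size, whose richness could be a consequence rather than a
#'   driver).
#' @param thresholds an [iucn_thresholds()].
#' @param min_land minimum land fraction for cell inclusion.
#' @param screen_threshold absolute-correlation threshold for the
#'   collinearity screen.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            synthetic = synthetic_config(seed = seed),
                            paths = list(),
                            grid = NULL,
                            neighbor_km = list(
                              default = seq(250, 500, by = 50),
                              median_log10_range = c(seq(250, 500, 50), 1000, 2000),
                              median_log10_population = c(seq(250, 500, 50), 1000, 2000),
                              median_growth_rate = c(seq(250, 500, 50), 1000, 1500),
                              median_transmission_score = c(seq(250, 500, 50), 1000, 1500)),
                            variables = .covariate_names,
                            thresholds = iucn_thresholds(),
                            min_land = 0.5,
                            screen_threshold = 0.8) {
  synthetic$seed <- as.integer(seed)
  if (is.null(grid))
    grid <- list(grid_cols = synthetic$grid_cols,
                 grid_rows = synthetic$grid_rows,
                 cell_km = synthetic$cell_km)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, paths = paths, grid = grid,
                 neighbor_km = neighbor_km, variables = variables,
                 thresholds = thresholds, min_land = min_land,
                 screen_threshold = screen_threshold),
            class = "pipeline_config")
}

.pipeline_stages <- c("simulate", "components", "breakpoints", "grid",
                      "sar", "average", "assess", "report")

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order: `simulate`
#' (synthetic world), `components` (per-language risk components),
#' `breakpoints` (pairwise threshold analyses), `grid` (equal-area cell
#' summaries and latitudinal bands), `sar` (neighbourhood selection and
#' SAR error fits per response), `average` (collinearity screen and
#' multimodel averaging), `assess` (IUCN categorization), `report`
#' (run manifest). Each stage writes CSV/GeoJSON outputs under
#' `config$out_dir` and later stages read the in-memory state; a stage
#' whose upstream state is missing stops with a dependency message.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stage names (default: all).
#' @param state optionally, the state list returned by a previous call
#'   (to resume with additional stages).
#' @return invisibly, the state list; `state$manifest` holds the run
#'   manifest after `report`.
#' @export
run_pipeline <- function(config, stages = .pipeline_stages, state = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(state)) state <- list(counts = list())
  need <- function(what, from) {
    if (is.null(state[[what]]))
      stop("stage dependency missing: need '", what,
           "' (run stage '", from, "' first)")
    state[[what]]
  }
  out <- function(...) file.path(config$out_dir, ...)

  for (stage in stages) {
    message("[glottorisk] stage: ", stage)
    if (stage == "simulate") {
      world <- generate_world(config$synthetic)
      wd <- out("world")
      write_world(world, wd)
      config$paths <- list(ranges = file.path(wd, "ranges.geojson"),
                           series = file.path(wd, "series.csv"),
                           covariates = file.path(wd, "covariates.csv"),
                           extinct_points = file.path(wd, "extinct_points.geojson"))
      state$world <- world
      state$counts$n_languages <- length(world$records)
    }
    if (stage == "components") {
      for (p in c("ranges", "series", "covariates")) {
        if (is.null(config$paths[[p]]))
          stop("missing required input path: ", p)
        if (!file.exists(config$paths[[p]]))
          stop("input file does not exist: ", config$paths[[p]])
      }
      g <- config$grid
      cs <- g$cell_km * 1000
      state$grid <- build_grid(c(-g$grid_cols / 2 * cs, g$grid_cols / 2 * cs,
                                 -g$grid_rows / 2 * cs, g$grid_rows / 2 * cs),
                               cell_size = cs)
      state$records <- read_ranges(config$paths$ranges)
      state$series <- read_series(config$paths$series)
      state$covariates <- read_covariates(config$paths$covariates)
      state$extinct_points <-
        if (!is.null(config$paths$extinct_points) &&
            file.exists(config$paths$extinct_points))
          read_extinct_points(config$paths$extinct_points)
        else NULL
      comp <- compute_risk_components(state$records, state$series,
                                      state$grid)
      state$components <- comp
      state$counts$n_series <- length(state$series)
      state$counts$n_eligible <- sum(comp$eligible)
      state$counts$n_ineligible <- sum(!comp$eligible)
      bias <- tryCatch(
        growth_rate_survey_bias(comp[comp$eligible & comp$converged %in% TRUE,
                                     c("rate", "oldest_year")]),
        error = function(e) NULL)
      state$survey_bias <- bias
      utils::write.csv(comp, out("risk_components.csv"), row.names = FALSE)
    }
    if (stage == "breakpoints") {
      comp <- need("components", "components")
      state$breakpoints <- pairwise_threshold_analyses(comp)
      tabs <- lapply(names(state$breakpoints), function(nm) {
        b <- state$breakpoints[[nm]]
        cbind(analysis = nm, b$table,
              psi = b$psi %||% NA, ci_low = (b$psi_ci %||% c(NA, NA))[1],
              ci_high = (b$psi_ci %||% c(NA, NA))[2],
              psi_natural = b$psi_natural %||% NA)
      })
      utils::write.csv(do.call(rbind, tabs), out("breakpoints.csv"),
                       row.names = FALSE)
    }
    if (stage == "grid") {
      comp <- need("components", "components")
      grid <- need("grid", "components")
      state$membership <- assign_languages(grid, state$records)
      state$summaries <- summarize_cells(grid, state$membership, comp,
                                         state$covariates,
                                         min_land = config$min_land)
      state$bands <- latitudinal_bands(grid, state$summaries)
      state$counts$n_cells <- nrow(state$summaries)
      state$counts$n_cells_land <- sum(state$summaries$included_land)
      utils::write.csv(state$summaries, out("cell_summaries.csv"),
                       row.names = FALSE)
      utils::write.csv(state$bands, out("latitudinal_bands.csv"),
                       row.names = FALSE)
    }
    if (stage == "sar") {
      sm <- need("summaries", "grid")
      responses <- c("median_log10_range", "median_log10_population",
                     "median_growth_rate", "median_transmission_score")
      state$sar <- list()
      for (resp in responses) {
        cells <- analysis_cells(sm, resp)
        if (nrow(cells) < 30) next
        X <- cbind("(Intercept)" = 1, as.matrix(cells[config$variables]))
        cand <- config$neighbor_km[[resp]] %||% config$neighbor_km$default
        sel <- select_neighborhood(cells[[resp]], X,
                                   cells[c("x", "y")], cand)
        state$sar[[resp]] <- c(sel, list(cells = cells))
      }
      tab <- do.call(rbind, lapply(names(state$sar), function(r)
        cbind(response = r, state$sar[[r]]$aic_table)))
      utils::write.csv(tab, out("sar_neighborhoods.csv"), row.names = FALSE)
    }
    if (stage == "average") {
      sar <- need("sar", "sar")
      state$average <- list()
      for (resp in names(sar)) {
        cells <- sar[[resp]]$cells
        vars <- config$variables
        if (resp %in% c("median_growth_rate", "median_transmission_score") &&
            "language_richness" %in% names(cells))
          vars <- c(vars, "language_richness")
        scr <- collinearity_screen(cells[vars],
                                   priority = vars,
                                   threshold = config$screen_threshold)
        mm <- sar_multimodel(cells[[resp]], cells[scr$retained],
                             sar[[resp]]$weights, scr$retained)
        state$average[[resp]] <- list(screen = scr, multimodel = mm)
        utils::write.csv(cbind(response = resp, mm$averaged),
                         out(paste0("averaged_", resp, ".csv")),
                         row.names = FALSE)
      }
    }
    if (stage == "assess") {
      comp <- need("components", "components")
      state$assessment <- assess_all(comp, config$thresholds)
      utils::write.csv(state$assessment$assessments,
                       out("threat_assessments.csv"), row.names = FALSE)
      if (!is.null(state$membership)) {
        state$threat_cells <- threat_maps(state$grid, state$membership,
                                          state$assessment$assessments,
                                          state$extinct_points)
        utils::write.csv(state$threat_cells, out("threat_cells.csv"),
                         row.names = FALSE)
      }
      state$counts$n_threatened <- state$assessment$summary$n_threatened
    }
    if (stage == "report") {
      files <- list.files(config$out_dir, recursive = TRUE,
                          full.names = TRUE, pattern = "\\.(csv|geojson|json)$")
      files <- files[basename(files) != "manifest.json"]
      hashes <- tools::md5sum(files)
      manifest <- list(seed = config$seed,
                       package_version =
                         as.character(utils::packageVersion("glottorisk")),
                       counts = state$counts,
                       outputs = as.list(stats::setNames(unname(hashes),
                                                         basename(files))))
      jsonlite::write_json(manifest, out("manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      state$manifest <- manifest
    }
  }
  invisible(state)
}
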