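#' Default pipeline configuration
#'
#' Configuration for the end-to-end toy pipeline: synthetic scene generation,
#' land system construction, demand derivation, suitability fitting,
#' allocation and validation. Any subset of fields can be overridden; the
#' full resolved configuration is written into the run metadata so a run can
#' be reproduced exactly.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir output directory (`NULL` = no artifacts written).
#' @param scene list of [scene_spec()] arguments for the synthetic cover map.
#' @param window upscaling block size in fine cells.
#' @param transitions tibble of [generate_transition_pair()] rules applied to
#'   the fine cover map, or `NULL` for a default rule set.
#' @param suitability list: `target`, `num_trees`, `sample_fraction`,
#'   `balanced`, `max_b_ratio`.
#' @param allocation list passed to [allocation_config()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL,
                            scene = list(nrow = 120L, ncol = 120L, n_types = 6L,
                                         correlation_length = 3,
                                         cell_size = 30),
                            window = 4L,
                            transitions = NULL,
                            suitability = list(),
                            allocation = list()) {
  suit <- utils::modifyList(
    list(target = "loss", num_trees = 200L, sample_fraction = 0.25,
         balanced = FALSE, max_b_ratio = 10), suitability)
  structure(list(seed = as.integer(seed), out_dir = out_dir, scene = scene,
                 window = as.integer(window), transitions = transitions,
                 suitability = suit, allocation = allocation),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$transitions)) y$transitions <- dplyr::bind_rows(y$transitions)
  do.call(pipeline_config, y)
}

default_transitions <- function(n_types) {
  # a few cover-level transitions among the service types, driver-linked so
  # the suitability model has signal to learn
  tibble::tibble(
    from = c(1L, 2L, 0L),
    to = c(0L, 0L, 2L),
    driver = c("link_a", "link_a", "link_b"),
    n = NA_integer_  # filled as a share of the class at run time
  )
}

#' Run the full demand-driven simulation pipeline on a synthetic scene
#'
#' Executes the four-part workflow end to end with known ground truth:
#' (1) generate a synthetic cover map, drivers and a before/after pair under
#' transition rules; (2) build the land system maps and derive the historical
#' service demand and per-class supply capacities; (3) fit location
#' suitability for every observed conversion target and assemble the
#' allocation inputs (conversion matrix, resistance); (4) allocate from the y1
#' map to the demand and validate against the observed y2 map at 30- and
#' 10-class thematic resolution. All artifacts (rasters, tables, change log,
#' run metadata) are written to `config$out_dir` when set; re-running with an
#' identical configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param quiet suppress progress messages.
#' @return a `pipeline_result` list: inputs, fitted models, the
#'   `allocation_result`, the validation table and artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[tipland] ", ...)
  t0 <- Sys.time()

  # -- part 1: synthetic scene ----------------------------------------------
  say("part 1/4: synthetic scene")
  sc_args <- config$scene
  sc_args$seed <- config$seed
  spec <- do.call(scene_spec, sc_args)
  cover1 <- generate_landscape(spec)
  rules <- config$transitions %||% default_transitions(spec$n_types)
  drivers_fine <- generate_drivers(
    cover1,
    linked = tibble::tibble(driver = c("link_a", "link_b"),
                            type = c(1L, 0L), effect = c(2.5, 2.5)),
    seed = config$seed + 1L)
  if (any(is.na(rules$n))) {
    n1 <- vapply(rules$from, function(k) sum(cover1$values == k, na.rm = TRUE),
                 integer(1))
    rules$n <- ifelse(is.na(rules$n), pmax(1L, as.integer(0.15 * n1)), rules$n)
  }
  pair <- generate_transition_pair(cover1, rules, drivers_fine,
                                   seed = config$seed + 2L)
  cover2 <- pair$y2

  # -- part 2: land systems, demand, supply capacity ------------------------
  say("part 2/4: land systems and demand")
  b1 <- build_land_system(cover1, window = config$window)
  up2 <- upscale_dominant_type(cover2, window = config$window)
  ls2 <- classify_density(up2$type, up2$fraction, b1$breaks)  # shared legend
  ls1 <- b1$ls
  demand <- demand_from_landcover(cover2, basin = "toy", year = 2L)
  ca <- compute_supply_capacity(cover1, ls1)

  # -- part 3: suitability and conversion parameters ------------------------
  say("part 3/4: suitability and conversion parameters")
  M <- derive_conversion_matrix(ls1, ls2)
  resistance <- estimate_resistance(ls1, ls2)
  dens <- compute_density_drivers(ls1, cover1)
  cover_coarse <- merge_density(ls1)
  drivers_coarse <- generate_drivers(
    cover_coarse, n_smooth = 2L,
    linked = tibble::tibble(driver = c("link_a", "link_b"),
                            type = c(1L, 0L), effect = c(2.5, 2.5)),
    correlation_length = 2, seed = config$seed + 3L)
  stack <- driver_stack(c(unclass(drivers_coarse), unclass(dens)))
  targets <- sort(unique(c(which(M == 1L & row(M) != col(M), arr.ind = TRUE)[, 2L] - 1L)))
  models <- list()
  suit <- list()
  for (j in targets) {
    sm <- try(build_training_samples(ls1, ls2, stack, j,
                                     target = config$suitability$target),
              silent = TRUE)
    if (inherits(sm, "try-error")) next
    fit <- try(fit_suitability_model(
      sm, num_trees = config$suitability$num_trees,
      sample_fraction = config$suitability$sample_fraction,
      balanced = config$suitability$balanced,
      max_b_ratio = config$suitability$max_b_ratio,
      seed = config$seed + 10L + j), silent = TRUE)
    if (inherits(fit, "try-error")) {
      say("  class ", j, ": skipped (single-label samples)")
      next
    }
    models[[as.character(j)]] <- fit
    suit[[as.character(j)]] <- predict_suitability(fit, stack)
  }
  if (!length(suit)) stop("no suitability model could be fitted", call. = FALSE)

  # -- part 4: allocation and validation ------------------------------------
  say("part 4/4: allocation and validation")
  alloc_cfg <- do.call(allocation_config, config$allocation)
  result <- allocate(ls1, suit, demand, ca, M, resistance, alloc_cfg)
  validation <- dplyr::bind_rows(
    validate_maps(ls1, ls2, result$final, thematic = 30),
    validate_maps(ls1, ls2, result$final, thematic = 10)
  )
  say(sprintf("  %s; kappa_30 = %.3f, fom_30 = %.3f", result$message,
              validation$kappa[1], validation$fom[1]))

  paths <- NULL
  if (!is.null(config$out_dir)) {
    paths <- write_pipeline_artifacts(config, cover1, cover2, ls1, ls2, demand,
                                      ca, M, resistance, result, validation, t0)
  }
  structure(list(
    config = config, spec = spec, cover_y1 = cover1, cover_y2 = cover2,
    ls_y1 = ls1, ls_y2 = ls2, breaks = b1$breaks, demand = demand, ca = ca,
    conv_matrix = M, resistance = resistance, drivers = stack,
    models = models, suitability = suit, allocation = result,
    validation = validation, truth = pair$truth, paths = paths
  ), class = "pipeline_result")
}

write_pipeline_artifacts <- function(config, cover1, cover2, ls1, ls2, demand,
                                     ca, M, resistance, result, validation, t0) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  write_raster(cover1, p("cover_y1.asc"))
  write_raster(cover2, p("cover_y2.asc"))
  write_raster(ls1, p("ls_y1.asc"))
  write_raster(ls2, p("ls_y2.asc"))
  write_raster(result$final, p("ls_simulated.asc"))
  write_demand_table(demand, p("demand.csv"))
  readr::write_csv(ca, p("supply_capacity.csv"))
  utils::write.csv(M, p("conversion_matrix.csv"))
  readr::write_csv(resistance, p("resistance.csv"))
  readr::write_csv(result$changes, p("changes.csv"))
  readr::write_csv(validation, p("validation.csv"))
  meta <- list(
    package = "tipland",
    version = as.character(utils::packageVersion("tipland")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed,
    window = config$window,
    scene = config$scene,
    suitability = config$suitability,
    allocation = config$allocation,
    converged = result$converged,
    n_changes = nrow(result$changes)
  )
  jsonlite::write_json(meta, p("run_metadata.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  list.files(config$out_dir, full.names = TRUE)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  scene %dx%d fine cells, window %d -> %dx%d land system cells\n",
              x$spec$nrow, x$spec$ncol, x$config$window,
              nrow(x$ls_y1$values), ncol(x$ls_y1$values)))
  cat("  allocation:", x$allocation$message, "\n")
  print(x$validation)
  invisible(x)
}
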