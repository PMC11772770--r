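#' Scene specification for the synthetic landscape generator
#'
#' @param nrow,ncol grid dimensions (fine cells).
#' @param n_types number of cover types used (2-10; codes 0..n_types-1).
#' @param weights per-type target abundance weights (recycled/normalized);
#'   default equal shares.
#' @param correlation_length spatial correlation length in cells; 0 gives
#'   independent cells, larger values give larger coherent patches.
#' @param cell_size fine cell size in metres (default 30).
#' @param seed random seed.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(nrow, ncol, n_types = 10L, weights = NULL,
                       correlation_length = 0, cell_size = 30, seed = 1L) {
  n_types <- as.integer(n_types)
  stopifnot(nrow >= 1L, ncol >= 1L, n_types >= 2L, n_types <= 10L)
  if (is.null(weights)) weights <- rep(1, n_types)
  stopifnot(length(weights) == n_types, all(weights >= 0), sum(weights) > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 n_types = n_types, weights = weights / sum(weights),
                 correlation_length = correlation_length,
                 cell_size = cell_size, seed = as.integer(seed)),
            class = "scene_spec")
}

# moving-average smoothing of a white-noise field; the kernel half-width sets
# the correlation length
smooth_field <- function(nr, nc, corr_len) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  h <- max(0L, as.integer(round(corr_len)))
  if (h == 0L) return(z)
  k <- rep(1, 2L * h + 1L)
  pad_smooth <- function(m) {
    # reflect-pad then separable moving average, rows then columns
    mp <- m[c(pmin(nr, pmax(1, (1 - h):(nr + h)))), , drop = FALSE]
    mp <- apply(mp, 2L, function(col) stats::filter(col, k / length(k)))
    mp <- mp[(h + 1L):(h + nr), , drop = FALSE]
    mp <- mp[, c(pmin(nc, pmax(1, (1 - h):(nc + h)))), drop = FALSE]
    mp <- t(apply(mp, 1L, function(row) stats::filter(row, k / length(k))))
    mp[, (h + 1L):(h + nc), drop = FALSE]
  }
  pad_smooth(z)
}

#' Generate a synthetic land cover raster
#'
#' Thresholded smoothed noise: a Gaussian field smoothed to the requested
#' correlation length is cut at the quantiles implied by the target weights,
#' so realized class shares track the weights while cells remain spatially
#' autocorrelated. Fully reproducible from `(spec, seed)`.
#'
#' @param spec a [scene_spec()].
#' @return a [land_raster()] of cover codes `0..n_types-1`.
#' @examples
#' generate_landscape(scene_spec(40, 40, n_types = 4, seed = 7))
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  z <- smooth_field(spec$nrow, spec$ncol, spec$correlation_length)
  # rank-transform so quantile cuts give (near-)exact target shares
  r <- rank(as.vector(z), ties.method = "first") / length(z)
  cuts <- cumsum(spec$weights)
  cls <- findInterval(r, cuts, left.open = TRUE)  # 0 .. n_types-1
  cls <- pmin(cls, spec$n_types - 1L)
  land_raster(matrix(cls, spec$nrow, spec$ncol), cell_size = spec$cell_size,
              layer = "cover")
}

#' Generate a synthetic driver stack for a cover raster
#'
#' Each driver is a smooth random field plus (optionally) a class-linked
#' signal: cells of a designated cover type are shifted by a stated effect
#' size, so recovery tests know the ground-truth association. The generative
#' links are recorded in the `"links"` attribute.
#'
#' @param cover a cover [land_raster()].
#' @param n_smooth number of purely smooth (noise) drivers.
#' @param linked tibble with `driver`, `type`, `effect` describing class-linked
#'   drivers, or `NULL` for a default pair linked to types 0 and 1.
#' @param correlation_length smoothing length of the fields.
#' @param seed random seed.
#' @return a [driver_stack()] with attribute `links`.
#' @export
generate_drivers <- function(cover, n_smooth = 3L, linked = NULL,
                             correlation_length = 4, seed = 1L) {
  stopifnot(is_land_raster(cover))
  if (is.null(linked)) {
    linked <- tibble::tibble(driver = c("link_a", "link_b"),
                             type = c(0L, 1L), effect = c(2, 2))
  }
  set.seed(seed)
  nr <- nrow(cover$values); nc <- ncol(cover$values)
  mk <- function(name, type = NA_integer_, effect = 0) {
    f <- smooth_field(nr, nc, correlation_length)
    f <- (f - mean(f)) / stats::sd(f)
    if (!is.na(type)) f <- f + effect * (cover$values == type)
    land_raster(f, cell_size = cover$cell_size, xll = cover$xll,
                yll = cover$yll, layer = name)
  }
  layers <- list()
  for (k in seq_len(n_smooth)) layers[[paste0("smooth_", k)]] <- mk(paste0("smooth_", k))
  for (k in seq_len(nrow(linked))) {
    layers[[linked$driver[k]]] <- mk(linked$driver[k], linked$type[k],
                                     linked$effect[k])
  }
  out <- driver_stack(layers)
  attr(out, "links") <- linked
  out
}

#' Generate a before/after map pair under known transition rules
#'
#' Applies each rule in order to the y1 map: among cells of the rule's
#' `from` class, the `n` cells with the highest values of the named driver
#' (ties by row-major order) convert to the `to` class. The realized per-class
#' persistence is recorded as ground truth, closing the loop for
#' [estimate_resistance()] and [derive_conversion_matrix()] tests.
#'
#' @param map_y1 categorical [land_raster()] (cover or land system codes).
#' @param rules tibble with columns `from`, `to`, `driver`, `n` (cells to
#'   convert); `driver = NA` ranks cells randomly (seeded).
#' @param drivers optional [driver_stack()] referenced by the rules.
#' @param seed seed for random-ranking rules.
#' @return list `y1`, `y2` ([land_raster()]s), `truth` (tibble
#'   `class, n_y1, n_stay, persistence`), `rules`.
#' @export
generate_transition_pair <- function(map_y1, rules, drivers = NULL, seed = 1L) {
  stopifnot(is_land_raster(map_y1))
  stopifnot(all(c("from", "to", "n") %in% names(rules)))
  if (!"driver" %in% names(rules)) rules$driver <- NA_character_
  v1 <- as.vector(map_y1$values)
  v2 <- v1
  set.seed(seed)
  nr <- nrow(map_y1$values)
  rowmajor <- (seq_along(v1) - 1L) %% nr * ncol(map_y1$values) +
    (seq_along(v1) - 1L) %/% nr + 1L
  for (k in seq_len(nrow(rules))) {
    from <- rules$from[k]; to <- rules$to[k]; n <- rules$n[k]
    cand <- which(v2 == from)
    if (length(cand) < n) {
      stop(sprintf("rule %d wants %d cells of class %d but only %d remain",
                   k, n, from, length(cand)), call. = FALSE)
    }
    drv <- rules$driver[k]
    score <- if (is.na(drv)) runif(length(cand)) else {
      if (is.null(drivers) || !drv %in% names(drivers)) {
        stop("rule references unknown driver: ", drv, call. = FALSE)
      }
      as.vector(drivers[[drv]]$values)[cand]
    }
    sel <- cand[order(-score, rowmajor[cand])][seq_len(n)]
    v2[sel] <- to
  }
  classes <- sort(unique(v1[!is.na(v1)]))
  truth <- tibble::tibble(
    class = classes,
    n_y1 = vapply(classes, function(k) sum(v1 == k, na.rm = TRUE), integer(1)),
    n_stay = vapply(classes, function(k) sum(v1 == k & v2 == k, na.rm = TRUE),
                    integer(1))
  )
  truth$persistence <- truth$n_stay / truth$n_y1
  y2 <- land_raster(matrix(v2, nrow(map_y1$values), ncol(map_y1$values)),
                    cell_size = map_y1$cell_size, xll = map_y1$xll,
                    yll = map_y1$yll, layer = map_y1$layer)
  list(y1 = map_y1, y2 = y2, truth = truth, rules = rules)
}

#' Generate a geometric demand trajectory
#'
#' Stand-in for IAM scenario tables: per-service demand grows geometrically
#' from a base year at the stated per-step rates.
#'
#' @param base demand tibble `basin, year, service, demand_km2` for the base
#'   year (one row per service).
#' @param rates named numeric vector of per-step growth rates (e.g.
#'   `c(cropland = 0.1)` for +10% per step; unnamed services default to 0).
#' @param years vector of years; the first must be the base year.
#' @return a demand tibble covering all `years`, CSV-compatible with
#'   [read_demand_table()].
#' @export
generate_demand_trajectory <- function(base, rates, years) {
  stopifnot(all(c("basin", "year", "service", "demand_km2") %in% names(base)))
  stopifnot(length(years) >= 1L, all(base$year == years[1L]))
  r <- setNames(rep(0, 4L), unname(services()))
  r[intersect(names(rates), names(r))] <- rates[intersect(names(rates), names(r))]
  out <- tidyr::crossing(base[c("basin", "service", "demand_km2")],
                         tibble::tibble(year = years, step = seq_along(years) - 1L))
  out$demand_km2 <- out$demand_km2 * unname((1 + r[out$service])^out$step)
  if (any(out$demand_km2 < 0)) stop("negative demand in trajectory", call. = FALSE)
  dplyr::arrange(out[c("basin", "year", "service", "demand_km2")],
                 .data$basin, .data$year, .data$service)
}

#' Read / write demand tables
#'
#' CSV with columns `basin, year, service, demand_km2`.
#'
#' @param path CSV path.
#' @return `read_demand_table()`: a tibble; `write_demand_table()`: the path,
#'   invisibly.
#' @export
read_demand_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("basin", "year", "service", "demand_km2") %in% names(tab)))
  bad <- setdiff(unique(tab$service), unname(services()))
  if (length(bad)) stop("unknown service(s) in demand table: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  tab
}

#' @rdname read_demand_table
#' @param demand a demand tibble.
#' @export
write_demand_table <- function(demand, path) {
  readr::write_csv(demand, path)
  invisible(path)
}
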