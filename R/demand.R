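#' The four land system services
#'
#' Demand from the integrated assessment model and supply from the land system
#' map meet through four aggregate services: cropland, forest, grassland and
#' shrubland area. Each service is backed by one basic cover type (codes 0-3).
#'
#' @return character vector of service names, named by backing cover code.
#' @export
services <- function() {
  c(`0` = "cropland", `1` = "forest", `2` = "grassland", `3` = "shrubland")
}

norm_type <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Mapping from IAM land types to land system services
#'
#' The default dictionary maps GCAM-style land type names onto the four
#' services; types that do not change (tundra, urban, rocky, snow or ice,
#' desert) are excluded from demand. The mapping ships as an editable YAML
#' file (`system.file("extdata", "gcam_service_map.yaml", package =
#' "tipland")`) and can be replaced via [read_service_map()].
#'
#' @return a tibble with `land_type` (case-normalized) and `service`
#'   (`"excluded"` marks the do-not-change types).
#' @export
gcam_service_map <- function() {
  map <- list(
    cropland = c("Corn", "Fibre crop", "Fodder grass", "Fodder herb",
                 "Misc crop", "Oil crop", "Palm fruit", "Rice", "Root tuber",
                 "Sugar crop", "Wheat", "Biomass grass", "Biomass tree",
                 "Other grain", "Other arable land"),
    forest = c("Unmanaged forest", "Protected unmanaged forest", "Forest"),
    grassland = c("Unmanaged pasture", "Protected grassland",
                  "Protected unmanaged pasture", "Pasture", "Grassland"),
    shrubland = c("Protected shrubland", "Shrubland"),
    excluded = c("Tundra", "Urban", "Rocky", "Snow or ice", "Desert")
  )
  tibble::tibble(
    land_type = norm_type(unlist(map, use.names = FALSE)),
    service = rep(names(map), lengths(map))
  )
}

#' @rdname gcam_service_map
#' @param path YAML file with one key per service (plus `excluded`), each a
#'   list of land type names.
#' @export
read_service_map <- function(path) {
  y <- yaml::read_yaml(path)
  bad <- setdiff(names(y), c(unname(services()), "excluded"))
  if (length(bad)) stop("unknown service keys in mapping: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  tibble::tibble(
    land_type = norm_type(unlist(y, use.names = FALSE)),
    service = rep(names(y), lengths(y))
  )
}

#' Label IAM land records with their land system service
#'
#' Attaches a `service` column to IAM land area records via the type mapping.
#' Records of excluded (non-changing) types are dropped with a message;
#' land types absent from the mapping raise an error listing the offending
#' strings.
#'
#' @param records data frame with at least `land_type`; typically
#'   `basin, land_type, year, area` from [read_iam_table()].
#' @param mapping a mapping tibble, default [gcam_service_map()].
#' @return the records labelled with `service`, excluded rows removed.
#' @examples
#' reclassify_iam_types(tibble::tibble(land_type = c("Corn", "Forest"),
#'                                     area = c(10, 20)))
#' @export
reclassify_iam_types <- function(records, mapping = gcam_service_map()) {
  stopifnot(is.data.frame(records), "land_type" %in% names(records))
  key <- norm_type(records$land_type)
  svc <- setNames(mapping$service, mapping$land_type)[key]
  unknown <- unique(records$land_type[is.na(svc)])
  if (length(unknown)) {
    stop("unknown IAM land type(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  drop <- svc == "excluded"
  if (any(drop)) {
    message("dropping ", sum(drop), " record(s) of excluded land types: ",
            paste(unique(records$land_type[drop]), collapse = ", "))
  }
  out <- tibble::as_tibble(records[!drop, , drop = FALSE])
  out$service <- unname(svc[!drop])
  out
}

#' Aggregate labelled records into per-basin service demand
#'
#' Demand for a service is the total area of its IAM land types within a basin
#' and year. Services with no records get demand 0 (with a warning), so the
#' result always carries all four services per basin-year.
#'
#' @param records reclassified records (see [reclassify_iam_types()]) with
#'   columns `basin`, `year`, `service`, `area` (km2).
#' @return a tibble `basin, year, service, demand_km2`.
#' @export
aggregate_service_demand <- function(records) {
  stopifnot(all(c("basin", "year", "service", "area") %in% names(records)))
  if (any(records$area < 0, na.rm = TRUE)) stop("negative area", call. = FALSE)
  out <- records |>
    dplyr::group_by(.data$basin, .data$year, .data$service) |>
    dplyr::summarise(demand_km2 = sum(.data$area), .groups = "drop") |>
    tidyr::complete(.data$basin, .data$year,
                    service = unname(services()),
                    fill = list(demand_km2 = 0))
  zero <- out$service[out$demand_km2 == 0]
  if (length(zero)) {
    warning("no records for service(s) ",
            paste(sort(unique(zero)), collapse = ", "),
            " in at least one basin-year; demand set to 0", call. = FALSE)
  }
  dplyr::arrange(out, .data$basin, .data$year,
                 match(.data$service, unname(services())))
}

#' Read an IAM land area table
#'
#' CSV with columns `basin, land_type, year, area` and optionally `unit`
#' (`km2` or `thous_km2`). The IAM conventionally reports thousand km2; all
#' areas are converted to km2 on ingest.
#'
#' @param path CSV path.
#' @param unit default unit when the file carries no `unit` column.
#' @return a tibble with `area` in km2.
#' @export
read_iam_table <- function(path, unit = c("thous_km2", "km2")) {
  unit <- match.arg(unit)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("basin", "land_type", "year", "area") %in% names(tab)))
  u <- if ("unit" %in% names(tab)) tab$unit else rep(unit, nrow(tab))
  bad <- setdiff(unique(u), c("km2", "thous_km2"))
  if (length(bad)) stop("unknown area unit(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  tab$area <- tab$area * ifelse(u == "thous_km2", 1000, 1)
  tab$unit <- NULL
  tab
}

block_bounds <- function(n_fine, n_coarse, window) {
  r0 <- (seq_len(n_coarse) - 1L) * window + 1L
  r1 <- pmin(n_fine, seq_len(n_coarse) * window)
  list(from = r0, to = r1)
}

#' Supply capacity of each land system class
#'
#' For each land system class j and service d, the capacity `CA[j, d]` is the
#' average area (km2) of the service's backing cover type among the fine cover
#' cells nested inside the coarse cells of class j. A class can therefore
#' supply several services at once and a service can be supplied by several
#' classes (the many-to-many demand/supply structure), and classes dominated
#' by a non-service cover type still supply whatever service area their cells
#' contain. Setting `service_classes_only = TRUE` zeroes the capacity rows of
#' those non-service classes so they take part in allocation only through the
#' conversion matrix; the default keeps the data-driven rows, which keeps the
#' booked supply of a map consistent with the fine-cell service areas that
#' define historical demand.
#'
#' @param cover fine-resolution cover [land_raster()].
#' @param ls coarse land system [land_raster()] whose cells nest an integer
#'   number of cover cells.
#' @param service_classes_only zero the capacity rows of non-service classes
#'   (default `FALSE`).
#' @return a tibble `class, service, capacity_km2` covering all 30 classes and
#'   4 services.
#' @export
compute_supply_capacity <- function(cover, ls, service_classes_only = FALSE) {
  stopifnot(is_land_raster(cover), is_land_raster(ls))
  window <- ls$cell_size / cover$cell_size
  if (abs(window - round(window)) > 1e-8) {
    stop("land system cell size is not an integer multiple of cover cell size",
         call. = FALSE)
  }
  window <- as.integer(round(window))
  nrc <- nrow(cover$values); ncc <- ncol(cover$values)
  nrl <- nrow(ls$values); ncl <- ncol(ls$values)
  if ((nrl - 1L) * window >= nrc || (ncl - 1L) * window >= ncc) {
    stop("rasters are misaligned: land system grid does not nest in cover grid",
         call. = FALSE)
  }
  cell_area <- (cover$cell_size / 1000)^2  # km2 per fine cell
  rb <- block_bounds(nrc, nrl, window)
  cb <- block_bounds(ncc, ncl, window)
  svc_codes <- as.integer(names(services()))
  acc <- matrix(0, 30L, 4L)   # summed supplied area per (class, service)
  n_cells <- numeric(30L)
  for (bi in seq_len(nrl)) {
    for (bj in seq_len(ncl)) {
      j <- ls$values[bi, bj]
      if (is.na(j)) next
      blk <- cover$values[rb$from[bi]:rb$to[bi], cb$from[bj]:cb$to[bj]]
      n_cells[j + 1L] <- n_cells[j + 1L] + 1
      for (d in seq_along(svc_codes)) {
        acc[j + 1L, d] <- acc[j + 1L, d] +
          sum(blk == svc_codes[d], na.rm = TRUE) * cell_area
      }
    }
  }
  ca <- acc / ifelse(n_cells > 0, n_cells, 1)
  if (service_classes_only) {
    non_service <- floor(0:29 / 3) > 3
    ca[non_service, ] <- 0
  }
  tibble::tibble(
    class = rep(0:29, times = 4L),
    service = rep(unname(services()), each = 30L),
    capacity_km2 = as.vector(ca)
  )
}

#' Supply capacity tibble as a 30 x 4 matrix
#'
#' @param ca tibble from [compute_supply_capacity()] (or any
#'   `class, service, capacity_km2` table).
#' @return numeric matrix, rows = classes 0-29, columns = services.
#' @export
ca_matrix <- function(ca) {
  stopifnot(all(c("class", "service", "capacity_km2") %in% names(ca)))
  m <- matrix(0, 30L, 4L, dimnames = list(0:29, unname(services())))
  m[cbind(ca$class + 1L, match(ca$service, colnames(m)))] <- ca$capacity_km2
  m
}

#' Service demand from an observed land cover map
#'
#' Historical-validation mode: demand for each service is the total area of
#' its backing cover type inside the (optional) region mask, so a simulation
#' started from an earlier map is pushed towards the observed composition.
#'
#' @param cover fine-resolution cover [land_raster()].
#' @param mask optional [land_raster()] with non-zero/non-NA cells marking the
#'   region; must share the cover geometry.
#' @param basin,year labels for the output table.
#' @return a tibble `basin, year, service, demand_km2`.
#' @export
demand_from_landcover <- function(cover, mask = NULL, basin = "all", year = NA_integer_) {
  stopifnot(is_land_raster(cover))
  v <- cover$values
  if (!is.null(mask)) {
    check_same_geometry(cover, mask, "cover and mask")
    keep <- !is.na(mask$values) & mask$values != 0
    if (!any(keep)) stop("empty mask", call. = FALSE)
    v <- ifelse(keep, v, NA)
  }
  cell_area <- (cover$cell_size / 1000)^2
  svc_codes <- as.integer(names(services()))
  tibble::tibble(
    basin = basin, year = year,
    service = unname(services()),
    demand_km2 = vapply(svc_codes, function(d) sum(v == d, na.rm = TRUE) * cell_area,
                        numeric(1))
  )
}

#' Linearly interpolate a demand table to intermediate years
#'
#' The IAM reports demand at coarse (e.g. 5- or 10-year) steps; allocation
#' runs one external iteration per simulation step with demand interpolated
#' linearly between the endpoint years.
#'
#' @param demand tibble `basin, year, service, demand_km2`.
#' @param years years to evaluate at (within the table's year range).
#' @return a tibble with the same columns at the requested years.
#' @export
interpolate_demand <- function(demand, years) {
  stopifnot(all(c("basin", "year", "service", "demand_km2") %in% names(demand)))
  demand |>
    dplyr::group_by(.data$basin, .data$service) |>
    dplyr::reframe({
      ap <- stats::approx(.data$year, .data$demand_km2, xout = years, rule = 2)
      tibble::tibble(year = years, demand_km2 = ap$y)
    })
}
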