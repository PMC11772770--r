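#' Land cover and land system legends
#'
#' The workflow uses ten basic land cover types (integer codes 0-9). A land
#' system class combines a dominant cover type with a within-cell density level
#' (low/medium/high), giving up to 30 classes with the type-major integer
#' layout `code = 3 * cover_code + density` (density 0 = low, 1 = medium,
#' 2 = high).
#'
#' @return `cover_types()`: a tibble with `code` and `cover`;
#'   `land_system_legend()`: a tibble with `value`, `cover_code`, `cover`,
#'   `density` and `label` for all 30 classes.
#' @examples
#' land_system_legend()
#' @export
cover_types <- function() {
  tibble::tibble(
    code = 0:9,
    cover = c("cropland", "forest", "grassland", "shrubland", "wetland",
              "water", "tundra", "artificial", "bare", "snow_ice")
  )
}

#' @rdname cover_types
#' @export
land_system_legend <- function() {
  ct <- cover_types()
  pretty <- c("Cropland", "Forest", "Grassland", "Shrubland", "Wetland",
              "Water", "Tundra", "Artificial", "Bare", "Snow/ice")
  tibble::tibble(
    value = 0:29,
    cover_code = rep(ct$code, each = 3L),
    cover = rep(ct$cover, each = 3L),
    density = rep(c("L", "M", "H"), times = 10L),
    label = paste0(rep(pretty, each = 3L), "_", rep(c("L", "M", "H"), 10L))
  )
}

#' Majority upscaling of a categorical land cover raster
#'
#' Traverses the fine raster in non-overlapping `window` x `window` blocks and,
#' for each block, records the dominant (modal) cover type and its area
#' fraction among the block's valid cells. With 30 m input and the default
#' 33-cell window this produces the 990 m grid on which land systems are
#' defined.
#'
#' Edge blocks that are only partially covered by the raster are kept when at
#' least half of the block area is inside, and dropped otherwise. Ties between
#' class counts are broken towards the lowest class code so results are
#' reproducible.
#'
#' @param cover a [land_raster()] of integer cover codes.
#' @param window block edge length in fine cells (default 33).
#' @return a list with `type` (coarse categorical [land_raster()]) and
#'   `fraction` (coarse [land_raster()] of dominant-type fractions in `[0, 1]`);
#'   both have `cell_size = window * cover$cell_size`. All-nodata blocks are
#'   nodata in both outputs.
#' @examples
#' cov <- land_raster(matrix(c(1, 1, 1, 2), 2, 2), cell_size = 30)
#' upscale_dominant_type(cov, window = 2)
#' @export
upscale_dominant_type <- function(cover, window = 33L) {
  stopifnot(is_land_raster(cover))
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("`window` must be >= 1", call. = FALSE)
  v <- cover$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < window || nc < window) {
    stop(sprintf("raster (%dx%d) smaller than window (%d)", nr, nc, window),
         call. = FALSE)
  }
  n_blk_r <- nr %/% window; rem_r <- nr %% window
  n_blk_c <- nc %/% window; rem_c <- nc %% window
  # trailing block row/col exists whenever there is a remainder; the per-block
  # coverage test below decides whether each edge block is kept
  if (rem_r > 0L) n_blk_r <- n_blk_r + 1L
  if (rem_c > 0L) n_blk_c <- n_blk_c + 1L
  type <- matrix(NA_real_, n_blk_r, n_blk_c)
  frac <- matrix(NA_real_, n_blk_r, n_blk_c)
  for (bi in seq_len(n_blk_r)) {
    r0 <- (bi - 1L) * window + 1L
    r1 <- min(nr, bi * window)
    for (bj in seq_len(n_blk_c)) {
      c0 <- (bj - 1L) * window + 1L
      c1 <- min(nc, bj * window)
      inside <- (r1 - r0 + 1L) * (c1 - c0 + 1L)
      if (inside < 0.5 * window * window) next  # mostly-outside edge block
      blk <- v[r0:r1, c0:c1]
      blk <- blk[!is.na(blk)]
      if (length(blk) == 0L) next
      counts <- table(blk)
      best <- which(counts == max(counts))
      # tie-break: lowest class code (names are sorted numerically-as-strings,
      # so re-sort explicitly)
      codes <- as.numeric(names(counts))[best]
      win <- min(codes)
      type[bi, bj] <- win
      frac[bi, bj] <- max(counts) / length(blk)
    }
  }
  cs <- window * cover$cell_size
  # drop all-NA trailing block rows/cols created by a <50% remainder
  keep_r <- rowSums(!is.na(type)) > 0L | seq_len(n_blk_r) <= (nr %/% window)
  keep_c <- colSums(!is.na(type)) > 0L | seq_len(n_blk_c) <= (nc %/% window)
  type <- type[keep_r, keep_c, drop = FALSE]
  frac <- frac[keep_r, keep_c, drop = FALSE]
  yll_new <- cover$yll + nr * cover$cell_size - nrow(type) * cs
  list(
    type = land_raster(type, cell_size = cs, xll = cover$xll, yll = yll_new,
                       layer = "dominant_type"),
    fraction = land_raster(frac, cell_size = cs, xll = cover$xll, yll = yll_new,
                           layer = "dominant_fraction")
  )
}

#' Jenks natural breaks of a numeric vector
#'
#' Exact Fisher dynamic-programming solution of the 1-D natural breaks
#' problem: partitions the sorted values into `k` contiguous classes
#' minimizing the total within-class sum of squared deviations. Runs on the
#' unique values with multiplicity weights, so it is exact and fast even for
#' long vectors with few distinct values (such as block fractions with
#' denominator `window^2`).
#'
#' @param x numeric vector (NAs dropped).
#' @param k number of classes (default 3).
#' @return numeric vector of `k - 1` breakpoints, each the maximum of a lower
#'   class, so class membership is `x <= b1`, `b1 < x <= b2`, `x > b2`.
#'   Returns `NULL` when `x` has fewer than `k` distinct values.
#' @examples
#' jenks_breaks(c(1, 2, 3, 10, 11, 12, 20, 21, 22) / 100)
#' @export
jenks_breaks <- function(x, k = 3L) {
  x <- x[!is.na(x)]
  k <- as.integer(k)
  ux <- sort(unique(x))
  n <- length(ux)
  if (n < k) return(NULL)
  w <- as.numeric(table(factor(x, levels = ux)))
  cw <- c(0, cumsum(w))
  cs1 <- c(0, cumsum(w * ux))
  cs2 <- c(0, cumsum(w * ux^2))
  # ssd of unique-value range i..j (1-based, inclusive), O(1) via prefix sums
  ssd <- function(i, j) {
    W <- cw[j + 1L] - cw[i]
    S1 <- cs1[j + 1L] - cs1[i]
    S2 <- cs2[j + 1L] - cs2[i]
    pmax(0, S2 - S1^2 / W)
  }
  # dp[g, j]: minimal cost of splitting 1..j into g classes
  dp <- matrix(Inf, k, n)
  idx <- matrix(0L, k, n)  # start index of the last class
  dp[1L, ] <- ssd(1L, seq_len(n))
  idx[1L, ] <- 1L
  if (k >= 2L) {
    for (g in 2:k) {
      for (j in g:n) {
        i <- g:j  # last class is i..j
        cost <- dp[g - 1L, i - 1L] + ssd(i, j)
        b <- which.min(cost)  # first minimum: deterministic tie-break
        dp[g, j] <- cost[b]
        idx[g, j] <- i[b]
      }
    }
  }
  bounds <- integer(k)  # end index of each class
  j <- n
  for (g in k:1L) {
    bounds[g] <- j
    j <- idx[g, j] - 1L
  }
  ux[bounds[-k]]
}

#' Density breakpoints per cover type
#'
#' Applies three-class Jenks natural breaks to the dominant-type fractions of
#' each cover type, yielding the two breakpoints that separate low, medium and
#' high density. Types with fewer than three distinct fraction values are
#' flagged degenerate; [classify_density()] assigns all their cells high
#' density.
#'
#' @param fractions a data frame with columns `type` (cover code) and
#'   `fraction`, e.g. from [upscale_dominant_type()] outputs; or the list that
#'   function returns.
#' @return a tibble with one row per type: `type`, `b1`, `b2`, `n`,
#'   `degenerate`.
#' @export
compute_density_breaks <- function(fractions) {
  if (is.list(fractions) && is_land_raster(fractions$type)) {
    fractions <- tibble::tibble(
      type = as.vector(fractions$type$values),
      fraction = as.vector(fractions$fraction$values)
    )
  }
  stopifnot(is.data.frame(fractions), all(c("type", "fraction") %in% names(fractions)))
  fractions <- fractions[!is.na(fractions$type) & !is.na(fractions$fraction), ]
  if (nrow(fractions) == 0L) stop("no valid (type, fraction) pairs", call. = FALSE)
  out <- fractions |>
    dplyr::group_by(type = .data$type) |>
    dplyr::summarise(
      breaks = list(jenks_breaks(.data$fraction, k = 3L)),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      degenerate = purrr::map_lgl(.data$breaks, is.null),
      b1 = purrr::map_dbl(.data$breaks, ~ if (is.null(.x)) NA_real_ else .x[1]),
      b2 = purrr::map_dbl(.data$breaks, ~ if (is.null(.x)) NA_real_ else .x[2])
    ) |>
    dplyr::select("type", "b1", "b2", "n", "degenerate") |>
    dplyr::arrange(.data$type)
  if (any(out$degenerate)) {
    message("degenerate density breaks (fewer than 3 distinct fractions) for type(s) ",
            paste(out$type[out$degenerate], collapse = ", "),
            "; all their cells will be classed high density")
  }
  out
}

#' Classify density and assemble the land system raster
#'
#' Combines a dominant-type raster, its fraction raster and per-type
#' breakpoints into the land system raster with codes `3 * type + density`.
#' Density is 0 (low) for `fraction <= b1`, 1 (medium) for
#' `b1 < fraction <= b2`, and 2 (high) otherwise; cells of a degenerate type
#' are all high density.
#'
#' @param type_grid,fraction_grid coarse rasters from [upscale_dominant_type()].
#' @param breaks tibble from [compute_density_breaks()].
#' @return a [land_raster()] of land system codes (0-29).
#' @export
classify_density <- function(type_grid, fraction_grid, breaks) {
  check_same_geometry(type_grid, fraction_grid, "type and fraction grids")
  ty <- as.vector(type_grid$values)
  fr <- as.vector(fraction_grid$values)
  present <- sort(unique(ty[!is.na(ty)]))
  missing <- setdiff(present, breaks$type)
  if (length(missing)) {
    stop("no density breaks for cover type(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  b1 <- setNames(breaks$b1, breaks$type)[as.character(ty)]
  b2 <- setNames(breaks$b2, breaks$type)[as.character(ty)]
  density <- ifelse(is.na(b1), 2,                      # degenerate type: high
                    ifelse(fr <= b1, 0, ifelse(fr <= b2, 1, 2)))
  code <- ifelse(is.na(ty), NA_real_, 3 * ty + density)
  land_raster(matrix(code, nrow(type_grid$values), ncol(type_grid$values)),
              cell_size = type_grid$cell_size, xll = type_grid$xll,
              yll = type_grid$yll, layer = "land_system")
}

#' Merge density levels back into cover types
#'
#' Collapses a 30-class land system raster to its ten cover types
#' (`floor(code / 3)`), the thematic resolution used for coarse validation.
#'
#' @param ls a land system [land_raster()].
#' @return a [land_raster()] of cover codes (0-9).
#' @examples
#' ls <- land_raster(matrix(c(3, 4, 5, NA), 2, 2), cell_size = 990)
#' merge_density(ls)$values
#' @export
merge_density <- function(ls) {
  stopifnot(is_land_raster(ls))
  v <- ls$values
  bad <- v[!is.na(v)]
  if (length(bad) && (any(bad < 0 | bad > 29) || any(bad != floor(bad)))) {
    stop("land system codes must be integers in 0..29", call. = FALSE)
  }
  land_raster(floor(v / 3), cell_size = ls$cell_size, xll = ls$xll, yll = ls$yll,
              layer = "cover")
}

#' Build a land system raster from a land cover raster
#'
#' Convenience wrapper: majority upscaling, global Jenks density breaks, and
#' density classification in one call. Breakpoints are computed globally over
#' the whole raster (a single legend), not per region.
#'
#' @inheritParams upscale_dominant_type
#' @param target_cell_size optional final resolution for a nearest-neighbour
#'   resampling step (e.g. 1000 to go from 990 m to 1 km); `NULL` skips it.
#' @return a list with `ls` (the land system [land_raster()]), `breaks`
#'   (tibble), `type` and `fraction` (the intermediate coarse rasters).
#' @export
build_land_system <- function(cover, window = 33L, target_cell_size = NULL) {
  up <- upscale_dominant_type(cover, window = window)
  breaks <- compute_density_breaks(up)
  ls <- classify_density(up$type, up$fraction, breaks)
  if (!is.null(target_cell_size)) ls <- resample_nearest(ls, target_cell_size)
  list(ls = ls, breaks = breaks, type = up$type, fraction = up$fraction)
}
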