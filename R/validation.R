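#' Confusion table between observed and simulated maps
#'
#' Cross-tabulates co-registered categorical rasters cell by cell; cells that
#' are nodata in either map are excluded pairwise.
#'
#' @param observed,simulated categorical [land_raster()]s.
#' @return a `confusion_table`: a K x K count matrix (observed in rows,
#'   simulated in columns, shared sorted class levels) with attribute `n`.
#' @export
confusion <- function(observed, simulated) {
  check_same_geometry(observed, simulated, "observed and simulated maps")
  o <- as.vector(observed$values); s <- as.vector(simulated$values)
  ok <- !is.na(o) & !is.na(s)
  lev <- sort(unique(c(o[ok], s[ok])))
  tab <- table(factor(o[ok], levels = lev), factor(s[ok], levels = lev))
  structure(unclass(tab), n = sum(ok), class = "confusion_table")
}

#' Cohen's kappa of a confusion table
#'
#' Chance-corrected overall agreement, `(P0 - Pc) / (1 - Pc)`, where `P0` is
#' the observed proportion of agreeing cells and `Pc` the agreement expected
#' under independent marginals (the product-of-marginals chance model).
#' Degenerate tables with `Pc = 1` (a single class on both margins) have no
#' defined kappa and return `NA` with a `"reason"` attribute rather than a
#' silent 0.
#'
#' @param table a matrix of counts (observed x simulated), e.g. from
#'   [confusion()].
#' @return kappa in `[-1, 1]`, or `NA` (attr `reason`) when undefined.
#' @examples
#' kappa_statistic(matrix(c(45, 5, 5, 45), 2, 2))  # 0.8
#' @export
kappa_statistic <- function(table) {
  m <- unclass(as.matrix(table))
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  n <- sum(m)
  if (n == 0) stop("empty confusion table", call. = FALSE)
  p0 <- sum(diag(m)) / n
  pc <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pc) < 1e-15) {
    return(structure(NA_real_, reason = "degenerate table: chance agreement is 1"))
  }
  (p0 - pc) / (1 - pc)
}

#' Change components A, B, C, D of a simulated change map
#'
#' Classifies every valid cell of the (initial, observed, simulated) triple:
#' A changed in reality but not in the simulation; B changed in both to the
#' same (correct) type; C changed in both but to the wrong type; D did not
#' change in reality but changed in the simulation. Cells unchanged in both
#' belong to none of the four.
#'
#' @param initial,observed,simulated co-registered categorical
#'   [land_raster()]s.
#' @return a tibble with one row: `A`, `B`, `C`, `D`, `n_valid`.
#' @export
change_components <- function(initial, observed, simulated) {
  check_same_geometry(initial, observed, "initial and observed maps")
  check_same_geometry(initial, simulated, "initial and simulated maps")
  i <- as.vector(initial$values)
  o <- as.vector(observed$values)
  s <- as.vector(simulated$values)
  ok <- !is.na(i) & !is.na(o) & !is.na(s)
  i <- i[ok]; o <- o[ok]; s <- s[ok]
  real_chg <- o != i
  sim_chg <- s != i
  tibble::tibble(
    A = sum(real_chg & !sim_chg),
    B = sum(real_chg & sim_chg & s == o),
    C = sum(real_chg & sim_chg & s != o),
    D = sum(!real_chg & sim_chg),
    n_valid = length(i)
  )
}

#' Figure of merit
#'
#' `FoM = B / (A + B + C + D)`: the fraction of correctly predicted change
#' among all cells where change was observed or simulated. Undefined (no
#' change anywhere) returns `NA` with a `"reason"` attribute.
#'
#' @param comp one-row tibble (or list) with `A`, `B`, `C`, `D`, e.g. from
#'   [change_components()].
#' @return FoM in `[0, 1]`, or `NA` (attr `reason`) when undefined.
#' @examples
#' figure_of_merit(list(A = 2, B = 6, C = 1, D = 1))  # 0.6
#' @export
figure_of_merit <- function(comp) {
  A <- comp$A; B <- comp$B; C <- comp$C; D <- comp$D
  stopifnot(all(c(A, B, C, D) >= 0))
  denom <- A + B + C + D
  if (denom == 0) {
    return(structure(NA_real_, reason = "no observed or simulated change"))
  }
  B / denom
}

#' Validate a simulated land system map
#'
#' Computes kappa and figure of merit at full (30-class) or merged (10-class)
#' thematic resolution.
#'
#' @param initial,observed,simulated land system [land_raster()]s.
#' @param thematic 30 (native classes) or 10 (densities merged with
#'   [merge_density()] before scoring).
#' @return a one-row tibble `thematic, kappa, fom, A, B, C, D, n_valid`.
#' @export
validate_maps <- function(initial, observed, simulated, thematic = 30) {
  stopifnot(thematic %in% c(10, 30))
  if (thematic == 10) {
    initial <- merge_density(initial)
    observed <- merge_density(observed)
    simulated <- merge_density(simulated)
  }
  comp <- change_components(initial, observed, simulated)
  tibble::tibble(
    thematic = thematic,
    kappa = as.numeric(kappa_statistic(confusion(observed, simulated))),
    fom = as.numeric(figure_of_merit(comp)),
    A = comp$A, B = comp$B, C = comp$C, D = comp$D, n_valid = comp$n_valid
  )
}
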