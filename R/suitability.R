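#' Driver stacks
#'
#' A driver stack is a named list of co-registered [land_raster()] layers
#' (soil, socioeconomic, transport, climate, topography, cover-density, ...)
#' used as features of the location-suitability model.
#'
#' @param ... named `land_raster` layers, or a single named list of them.
#' @return the validated named list, classed `driver_stack`.
#' @export
driver_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1L]]) && !is_land_raster(layers[[1L]])) {
    layers <- layers[[1L]]
  }
  if (is.null(names(layers)) || any(names(layers) == "")) {
    stop("all driver layers must be named", call. = FALSE)
  }
  stopifnot(all(vapply(layers, is_land_raster, logical(1))))
  for (nm in names(layers)[-1]) {
    check_same_geometry(layers[[1L]], layers[[nm]], paste("drivers", nm))
  }
  structure(layers, class = c("driver_stack", "list"))
}

driver_frame <- function(drivers) {
  df <- tibble::as_tibble(lapply(drivers, function(l) as.vector(l$values)))
  names(df) <- names(drivers)
  df
}

#' Cover-density driver layers
#'
#' One layer per basic cover type giving the within-cell area proportion of
#' that type among the fine cover cells nested in each coarse land system
#' cell. These join the driver stack so the suitability model can see local
#' land composition, mirroring the density-of-cover driver category.
#'
#' @param ls coarse land system [land_raster()].
#' @param cover fine cover [land_raster()] nested in `ls` cells.
#' @return a [driver_stack()] with layers `density_<cover>` for all ten types,
#'   values in `[0, 1]`.
#' @export
compute_density_drivers <- function(ls, cover) {
  stopifnot(is_land_raster(ls), is_land_raster(cover))
  window <- ls$cell_size / cover$cell_size
  if (abs(window - round(window)) > 1e-8) {
    stop("land system cell size is not an integer multiple of cover cell size",
         call. = FALSE)
  }
  window <- as.integer(round(window))
  nrl <- nrow(ls$values); ncl <- ncol(ls$values)
  rb <- block_bounds(nrow(cover$values), nrl, window)
  cb <- block_bounds(ncol(cover$values), ncl, window)
  ct <- cover_types()
  props <- array(NA_real_, c(nrl, ncl, nrow(ct)))
  for (bi in seq_len(nrl)) {
    for (bj in seq_len(ncl)) {
      blk <- cover$values[rb$from[bi]:rb$to[bi], cb$from[bj]:cb$to[bj]]
      n <- sum(!is.na(blk))
      if (n == 0L) next
      cnt <- tabulate(blk[!is.na(blk)] + 1L, nbins = nrow(ct))
      props[bi, bj, ] <- cnt / n
    }
  }
  layers <- lapply(seq_len(nrow(ct)), function(k) {
    land_raster(matrix(props[, , k], nrl, ncl), cell_size = ls$cell_size, xll = ls$xll,
                yll = ls$yll, layer = paste0("density_", ct$cover[k]))
  })
  names(layers) <- paste0("density_", ct$cover)
  driver_stack(layers)
}

#' Training samples for the suitability model of one class
#'
#' Labels every valid cell of the map pair for class `class_j`. Under the
#' default `target = "loss"` rule, cells that are of class j at y1 but not at
#' y2 form sample set A and all remaining cells form sample set B. The
#' `"presence_at_y2"` variant instead labels A the cells that are of class j
#' at y2 (the gain-oriented convention); both are provided because the two
#' readings of the sampling rule differ and the choice is recorded in the
#' fitted model.
#'
#' @param ls_y1,ls_y2 co-registered land system [land_raster()]s.
#' @param drivers a [driver_stack()] sharing their geometry.
#' @param class_j land system class code (0-29); must be present at y1.
#' @param target `"loss"` (default) or `"presence_at_y2"`.
#' @return a tibble with `label` (factor A/B), `row`, `col` and one column per
#'   driver; rows with any missing driver are dropped.
#' @export
build_training_samples <- function(ls_y1, ls_y2, drivers, class_j,
                                   target = c("loss", "presence_at_y2")) {
  target <- match.arg(target)
  check_same_geometry(ls_y1, ls_y2, "land system maps")
  check_same_geometry(ls_y1, drivers[[1L]], "maps and drivers")
  a <- as.vector(ls_y1$values); b <- as.vector(ls_y2$values)
  if (target == "loss" && !any(a == class_j, na.rm = TRUE)) {
    stop("class ", class_j, " absent at y1", call. = FALSE)
  }
  if (target == "presence_at_y2" && !any(b == class_j, na.rm = TRUE)) {
    stop("class ", class_j, " absent at y2", call. = FALSE)
  }
  label <- if (target == "loss") {
    ifelse(a == class_j & b != class_j, "A", "B")
  } else {
    ifelse(b == class_j, "A", "B")
  }
  nr <- nrow(ls_y1$values)
  df <- driver_frame(drivers)
  df$label <- factor(label, levels = c("A", "B"))
  df$row <- (seq_along(a) - 1L) %% nr + 1L
  df$col <- (seq_along(a) - 1L) %/% nr + 1L
  keep <- !is.na(a) & !is.na(b) & stats::complete.cases(df[names(drivers)])
  out <- tibble::as_tibble(df[keep, c("label", "row", "col", names(drivers))])
  attr(out, "class_j") <- class_j
  attr(out, "target") <- target
  out
}

#' Fit the random-forest location-suitability model
#'
#' A probability random forest over the driver columns: 200 trees by default,
#' each grown on a 25% subsample of the rows drawn without replacement. Class
#' B may be downsampled to at most `max_b_ratio` times class A to bound
#' memory; the subsampling and tree construction are governed by one seed, so
#' fits are reproducible.
#'
#' @param samples tibble from [build_training_samples()].
#' @param num_trees number of trees (default 200).
#' @param sample_fraction per-tree subsample fraction (default 0.25). With
#'   `balanced = TRUE` the fraction is applied per class instead.
#' @param balanced class-balanced per-tree subsampling (default `FALSE`).
#' @param max_b_ratio cap on the B:A row ratio (default 10).
#' @param seed random seed for subsampling and tree construction.
#' @return a `suitability_model` wrapping the ranger fit plus the feature
#'   names, class code, labelling rule and seed.
#' @export
fit_suitability_model <- function(samples, num_trees = 200L,
                                  sample_fraction = 0.25, balanced = FALSE,
                                  max_b_ratio = 10, seed = 1L) {
  stopifnot("label" %in% names(samples))
  features <- setdiff(names(samples), c("label", "row", "col"))
  if (!length(features)) stop("no driver columns in samples", call. = FALSE)
  tab <- table(samples$label)
  if (any(tab == 0L)) {
    stop("single-label sample set (no '", names(tab)[tab == 0L][1L],
         "' rows); class cannot be modelled -- augment samples or skip it",
         call. = FALSE)
  }
  n_a <- sum(samples$label == "A")
  idx_b <- which(samples$label == "B")
  if (length(idx_b) > max_b_ratio * n_a) {
    set.seed(seed)
    idx_b <- sort(sample(idx_b, max_b_ratio * n_a))
    samples <- samples[sort(c(which(samples$label == "A"), idx_b)), ]
  }
  frac <- if (balanced) rep(sample_fraction, 2L) else sample_fraction
  fit <- ranger::ranger(
    dependent.variable.name = "label",
    data = as.data.frame(samples[c("label", features)]),
    num.trees = num_trees, probability = TRUE, replace = FALSE,
    sample.fraction = frac, importance = "impurity", seed = seed,
    num.threads = 1L
  )
  structure(list(fit = fit, features = features,
                 class_j = attr(samples, "class_j"),
                 target = attr(samples, "target"),
                 num_trees = num_trees, sample_fraction = sample_fraction,
                 balanced = balanced, seed = seed,
                 n_samples = nrow(samples), n_a = sum(samples$label == "A"),
                 n_b = sum(samples$label == "B")),
            class = "suitability_model")
}

#' @export
print.suitability_model <- function(x, ...) {
  cat(sprintf("<suitability_model> class %s (%s rule): %d trees, %g subsample, %d features\n",
              x$class_j %||% "?", x$target %||% "loss", x$num_trees,
              x$sample_fraction, length(x$features)))
  cat(sprintf("  %d samples (A: %d, B: %d), OOB Brier %.4f\n",
              x$n_samples, x$n_a, x$n_b, x$fit$prediction.error))
  invisible(x)
}

#' Tidy a suitability model
#'
#' `tidy()` gives per-driver impurity importance; `glance()` a one-row fit
#' summary.
#'
#' @param x a `suitability_model`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy suitability_model
#' @export
tidy.suitability_model <- function(x, ...) {
  imp <- ranger::importance(x$fit)
  tibble::tibble(driver = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname tidy.suitability_model
#' @method glance suitability_model
#' @export
glance.suitability_model <- function(x, ...) {
  tibble::tibble(
    class_j = x$class_j %||% NA_integer_, target = x$target %||% "loss",
    num_trees = x$num_trees, sample_fraction = x$sample_fraction,
    n_samples = x$n_samples, n_a = x$n_a, n_b = x$n_b,
    oob_brier = x$fit$prediction.error, seed = x$seed
  )
}

#' Predict a location-suitability surface
#'
#' Evaluates the fitted model over a driver stack, returning the per-cell
#' class-A probability in `[0, 1]`. Cells with any missing driver are nodata.
#'
#' @param model a `suitability_model`.
#' @param drivers a [driver_stack()] containing every feature the model was
#'   trained on.
#' @return a [land_raster()] suitability surface.
#' @export
predict_suitability <- function(model, drivers) {
  stopifnot(inherits(model, "suitability_model"))
  missing <- setdiff(model$features, names(drivers))
  if (length(missing)) {
    stop("driver stack is missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- driver_frame(drivers)[model$features]
  ok <- stats::complete.cases(df)
  p <- rep(NA_real_, nrow(df))
  if (any(ok)) {
    pred <- stats::predict(model$fit, data = as.data.frame(df[ok, , drop = FALSE]),
                           seed = model$seed, num.threads = 1L)
    p[ok] <- pred$predictions[, "A"]
  }
  g <- drivers[[1L]]
  land_raster(matrix(p, nrow(g$values), ncol(g$values)),
              cell_size = g$cell_size, xll = g$xll, yll = g$yll,
              layer = paste0("p_loc_", model$class_j %||% ""))
}
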