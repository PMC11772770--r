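#' Conversion matrix from an observed map pair
#'
#' Builds the binary from/to permission matrix for class transitions: a
#' conversion a -> b is allowed iff at least one cell made that transition
#' between the two maps. The diagonal (persistence) is always allowed.
#'
#' @param ls_y1,ls_y2 co-registered land system [land_raster()]s.
#' @return a 30 x 30 0/1 matrix with class codes 0-29 as dimnames.
#' @export
derive_conversion_matrix <- function(ls_y1, ls_y2) {
  check_same_geometry(ls_y1, ls_y2, "land system maps")
  a <- as.vector(ls_y1$values); b <- as.vector(ls_y2$values)
  ok <- !is.na(a) & !is.na(b)
  M <- matrix(0L, 30L, 30L, dimnames = list(0:29, 0:29))
  if (any(ok)) {
    pairs <- unique(cbind(a[ok], b[ok]))
    M[pairs + 1L] <- 1L
  }
  diag(M) <- 1L
  M
}

#' Conversion resistance from observed persistence
#'
#' The resistance of a land system class is the proportion of its cells at y1
#' that keep the same class at y2 (its persistence between the two dates).
#' Classes absent at y1 get a configurable default.
#'
#' @inheritParams derive_conversion_matrix
#' @param default resistance assigned to classes unseen at y1 (default 0.5).
#' @return a tibble `class, resistance, n_y1` for classes 0-29.
#' @export
estimate_resistance <- function(ls_y1, ls_y2, default = 0.5) {
  check_same_geometry(ls_y1, ls_y2, "land system maps")
  a <- as.vector(ls_y1$values); b <- as.vector(ls_y2$values)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n1 <- tabulate(a + 1L, nbins = 30L)
  stay <- tabulate((a + 1L)[a == b], nbins = 30L)
  res <- ifelse(n1 > 0, stay / pmax(n1, 1L), default)
  if (any(n1 == 0)) {
    message("class(es) ", paste(which(n1 == 0) - 1L, collapse = ", "),
            " absent at y1; resistance set to default ", default)
  }
  tibble::tibble(class = 0:29, resistance = res, n_y1 = n1)
}

res_vector <- function(resistance) {
  stopifnot(all(c("class", "resistance") %in% names(resistance)))
  v <- numeric(30L)
  v[resistance$class + 1L] <- resistance$resistance
  v
}

#' Conversion potential of a candidate change
#'
#' The potential of converting a cell to class j is the sum of four additive
#' components: location suitability, the conversion resistance of the cell's
#' class at the start of the external iteration, neighbourhood effects (0 by
#' default in this workflow) and the adaptive competitive advantage. Cells are
#' converted in descending order of this potential.
#'
#' @param p_loc,p_res,p_nei,p_comp numeric component values (vectorized).
#' @return `p_loc + p_res + p_nei + p_comp`.
#' @examples
#' conversion_potential(0.5, 0.2, 0, 0.1)
#' @export
conversion_potential <- function(p_loc, p_res, p_nei = 0, p_comp = 0) {
  p_loc + p_res + p_nei + p_comp
}

#' Competitive-advantage bookkeeping
#'
#' `new_competitive_state()` starts the internal-iteration bookkeeping of the
#' adaptive competitive advantage: iteration index i = 1, speed = seed
#' (default 1), all service inertias 0. `update_competitive_state()` advances
#' to the next internal iteration: the speed grows by `step` (default 0.001)
#' and each service's inertia accumulates the supply shortfall of the previous
#' iteration divided by the new speed,
#' `inertia_d <- inertia_d + (demand_d - supply_d) / speed`.
#' Services in surplus therefore accumulate negative inertia, discouraging
#' further conversions towards their suppliers.
#'
#' @param seed initial speed value (default 1).
#' @param step speed increment per internal iteration (default 0.001).
#' @return a `competitive_state` list with fields `i`, `speed`, `inertia`,
#'   `seed`, `step`.
#' @examples
#' st <- new_competitive_state()
#' st <- update_competitive_state(st, demand = c(cropland = 100), supply_prev = c(cropland = 90))
#' st$speed    # 1.001
#' st$inertia  # 10 / 1.001
#' @export
new_competitive_state <- function(seed = 1, step = 0.001) {
  if (seed <= 0) stop("speed seed must be positive", call. = FALSE)
  structure(list(i = 1L, speed = seed,
                 inertia = setNames(numeric(4L), unname(services())),
                 seed = seed, step = step),
            class = "competitive_state")
}

#' @rdname new_competitive_state
#' @param state a `competitive_state`.
#' @param demand,supply_prev named numeric vectors (km2) over the services;
#'   `supply_prev` is the supply at the end of the previous internal iteration.
#' @export
update_competitive_state <- function(state, demand, supply_prev) {
  stopifnot(inherits(state, "competitive_state"))
  svc <- intersect(names(state$inertia), names(demand))
  if (length(svc) == 0L) svc <- names(demand)
  state$i <- state$i + 1L
  state$speed <- state$speed + state$step
  if (state$speed <= 0) stop("speed became non-positive", call. = FALSE)
  gap <- demand[svc] - supply_prev[svc]
  state$inertia[svc] <- state$inertia[svc] + gap / state$speed
  state
}

#' Competitive advantage of switching between classes
#'
#' For a cell currently of class u, the competitive advantage of class j sums,
#' over the services, the service inertia times the marginal capacity gain of
#' the switch, normalized by the total capacity of all classes for that
#' service: `sum_d inertia_d * (CA[j,d] - CA[u,d]) / sum_j CA[j,d]`. It is
#' zero whenever all inertias are zero (the first internal iteration) and for
#' j = u.
#'
#' @param state a `competitive_state`.
#' @param ca 30 x 4 capacity matrix (see [ca_matrix()]).
#' @param from,to optional class codes; when omitted the full 30 x 30 matrix
#'   `P_comp[u + 1, j + 1]` is returned.
#' @return a scalar (vectorized over `from`/`to`) or the full matrix.
#' @export
competitive_advantage <- function(state, ca, from = NULL, to = NULL) {
  stopifnot(inherits(state, "competitive_state"))
  tot <- colSums(ca)
  active <- state$inertia != 0
  if (any(active & tot <= 0)) {
    stop("service(s) unservable (zero total capacity with nonzero inertia): ",
         paste(names(tot)[active & tot <= 0], collapse = ", "), call. = FALSE)
  }
  P <- matrix(0, 30L, 30L, dimnames = list(0:29, 0:29))
  for (d in which(active)) {
    P <- P + state$inertia[d] * outer(-ca[, d], ca[, d], `+`) / tot[d]
  }
  if (is.null(from)) return(P)
  P[cbind(from + 1L, to + 1L)]
}

#' Allocation configuration
#'
#' @param rel_tol per-service relative convergence tolerance on
#'   |supply - demand| (default 0.001, i.e. 0.1%); the absolute floor is one
#'   cell-equivalent of the largest capacity entry.
#' @param coarse_cap maximum number of coarse internal iterations
#'   (default 20000), after which the cell-by-cell fine phase runs.
#' @param fine_phase enable the fine phase (default `TRUE`).
#' @param neighbourhood_weight weight of the neighbourhood component
#'   (default 0; no kernel is applied in this workflow).
#' @param comp_seed,comp_step seed and step of the competitive-advantage speed
#'   sequence (defaults 1 and 0.001).
#' @param abs_floor absolute tolerance floor in km2; `NULL` (default) uses one
#'   cell-equivalent of the largest capacity entry.
#' @return an `allocation_config` list.
#' @export
allocation_config <- function(rel_tol = 0.001, coarse_cap = 20000L,
                              fine_phase = TRUE, neighbourhood_weight = 0,
                              comp_seed = 1, comp_step = 0.001,
                              abs_floor = NULL) {
  stopifnot(rel_tol > 0, coarse_cap >= 1L)
  structure(list(rel_tol = rel_tol, coarse_cap = as.integer(coarse_cap),
                 fine_phase = fine_phase,
                 neighbourhood_weight = neighbourhood_weight,
                 comp_seed = comp_seed, comp_step = comp_step,
                 abs_floor = abs_floor),
            class = "allocation_config")
}

demand_vector <- function(demand) {
  svc <- unname(services())
  if (is.data.frame(demand)) {
    stopifnot(all(c("service", "demand_km2") %in% names(demand)))
    if (anyDuplicated(demand$service)) {
      stop("demand table has duplicated services; filter to one basin-year first",
           call. = FALSE)
    }
    d <- setNames(rep(0, 4L), svc)
    d[demand$service] <- demand$demand_km2
    return(d)
  }
  stopifnot(is.numeric(demand), !is.null(names(demand)))
  d <- setNames(rep(0, 4L), svc)
  d[intersect(names(demand), svc)] <- demand[intersect(names(demand), svc)]
  d
}

ploc_matrix <- function(suitability, n_cells, dims) {
  P <- matrix(NA_real_, n_cells, 30L)
  for (nm in names(suitability)) {
    j <- suppressWarnings(as.integer(nm))
    if (is.na(j) || j < 0L || j > 29L) {
      stop("suitability layer name is not a class code 0..29: ", nm, call. = FALSE)
    }
    lay <- suitability[[nm]]
    if (!identical(dim(lay$values), dims)) {
      stop("suitability layer ", nm, " geometry mismatch", call. = FALSE)
    }
    P[, j + 1L] <- as.vector(lay$values)
  }
  P
}

#' Demand-driven land system allocation
#'
#' The core simulator: starting from an initial land system map, cells are
#' converted one at a time, in descending conversion potential, until the
#' supply of the four land system services meets the demand within tolerance.
#' Each internal iteration re-ranks candidates because the adaptive
#' competitive advantage term evolves with the remaining supply-demand gap
#' (see [update_competitive_state()]). A candidate conversion is only admitted
#' if it strictly reduces the total absolute supply-demand deviation, and ties
#' in potential are broken by (row-major cell index, class code), so runs are
#' fully deterministic. After `coarse_cap` iterations without convergence, a
#' cell-by-cell fine phase visits each cell at most once in descending
#' best-candidate potential.
#'
#' @param initial land system [land_raster()] (codes 0-29).
#' @param suitability named list of [land_raster()] suitability surfaces, one
#'   per candidate class, names = class codes ("0".."29").
#' @param demand demand table (`service`, `demand_km2`) for one basin-year, or
#'   a named numeric vector in km2.
#' @param ca capacity tibble from [compute_supply_capacity()] or a 30 x 4
#'   matrix.
#' @param conv_matrix 30 x 30 0/1 matrix from [derive_conversion_matrix()].
#' @param resistance tibble from [estimate_resistance()] or a length-30 vector.
#' @param config an [allocation_config()].
#' @param frozen optional [land_raster()] mask; cells with non-zero non-NA
#'   values never change.
#' @return an `allocation_result`: `final` (the converted map), `changes`
#'   (tibble `iteration, row, col, from, to`), `converged`, `infeasible`,
#'   `supply`, `demand`, `tolerance`, `iterations`, `fine_iterations`,
#'   `state`, `message`.
#' @export
allocate <- function(initial, suitability, demand, ca, conv_matrix, resistance,
                     config = allocation_config(), frozen = NULL) {
  stopifnot(is_land_raster(initial), inherits(config, "allocation_config"))
  dims <- dim(initial$values)
  u <- as.vector(initial$values)            # current class per cell
  valid <- !is.na(u)
  demand <- demand_vector(demand)
  if (any(!is.finite(demand))) stop("demand must be finite", call. = FALSE)
  CA <- if (is.matrix(ca)) ca else ca_matrix(ca)
  M <- conv_matrix
  stopifnot(identical(dim(M), c(30L, 30L)))
  pres <- if (is.data.frame(resistance)) res_vector(resistance) else resistance
  stopifnot(length(pres) == 30L)
  Ploc <- ploc_matrix(suitability, length(u), dims)
  frozen_v <- if (is.null(frozen)) rep(FALSE, length(u)) else {
    check_same_geometry(initial, frozen, "initial map and frozen mask")
    !is.na(frozen$values) & as.vector(frozen$values) != 0
  }

  counts <- tabulate(u[valid] + 1L, nbins = 30L)
  supply <- as.vector(counts %*% CA); names(supply) <- colnames(CA)
  tol <- pmax(config$rel_tol * demand, config$abs_floor %||% max(CA))

  # feasibility: best attainable supply if every cell switched to its highest-
  # capacity reachable class per service; cells may convert in several steps,
  # so reachability is the transitive closure of the conversion matrix
  reach <- matrix_closure(M)
  cap_best <- sapply(seq_len(4L), function(d) {
    per_class <- apply(reach, 1L, function(r) max(CA[r, d]))
    sum(per_class[u[valid & !frozen_v] + 1L]) +
      sum(CA[u[valid & frozen_v] + 1L, d])
  })
  if (any(demand > cap_best + 1e-9)) {
    bad <- names(supply)[demand > cap_best + 1e-9]
    return(structure(list(
      final = initial, changes = empty_changes(), converged = FALSE,
      infeasible = TRUE, supply = supply, demand = demand, tolerance = tol,
      iterations = 0L, fine_iterations = 0L,
      state = new_competitive_state(config$comp_seed, config$comp_step),
      message = paste0("demand infeasible under the conversion matrix for: ",
                       paste(bad, collapse = ", "))
    ), class = "allocation_result"))
  }

  state <- new_competitive_state(config$comp_seed, config$comp_step)
  pres_cells <- pres[u + 1L]                 # T(c, t, 0): fixed for this run
  base <- Ploc + pres_cells                  # P_loc + P_res (+ P_nei = 0)
  changes <- list()
  n_changes <- 0L

  pick_candidate <- function() {
    gap <- demand - supply
    dev_now <- sum(pmax(0, abs(gap) - tol))
    Pcomp <- competitive_advantage(state, CA)
    # admissibility & deviation change depend only on the (u, j) class pair;
    # deviation counts only the excess beyond tolerance, so rebalancing moves
    # that shuffle within-tolerance services remain admissible
    dev_after <- matrix(0, 30L, 30L)
    for (d in seq_len(4L)) {
      dev_after <- dev_after +
        pmax(0, abs(gap[d] - outer(-CA[, d], CA[, d], `+`)) - tol[d])
    }
    pair_ok <- (M == 1L) & (dev_after < dev_now - 1e-9)
    diag(pair_ok) <- FALSE
    u_idx <- ifelse(valid, u + 1L, 1L)  # nodata cells masked below
    S <- base + Pcomp[u_idx, , drop = FALSE]
    S[!pair_ok[u_idx, , drop = FALSE]] <- -Inf
    S[!valid | frozen_v, ] <- -Inf
    S[is.na(S)] <- -Inf
    m <- max(S)
    if (!is.finite(m)) return(NULL)
    hits <- which(S == m, arr.ind = TRUE)
    # D19 tie-break: row-major cell index, then class code
    cell_row <- (hits[, 1L] - 1L) %% dims[1L] + 1L
    cell_col <- (hits[, 1L] - 1L) %/% dims[1L] + 1L
    ord <- order((cell_row - 1L) * dims[2L] + cell_col, hits[, 2L])
    h <- hits[ord[1L], ]
    list(cell = h[[1L]], to = h[[2L]] - 1L, row = cell_row[ord[1L]],
         col = cell_col[ord[1L]])
  }

  apply_conversion <- function(cand, phase_iter) {
    from <- u[cand$cell]
    u[cand$cell] <<- cand$to
    supply <<- supply + CA[cand$to + 1L, ] - CA[from + 1L, ]
    n_changes <<- n_changes + 1L
    changes[[n_changes]] <<- c(phase_iter, cand$row, cand$col, from, cand$to)
  }

  converged <- function() all(abs(supply - demand) <= tol)

  # ---- coarse phase: one conversion per internal iteration -----------------
  while (!converged() && state$i <= config$coarse_cap) {
    cand <- pick_candidate()
    if (is.null(cand)) break
    apply_conversion(cand, state$i)
    state <- update_competitive_state(state, demand, supply)
  }
  coarse_iters <- state$i

  # ---- fine phase: visit each cell at most once ----------------------------
  fine_iters <- 0L
  if (!converged() && config$fine_phase) {
    gap <- demand - supply
    Pcomp <- competitive_advantage(state, CA)
    u_idx <- ifelse(valid, u + 1L, 1L)
    S <- base + Pcomp[u_idx, , drop = FALSE]
    best <- apply(S, 1L, function(r) if (all(is.na(r))) -Inf else max(r, na.rm = TRUE))
    visit <- order(best, decreasing = TRUE)
    for (cell in visit) {
      if (converged()) break
      if (!valid[cell] || frozen_v[cell]) next
      fine_iters <- fine_iters + 1L
      gap <- demand - supply
      dev_now <- sum(pmax(0, abs(gap) - tol))
      cur <- u[cell]
      cand_j <- which(M[cur + 1L, ] == 1L) - 1L
      cand_j <- cand_j[cand_j != cur & !is.na(Ploc[cell, cand_j + 1L])]
      if (!length(cand_j)) next
      dev_after <- vapply(cand_j, function(j) {
        sum(pmax(0, abs(gap - (CA[j + 1L, ] - CA[cur + 1L, ])) - tol))
      }, numeric(1))
      ok <- dev_after < dev_now - 1e-9
      if (!any(ok)) next
      Pcomp <- competitive_advantage(state, CA)
      sc <- base[cell, cand_j + 1L] + Pcomp[cur + 1L, cand_j + 1L]
      sc[!ok] <- -Inf
      j <- cand_j[which.max(sc)]
      cand <- list(cell = cell, to = j,
                   row = (cell - 1L) %% dims[1L] + 1L,
                   col = (cell - 1L) %/% dims[1L] + 1L)
      apply_conversion(cand, state$i)
      state <- update_competitive_state(state, demand, supply)
    }
  }

  final <- land_raster(matrix(u, dims[1L], dims[2L]),
                       cell_size = initial$cell_size, xll = initial$xll,
                       yll = initial$yll, layer = "land_system_simulated")
  ok <- converged()
  structure(list(
    final = final,
    changes = changes_tibble(changes),
    converged = ok, infeasible = FALSE,
    supply = supply, demand = demand, tolerance = tol,
    iterations = coarse_iters, fine_iterations = fine_iters,
    state = state,
    message = if (ok) "converged" else
      paste0("not converged: max |supply-demand| = ",
             format(max(abs(supply - demand)), digits = 4), " km2")
  ), class = "allocation_result")
}

empty_changes <- function() {
  tibble::tibble(iteration = integer(), row = integer(), col = integer(),
                 from = integer(), to = integer())
}

changes_tibble <- function(changes) {
  if (!length(changes)) return(empty_changes())
  m <- do.call(rbind, changes)
  tibble::tibble(iteration = as.integer(m[, 1L]), row = as.integer(m[, 2L]),
                 col = as.integer(m[, 3L]), from = as.integer(m[, 4L]),
                 to = as.integer(m[, 5L]))
}

#' @export
print.allocation_result <- function(x, ...) {
  cat("<allocation_result>", x$message, "\n")
  cat(sprintf("  %d conversions in %d coarse + %d fine iterations\n",
              nrow(x$changes), x$iterations, x$fine_iterations))
  gap <- x$supply - x$demand
  for (s in names(gap)) {
    cat(sprintf("  %-10s demand %10.3f  supply %10.3f  gap %+.3f km2\n",
                s, x$demand[s], x$supply[s], gap[s]))
  }
  invisible(x)
}

#' Tidy an allocation result
#'
#' `tidy()` returns the change log (one row per converted cell); `glance()`
#' returns a one-row summary of convergence and the per-service gaps.
#'
#' @param x an `allocation_result` from [allocate()].
#' @param ... unused.
#' @return a tibble.
#' @method tidy allocation_result
#' @export
tidy.allocation_result <- function(x, ...) x$changes

#' @rdname tidy.allocation_result
#' @method glance allocation_result
#' @export
glance.allocation_result <- function(x, ...) {
  tibble::tibble(
    converged = x$converged, infeasible = x$infeasible,
    n_changes = nrow(x$changes), coarse_iterations = x$iterations,
    fine_iterations = x$fine_iterations,
    max_abs_gap_km2 = max(abs(x$supply - x$demand)),
    max_rel_gap = max(abs(x$supply - x$demand) / pmax(x$demand, 1e-12))
  )
}

#' @rdname tidy.allocation_result
#' @param object an `allocation_result`.
#' @method autoplot allocation_result
#' @export
autoplot.allocation_result <- function(object, ...) {
  autoplot.land_raster(object$final, categorical = TRUE)
}


# transitive closure of a 0/1 permission matrix (a cell of class a can end up
# as class b through any chain of allowed conversions)
matrix_closure <- function(M) {
  R <- M > 0
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) return(R)
    R <- R2
  }
}
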