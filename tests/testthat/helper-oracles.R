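# Independent, loop-based oracles used across the suite. These deliberately
# avoid the package's vectorized implementations: naive tallies, exhaustive
# enumeration and step-by-step recomputation from first principles.

# per-block class counting: modal class (lowest code on ties) and its fraction
oracle_block_stats <- function(values, r0, r1, c0, c1) {
  cells <- as.vector(values[r0:r1, c0:c1])
  cells <- cells[!is.na(cells)]
  if (length(cells) == 0L) return(list(type = NA_real_, fraction = NA_real_))
  best_type <- NA_real_; best_count <- -1L
  for (k in sort(unique(cells))) {
    cnt <- sum(cells == k)
    if (cnt > best_count) { best_count <- cnt; best_type <- k }
  }
  list(type = best_type, fraction = best_count / length(cells))
}

# exhaustive 3-class Jenks: enumerate every (i, j) split of the sorted values
# and return the minimal within-class SSD and all optimal break pairs
oracle_jenks3 <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  ssd <- function(v) if (length(v) <= 1L) 0 else sum((v - mean(v))^2)
  best <- Inf; breaks <- list()
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      cost <- ssd(x[1:i]) + ssd(x[(i + 1):j]) + ssd(x[(j + 1):n])
      if (cost < best - 1e-12) {
        best <- cost; breaks <- list(c(x[i], x[j]))
      } else if (cost < best + 1e-12) {
        breaks <- c(breaks, list(c(x[i], x[j])))
      }
    }
  }
  list(ssd = best, breaks = unique(breaks))
}

# within-class SSD achieved by a pair of breakpoints (<= b1 | <= b2 | > b2)
jenks_partition_ssd <- function(x, b) {
  x <- x[!is.na(x)]
  ssd <- function(v) if (length(v) <= 1L) 0 else sum((v - mean(v))^2)
  ssd(x[x <= b[1]]) + ssd(x[x > b[1] & x <= b[2]]) + ssd(x[x > b[2]])
}

# hand-rolled kappa from first principles (per-cell tally, no matrix algebra)
oracle_kappa <- function(obs, sim) {
  stopifnot(length(obs) == length(sim))
  n <- length(obs)
  p0 <- sum(obs == sim) / n
  pc <- 0
  for (k in unique(c(obs, sim))) {
    pc <- pc + (sum(obs == k) / n) * (sum(sim == k) / n)
  }
  (p0 - pc) / (1 - pc)
}

oracle_fom <- function(ini, obs, sim) {
  A <- B <- C <- D <- 0L
  for (i in seq_along(ini)) {
    rc <- obs[i] != ini[i]; sc <- sim[i] != ini[i]
    if (rc && !sc) A <- A + 1L
    else if (rc && sc && sim[i] == obs[i]) B <- B + 1L
    else if (rc && sc) C <- C + 1L
    else if (!rc && sc) D <- D + 1L
  }
  if (A + B + C + D == 0L) return(NA_real_)
  B / (A + B + C + D)
}

# rank-based AUC (Mann-Whitney), independent of any model package
oracle_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Moran's I with rook contiguity on a matrix (naive double loop over edges)
oracle_morans_i <- function(m) {
  z <- m - mean(m)
  num <- 0; W <- 0
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (i < nr) { num <- num + 2 * z[i, j] * z[i + 1, j]; W <- W + 2 }
      if (j < nc) { num <- num + 2 * z[i, j] * z[i, j + 1]; W <- W + 2 }
    }
  }
  (length(m) / W) * num / sum(z^2)
}

# Exhaustive greedy allocator sharing the engine's definitions (ranking,
# admission on excess-beyond-tolerance, tie-break by row-major cell then class)
# but recomputed from scratch each iteration with plain loops. Single-phase
# (coarse only), one conversion per internal iteration.
oracle_greedy_allocate <- function(u_mat, ploc, ca, M, pres, demand, rel_tol = 0.001,
                                   comp_seed = 1, comp_step = 0.001,
                                   max_iter = 5000L) {
  nr <- nrow(u_mat); nc <- ncol(u_mat)
  u <- u_mat
  pres_cells <- matrix(pres[u + 1L], nr, nc)
  tol <- pmax(rel_tol * demand, max(ca))
  counts <- tabulate(as.vector(u) + 1L, nbins = nrow(ca))
  supply <- setNames(as.vector(counts %*% ca), colnames(ca))
  # same feasibility contract as the engine: with multi-step reachability,
  # unreachable demand means no iteration at all
  reach <- M > 0
  repeat {
    r2 <- reach | ((reach %*% reach) > 0)
    if (identical(r2, reach)) break
    reach <- r2
  }
  for (d in seq_len(4L)) {
    per_class <- apply(reach, 1L, function(r) max(ca[r, d]))
    if (demand[d] > sum(per_class[as.vector(u) + 1L]) + 1e-9) {
      return(list(final = u_mat, changes = list(), supply = supply,
                  converged = FALSE))
    }
  }
  inertia <- setNames(numeric(4L), colnames(ca))
  speed <- comp_seed
  tot <- colSums(ca)
  changes <- list()
  it <- 1L
  dev_total <- function(gap) sum(pmax(0, abs(gap) - tol))
  repeat {
    gap <- demand - supply
    if (all(abs(gap) <= tol) || it > max_iter) break
    best <- NULL
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      cur <- u[i, j]
      for (to in 0:(nrow(ca) - 1L)) {
        if (to == cur || M[cur + 1L, to + 1L] != 1L) next
        pl <- ploc[[as.character(to)]]
        if (is.null(pl) || is.na(pl[i, j])) next
        gap_after <- gap - (ca[to + 1L, ] - ca[cur + 1L, ])
        if (!(dev_total(gap_after) < dev_total(gap) - 1e-9)) next
        pcomp <- 0
        for (d in seq_len(4L)) {
          if (inertia[d] != 0) {
            pcomp <- pcomp + inertia[d] * (ca[to + 1L, d] - ca[cur + 1L, d]) / tot[d]
          }
        }
        score <- (pl[i, j] + pres_cells[i, j]) + pcomp
        key <- c((i - 1L) * nc + j, to)
        if (is.null(best) || score > best$score ||
            (score == best$score &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, to = to, score = score, key = key)
        }
      }
    }
    if (is.null(best)) break
    from <- u[best$i, best$j]
    u[best$i, best$j] <- best$to
    supply <- supply + ca[best$to + 1L, ] - ca[from + 1L, ]
    changes[[length(changes) + 1L]] <-
      c(it, best$i, best$j, from, best$to)
    speed <- speed + comp_step
    inertia <- inertia + (demand - supply) / speed
    it <- it + 1L
  }
  list(final = u, changes = changes, supply = supply,
       converged = all(abs(demand - supply) <= tol))
}

# small helpers for building fixtures -----------------------------------------
rast <- function(m, cell_size = 30, ...) land_raster(as.matrix(m), cell_size, ...)

const_suit <- function(template, classes, value = 0.5) {
  out <- lapply(classes, function(j) {
    land_raster(matrix(value, nrow(template$values), ncol(template$values)),
                cell_size = template$cell_size, xll = template$xll,
                yll = template$yll)
  })
  names(out) <- as.character(classes)
  out
}

# a random single-service allocation instance on an n x n grid
random_single_service_instance <- function(n, n_classes = 4L, seed = 1L) {
  set.seed(seed)
  classes <- 0:(n_classes - 1L)
  u <- matrix(sample(classes, n * n, replace = TRUE), n, n)
  ca <- matrix(0, 30L, 4L, dimnames = list(0:29, unname(tipland::services())))
  ca[classes + 1L, 1L] <- round(runif(n_classes, 0.1, 1), 3)
  M <- matrix(0L, 30L, 30L, dimnames = list(0:29, 0:29))
  diag(M) <- 1L
  for (a in classes) for (b in classes) {
    if (a != b && runif(1) < 0.6) M[a + 1L, b + 1L] <- 1L
  }
  pres <- numeric(30L)
  pres[classes + 1L] <- round(runif(n_classes, 0, 0.5), 3)
  suit <- lapply(classes, function(j) {
    land_raster(matrix(round(runif(n * n), 3), n, n), cell_size = 990)
  })
  names(suit) <- as.character(classes)
  initial <- land_raster(u, cell_size = 990)
  counts <- tabulate(u + 1L, nbins = 30L)
  supply0 <- as.vector(counts %*% ca)
  demand <- setNames(supply0, colnames(ca))
  # perturb the active service by a few random cell-capacity quanta
  demand[1L] <- demand[1L] +
    sum(sample(ca[classes + 1L, 1L], sample(2:5, 1L), replace = TRUE)) *
    sample(c(-1, 1), 1L)
  demand[1L] <- max(demand[1L], 0.5 * supply0[1L])
  list(initial = initial, suit = suit, ca = ca, M = M, pres = pres,
       demand = demand)
}
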