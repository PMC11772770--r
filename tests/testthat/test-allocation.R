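test_that("conversion matrix records observed transitions plus the diagonal", {
  m1 <- land_raster(matrix(c(3, 3, 6, 6), 2, 2), 990)
  M <- derive_conversion_matrix(m1, m1)
  expect_equal(sum(M) - 30L, 0L)  # identity-only off-diagonal

  m2 <- land_raster(matrix(c(0, 3, 6, 6), 2, 2), 990)
  M2 <- derive_conversion_matrix(m1, m2)
  expect_equal(M2["3", "0"], 1L)
  expect_equal(sum(M2[row(M2) != col(M2)]), 1L)

  # random pair vs brute-force transition enumeration
  set.seed(17)
  a <- matrix(sample(0:11, 100, replace = TRUE), 10, 10)
  b <- matrix(sample(0:11, 100, replace = TRUE), 10, 10)
  M3 <- derive_conversion_matrix(land_raster(a, 990), land_raster(b, 990))
  for (f in 0:11) for (t in 0:11) {
    seen <- any(a == f & b == t)
    expect_equal(M3[f + 1, t + 1] == 1L, seen || f == t)
  }
})

test_that("resistance equals observed persistence with a default for unseen classes", {
  a <- matrix(c(rep(4, 10), rep(7, 5)), 3, 5)
  b <- a; b[c(1, 2)] <- 9  # 2 of 10 class-4 cells convert
  suppressMessages({
    r <- estimate_resistance(land_raster(a, 990), land_raster(b, 990))
  })
  expect_equal(r$resistance[r$class == 4], 0.8)
  expect_equal(r$resistance[r$class == 7], 1.0)   # fully persistent
  expect_equal(r$resistance[r$class == 9], 0.5)   # unseen at y1 -> default
  b2 <- a; b2[a == 7] <- 1
  suppressMessages(r2 <- estimate_resistance(land_raster(a, 990),
                                             land_raster(b2, 990)))
  expect_equal(r2$resistance[r2$class == 7], 0.0) # fully turned over
})

test_that("conversion potential is the plain sum of its four components", {
  expect_equal(conversion_potential(0.5, 0.2, 0, 0.1), 0.8)
  expect_equal(conversion_potential(c(0.1, 0.3), 0.2), c(0.3, 0.5))
})

test_that("competitive state follows the seed/step speed sequence and accumulates inertia", {
  st <- new_competitive_state()
  expect_equal(st$speed, 1)
  expect_equal(unname(st$inertia), rep(0, 4))
  demand <- c(cropland = 100, forest = 50, grassland = 10, shrubland = 5)
  supply <- c(cropland = 90, forest = 50, grassland = 10, shrubland = 5)
  st2 <- update_competitive_state(st, demand, supply)
  expect_equal(st2$speed, 1.001)
  expect_equal(st2$inertia[["cropland"]], 10 / 1.001)
  st3 <- update_competitive_state(st2, demand, supply)
  expect_equal(st3$speed, 1.002)
  expect_equal(st3$inertia[["cropland"]], 10 / 1.001 + 10 / 1.002)
  # equilibrium: supply == demand keeps inertia at zero
  st_eq <- update_competitive_state(st, demand, demand)
  expect_equal(unname(st_eq$inertia), rep(0, 4))
  expect_error(new_competitive_state(seed = 0), "positive")
})

test_that("competitive advantage evaluates the inertia-weighted marginal gain", {
  ca <- matrix(0, 30, 4, dimnames = list(0:29, unname(services())))
  ca[1:3, 1] <- c(2, 1, 2)  # classes 0..2 supply cropland; total 5
  st <- new_competitive_state()
  expect_true(all(competitive_advantage(st, ca) == 0))  # zero inertia
  st$inertia[] <- 0
  st$inertia["cropland"] <- 10
  # inertia 10, CA_j = 2, CA_u = 1, sum CA = 5 -> 10 * (2 - 1) / 5 = 2
  expect_equal(competitive_advantage(st, ca, from = 1, to = 0), 2)
  expect_equal(competitive_advantage(st, ca, from = 1, to = 1), 0)  # j = u
  st$inertia["forest"] <- 3
  expect_error(competitive_advantage(st, ca), "unservable")
})

test_that("allocation at equilibrium demand makes zero changes", {
  set.seed(2)
  u <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  initial <- land_raster(u, cell_size = 990)
  ca <- matrix(0, 30, 4, dimnames = list(0:29, unname(services())))
  ca[1:4, ] <- round(runif(16), 2)
  M <- matrix(1L, 30, 30, dimnames = list(0:29, 0:29))
  pres <- rep(0.2, 30)
  counts <- tabulate(u + 1L, nbins = 30)
  demand <- setNames(as.vector(counts %*% ca), colnames(ca))
  res <- allocate(initial, const_suit(initial, 0:3), demand, ca, M, pres)
  expect_true(res$converged)
  expect_equal(nrow(res$changes), 0L)
  expect_equal(res$iterations, 1L)
  expect_identical(res$final$values, initial$values)
})

test_that("demand beyond total convertible capacity reports infeasibility without iterating", {
  u <- matrix(0L, 5, 5)
  initial <- land_raster(u, cell_size = 990)
  ca <- matrix(0, 30, 4, dimnames = list(0:29, unname(services())))
  ca[1, 1] <- 0.5; ca[2, 2] <- 0.9
  M <- diag(30); dimnames(M) <- list(0:29, 0:29)  # nothing can convert
  demand <- c(cropland = 12.5, forest = 10, grassland = 0, shrubland = 0)
  res <- allocate(initial, const_suit(initial, 0:1), demand, ca, M, rep(0, 30))
  expect_true(res$infeasible)
  expect_false(res$converged)
  expect_equal(nrow(res$changes), 0L)
  expect_match(res$message, "forest")
})

test_that("a gradient toy converts exactly the k top-ranked eligible cells", {
  # cropland demand raised by exactly k cells' capacity over a strict
  # suitability gradient: the k best eligible cells must flip, nothing else
  n <- 10L; k <- 7L
  u <- matrix(1L, n, n)  # all forest-ish class 1
  initial <- land_raster(u, cell_size = 990)
  ca <- matrix(0, 30, 4, dimnames = list(0:29, unname(services())))
  ca[1, "cropland"] <- 1     # class 0 supplies cropland
  ca[2, "forest"] <- 1       # class 1 supplies forest
  M <- diag(30); dimnames(M) <- list(0:29, 0:29)
  M[2, 1] <- 1               # forest -> cropland allowed
  grad <- matrix(seq(0, 1, length.out = n * n), n, n)  # strict gradient
  suit <- list(`0` = land_raster(grad, cell_size = 990))
  demand <- c(cropland = k, forest = n * n - k, grassland = 0, shrubland = 0)
  res <- allocate(initial, suit, demand, ca, M, rep(0, 30),
                  allocation_config(rel_tol = 1e-9, abs_floor = 0.5))
  expect_true(res$converged)
  expect_equal(nrow(res$changes), k)
  converted <- res$final$values == 0L
  expect_equal(sum(converted), k)
  # exactly the k largest gradient cells converted
  expect_setequal(grad[converted], sort(grad, decreasing = TRUE)[1:k])
})

test_that("allocation equals the exhaustive greedy oracle on random single-service instances", {
  for (seed in 1:8) {
    inst <- random_single_service_instance(n = sample(6:12, 1), seed = seed)
    res <- allocate(inst$initial, inst$suit, inst$demand, inst$ca, inst$M,
                    inst$pres, allocation_config(fine_phase = FALSE))
    o <- oracle_greedy_allocate(inst$initial$values, inst$suit |>
                                  lapply(function(r) r$values),
                                inst$ca, inst$M, inst$pres, inst$demand)
    expect_identical(res$final$values, o$final)
    expect_equal(res$converged, o$converged)
    expect_equal(nrow(res$changes), length(o$changes))
  }
})

test_that("allocation respects the conversion matrix, conserves cells and audits supply", {
  set.seed(33)
  u <- matrix(sample(0:5, 144, replace = TRUE), 12, 12)
  u[1, 1] <- NA
  initial <- land_raster(u, cell_size = 990)
  ca <- matrix(0, 30, 4, dimnames = list(0:29, unname(services())))
  ca[1:6, ] <- round(matrix(runif(24), 6, 4), 2)
  M <- matrix(0L, 30, 30, dimnames = list(0:29, 0:29)); diag(M) <- 1L
  for (a in 0:5) for (b in 0:5) if (runif(1) < 0.5) M[a + 1, b + 1] <- 1L
  pres <- runif(30, 0, 0.5)
  counts <- tabulate(u[!is.na(u)] + 1L, nbins = 30)
  demand <- setNames(as.vector(counts %*% ca), colnames(ca))
  demand["cropland"] <- demand["cropland"] * 1.1
  demand["forest"] <- demand["forest"] * 0.92
  res <- allocate(initial, const_suit(initial, 0:5, 0.3), demand, ca, M, pres)
  # every logged change is a permitted transition
  expect_true(all(M[cbind(res$changes$from + 1L, res$changes$to + 1L)] == 1L))
  # nodata cells never change; valid cell count conserved
  expect_true(is.na(res$final$values[1, 1]))
  expect_equal(sum(!is.na(res$final$values)), sum(!is.na(u)))
  # supply recomputed from scratch equals the incrementally tracked supply
  counts2 <- tabulate(res$final$values[!is.na(res$final$values)] + 1L, nbins = 30)
  expect_equal(as.vector(counts2 %*% ca), unname(res$supply))
})

test_that("frozen cells never change", {
  inst <- random_single_service_instance(10, seed = 42)
  frozen <- land_raster(matrix(0, 10, 10), cell_size = 990)
  frozen$values[1:5, ] <- 1
  res <- allocate(inst$initial, inst$suit, inst$demand, inst$ca, inst$M,
                  inst$pres, frozen = frozen)
  expect_identical(res$final$values[1:5, ], inst$initial$values[1:5, ])
  expect_true(all(res$changes$row > 5))
})

test_that("identical inputs give byte-identical change logs", {
  inst <- random_single_service_instance(10, seed = 11)
  r1 <- allocate(inst$initial, inst$suit, inst$demand, inst$ca, inst$M, inst$pres)
  r2 <- allocate(inst$initial, inst$suit, inst$demand, inst$ca, inst$M, inst$pres)
  expect_identical(r1$changes, r2$changes)
  expect_identical(r1$final$values, r2$final$values)
})

test_that("converged supply responds monotonically to rising single-service demand", {
  inst <- random_single_service_instance(10, seed = 23)
  base <- inst$demand
  got <- numeric(0)
  for (mult in c(1.00, 1.02, 1.04)) {
    d <- base; d[1] <- base[1] * mult
    res <- allocate(inst$initial, inst$suit, d, inst$ca, inst$M, inst$pres)
    got <- c(got, res$supply[1])
  }
  expect_true(all(diff(got) >= -1e-9))
})

test_that("tidy/glance expose the change log and convergence summary", {
  inst <- random_single_service_instance(8, seed = 2)
  res <- allocate(inst$initial, inst$suit, inst$demand, inst$ca, inst$M, inst$pres)
  expect_named(tidy(res), c("iteration", "row", "col", "from", "to"))
  gl <- glance(res)
  expect_equal(gl$n_changes, nrow(res$changes))
  expect_true(is.logical(gl$converged))
})
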