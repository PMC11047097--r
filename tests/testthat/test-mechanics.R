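# Contact mechanics kernels against closed-form oracles.

cellA <- function(...) {
  c0 <- list(x = 0, y = 0, angle = 0, length = 2, radius = 0.5, id = 1)
  mod <- list(...)
  c0[names(mod)] <- mod
  c0
}

test_that("pair_repulsion follows the Hertzian law F = k o^1.5", {
  # parallel horizontal cells, vertical gap 0.9 -> overlap 0.1
  A <- cellA()
  B <- cellA(y = 0.9, id = 2)
  out <- pair_repulsion(A, B, k_cell = 1e5)
  expect_equal(sqrt(sum(out$forceA^2)), 1e5 * 0.1^1.5, tolerance = 1e-9)
  expect_equal(out$forceA, -out$forceB)
  expect_lt(out$forceA[2], 0)  # A pushed down, away from B

  # no contact -> exactly zero
  far <- pair_repulsion(A, cellA(y = 3, id = 2), 1e5)
  expect_identical(far$forceA, c(0, 0))
  expect_identical(far$torqueA, 0)
})

test_that("pair forces are antisymmetric for random configurations", {
  set.seed(7)
  for (i in 1:200) {
    A <- cellA(x = runif(1, -1, 1), y = runif(1, -1, 1),
               angle = runif(1, 0, 2 * pi), length = runif(1, 2, 4), id = i)
    B <- cellA(x = runif(1, -1, 1), y = runif(1, -1, 1),
               angle = runif(1, 0, 2 * pi), length = runif(1, 2, 4),
               id = i + 1000)
    out <- pair_repulsion(A, B, k_cell = 2e4)
    expect_equal(out$forceA + out$forceB, c(0, 0), tolerance = 1e-9)
  }
})

test_that("coincident centerlines use a deterministic tie-break", {
  A <- cellA(); B <- cellA(id = 2)
  o1 <- pair_repulsion(A, B, 1e4)
  o2 <- pair_repulsion(A, B, 1e4)
  expect_identical(o1, o2)
  expect_gt(sqrt(sum(o1$forceA^2)), 0)
  # force perpendicular to the (shared) axis
  expect_equal(o1$forceA[1], 0, tolerance = 1e-12)
})

test_that("wall_forces follows the linear law at sampled contact points", {
  flat <- well_spec(flat = TRUE)
  # horizontal cell, center height 0.4, radius 0.5: all 3 sample points
  # penetrate 0.1 -> upward force 3*k*0.1 (caps + midpoint), zero torque
  out <- wall_forces(cellA(x = 50, y = 0.4), flat, k_wall = 1e5)
  expect_equal(out$force, c(0, 3 * 1e5 * 0.1), tolerance = 1e-9)
  expect_equal(out$torque, 0, tolerance = 1e-9)

  # interior cell: zero
  out0 <- wall_forces(cellA(x = 50, y = 30), flat, 1e5)
  expect_identical(out0$force, c(0, 0))

  # tilted cell with one cap in the wall: torque rotates it away
  tl <- wall_forces(cellA(x = 50, y = 0.9, angle = -0.7), flat, 1e5)
  expect_gt(tl$force[2], 0)
  expect_true(abs(tl$torque) > 0)
  # right cap is the penetrating one (angle -0.7) -> positive torque (CCW)
  expect_gt(tl$torque, 0)
})

test_that("adhesion springs create, pull only under extension, and break", {
  spec <- well_spec(flat = TRUE)
  p <- physics_params(adhesion = TRUE, epsilon_max = 0.05)
  # cell touching the bottom: spring created at the nearest contact
  st1 <- adhesion_forces(cellA(x = 50, y = 0.45), NULL, spec, p)
  expect_equal(nrow(st1$springs), 1)
  expect_equal(st1$springs$rest_length, 0.45, tolerance = 1e-9)
  expect_equal(st1$force, c(0, 0))  # at rest on creation

  # lift the cell: extension 0.02 of rest 0.45 -> eps = 0.044 < 0.05, holds
  held <- adhesion_forces(cellA(x = 50, y = 0.47), st1$springs, spec, p)
  expect_equal(nrow(held$springs), 1)
  expect_equal(held$force[2], -p$k_adhesion * 0.02, tolerance = 1e-6)

  # rest 0.45, eps_max 5%: extension 0.0225 is the threshold
  ok <- adhesion_forces(cellA(x = 50, y = 0.45 + 0.022), st1$springs, spec, p)
  expect_equal(nrow(ok$springs), 1)
  broken <- adhesion_forces(cellA(x = 50, y = 0.45 + 0.023), st1$springs,
                            spec, p)
  expect_equal(nrow(broken$springs), 0)

  # compression: no force
  comp <- adhesion_forces(cellA(x = 50, y = 0.40), st1$springs, spec, p)
  expect_equal(comp$force, c(0, 0))

  # far from any wall: nothing happens
  none <- adhesion_forces(cellA(x = 50, y = 30), NULL, spec, p)
  expect_equal(nrow(none$springs), 0)
  expect_equal(none$force, c(0, 0))
})

test_that("momentum bookkeeping: summed pair forces cancel in a crowd", {
  set.seed(11)
  n <- 60
  cells <- data.frame(
    x = runif(n, 2, 28), y = runif(n, 2, 28),
    angle = runif(n, 0, 2 * pi), length = runif(n, 2, 4))
  st <- mk_state(cells, well_spec(width = 30, height = 30, flat = TRUE))
  fm <- pair_force_matrix(st)
  expect_lt(max(abs(colSums(fm))), 1e-6)
  expect_gt(max(abs(fm)), 0)  # the configuration does contain contacts
})
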