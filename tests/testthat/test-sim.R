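# Simulator behavior at reduced scale: initialization, growth/division,
# relaxation, conservation, removal, reproducibility.

small_spec <- well_spec(width = 30, height = 15, flat = TRUE)

test_that("sim_init places distinct, non-overlapping founders", {
  st <- sim_init(small_spec, test_params(), n_cells = 40,
                 strain_mix = c(neutralA = 0.5, neutralB = 0.5), seed = 3)
  expect_equal(nrow(st$cells), 40)
  expect_equal(length(unique(st$cells$genotype)), 40)
  expect_equal(st$cells$genotype, st$cells$founder_id)
  expect_gte(corrugo:::cpp_min_separation(st), 0)
  expect_true(all(st$cells$length >= 2 & st$cells$length < 4))
  # strain counts are a fair binomial draw (loose 4-sigma band)
  nB <- sum(st$cells$strain_i == 2)
  expect_true(nB >= 20 - 4 * sqrt(10) && nB <= 20 + 4 * sqrt(10))
  # single founder also works
  st1 <- sim_init(small_spec, test_params(), n_cells = 1, seed = 1)
  expect_equal(nrow(st1$cells), 1)
  # impossible packings abort
  expect_error(sim_init(well_spec(width = 6, height = 6, flat = TRUE),
                        test_params(), n_cells = 100, seed = 1),
               "could not place")
})

test_that("growth is exponential with the strain's fitness multiplier", {
  st <- sim_init(small_spec, test_params(), n_cells = 10, seed = 5)
  st$cells$length <- 2  # below division threshold throughout
  st$cells$growth_multiplier <- rep(c(1, 1.5), 5)
  dt <- 0.1
  g2 <- grow_and_divide(st, dt)
  dlog <- log(g2$cells$length) - log(st$cells$length)
  expect_equal(dlog[2] / dlog[1], 1.5, tolerance = 1e-12)
  expect_equal(dlog[1], st$params$elongation_rate * dt, tolerance = 1e-12)
  # zero elongation: nothing but time changes
  p0 <- test_params(elongation_rate = 0)
  st0 <- sim_init(small_spec, p0, n_cells = 5, seed = 2)
  g0 <- grow_and_divide(st0, 0.5)
  expect_identical(g0$cells$length, st0$cells$length)
  expect_equal(g0$time, 0.5)
})

test_that("division conserves centerline length and inheritance", {
  st <- sim_init(small_spec, test_params(), n_cells = 3, seed = 7)
  st$cells$length <- c(3.99, 2.5, 3.8)
  st$cells$genotype <- c(11L, 12L, 13L)
  g <- grow_and_divide(st, 0.1)  # pushes the first and third over l_div
  expect_gt(nrow(g$cells), 3)
  for (gt in c(11L, 13L)) {
    daughters <- g$cells[g$cells$genotype == gt, ]
    expect_equal(nrow(daughters), 2)
    parent_len <- st$cells$length[st$cells$genotype == gt] *
      exp(st$params$elongation_rate * 0.1)
    expect_equal(sum(daughters$length), parent_len, tolerance = 1e-9)
    expect_equal(daughters$length[1], daughters$length[2])
  }
  # fresh ids for daughters
  expect_false(any(g$cells$id[g$cells$genotype == 11L] %in% st$cells$id))
})

test_that("an isolated cell without growth does not move", {
  p <- test_params(elongation_rate = 0)
  st <- sim_init(small_spec, p, n_cells = 1, seed = 9)
  st2 <- sim_step(st, n_steps = 50)
  expect_equal(st2$cells$x, st$cells$x, tolerance = 1e-12)
  expect_equal(st2$cells$y, st$cells$y, tolerance = 1e-12)
})

test_that("overlapping cells relax apart and energy decreases", {
  p <- test_params(elongation_rate = 0)
  st <- sim_init(small_spec, p, n_cells = 1, seed = 1)
  # plant two overlapping cells mid-well (0.1 um overlap, slight offset so
  # the closest-point pair is unambiguous)
  st$cells <- rbind(st$cells, st$cells)
  st$cells$id <- 1:2
  st$cells$x <- c(15, 15.3); st$cells$y <- c(7, 7.9)
  st$cells$angle <- c(0, 0); st$cells$length <- c(3, 3)
  energies <- numeric(40)
  seps <- numeric(40)
  for (i in 1:40) {
    st <- sim_step(st)
    energies[i] <- total_elastic_energy(st)
    seps[i] <- corrugo:::cpp_min_separation(st)
  }
  # energy is the Lyapunov function of the relaxation; the minimum
  # separation itself may wiggle while the rods rotate apart
  expect_true(all(diff(energies) <= 1e-9))
  expect_gt(seps[40], -0.05)
  expect_gt(seps[40], seps[1])
})

test_that("cells escaping through the open top are removed and counted", {
  p <- test_params(elongation_rate = 0)
  st <- sim_init(small_spec, p, n_cells = 5, seed = 11)
  st$cells$y[1] <- small_spec$height + 0.5  # force one cell out
  st2 <- sim_step(st)
  expect_equal(nrow(st2$cells), 4)
  expect_equal(st2$removed_count, 1)
  expect_gt(st2$removed_area, 0)
})

test_that("runs are reproducible given the seed and genotypes never appear", {
  spec <- well_spec(width = 24, height = 12, period_T = 12, amplitude_A = 4)
  run1 <- quick_run(spec, t_end = 6, seed = 13, n_cells = 20,
                    snapshot_every = 2)
  run2 <- quick_run(spec, t_end = 6, seed = 13, n_cells = 20,
                    snapshot_every = 2)
  fin1 <- run1[[length(run1)]]
  fin2 <- run2[[length(run2)]]
  expect_identical(fin1$cells$x, fin2$cells$x)
  expect_identical(fin1$cells$genotype, fin2$cells$genotype)
  # no mutation: genotype sets only shrink along the run
  genos <- lapply(run1, function(s) unique(s$cells$genotype))
  for (i in seq_along(genos)[-1])
    expect_true(all(genos[[i]] %in% genos[[i - 1]]))
  # t_end = 0 returns the initial state only
  r0 <- quick_run(spec, t_end = 0, seed = 1, n_cells = 5)
  expect_length(r0, 1)
  expect_equal(r0[[1]]$time, 0)
})

test_that("the stability guard reports displacement blowups", {
  # absurd stiffness with adaptivity off must abort, not silently continue
  p <- test_params(k_cell = 1e12, dt = 1)
  st <- sim_init(small_spec, p, n_cells = 1, seed = 1)
  st$cells <- rbind(st$cells, st$cells)
  st$cells$id <- 1:2
  st$cells$x <- c(15, 15); st$cells$y <- c(7, 7.5); st$cells$angle <- c(0, 0)
  expect_error(sim_step(st, adaptive = FALSE), "unstable")
})
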