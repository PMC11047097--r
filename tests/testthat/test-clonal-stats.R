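test_that("clone_census counts genotypes and normalizes fractions", {
  spec <- well_spec(flat = TRUE)
  st <- mk_state(data.frame(x = c(10, 20, 30), y = 5,
                            genotype = c(7L, 7L, 7L)), spec)
  cc <- clone_census(st)
  expect_equal(cc$n_clones, 1)
  expect_equal(unname(cc$fractions), 1)
  st2 <- mk_state(data.frame(x = seq(5, 95, length.out = 10), y = 5,
                             genotype = c(rep(1L, 6), rep(2L, 4))), spec)
  cc2 <- clone_census(st2)
  expect_equal(cc2$n_clones, 2)
  expect_equal(sum(cc2$fractions), 1)
  expect_equal(unname(cc2$fractions["1"]), 0.6)
  empty <- st
  empty$cells <- empty$cells[0, ]
  expect_error(clone_census(empty), "empty")
})

test_that("transect picks up the nearest overlapping cell", {
  spec <- well_spec(width = 40, height = 20, flat = TRUE)
  # two half-wells of two clones: horizontal cells packed along y = 2
  cells <- data.frame(
    x = seq(1, 39, by = 2), y = 2, angle = 0, length = 2,
    genotype = rep(c(1L, 2L), each = 10),
    strain_i = rep(c(1L, 2L), each = 10))
  st <- mk_state(cells, spec)
  pr <- transect(st, offset = 2, spacing = 0.5)
  occ <- !is.na(pr$labels)
  expect_true(any(occ))
  expect_equal(sort(unique(pr$labels[occ])), c(1L, 2L))
  # exactly one label change
  runs <- rle(pr$labels[occ])
  expect_equal(length(runs$values), 2)
  # frequencies mirror the strain assignment
  expect_equal(unname(pr$f1[occ]),
               as.numeric(pr$labels[occ] == 1L))
})

test_that("boundary_density normalizes and localizes boundaries", {
  # single boundary at x = 50 of a width-100 profile
  prof <- sector_profile(seq(0.5, 99.5, by = 1),
                         labels = rep(c(1L, 2L), each = 50), width = 100)
  bd <- boundary_density(prof, n_bins = 50)
  expect_false(bd$empty)
  expect_equal(sum(bd$density * diff(bd$breaks)), 1, tolerance = 1e-9)
  expect_lt(abs(bd$mids[which.max(bd$density)] - 0.5), 0.011)
  # unoccupied gap does not create a boundary
  lab <- rep(c(1L, 2L), each = 50)
  lab[49:52] <- NA
  bd2 <- boundary_density(sector_profile(seq(0.5, 99.5, 1), labels = lab,
                                         width = 100))
  expect_true(bd2$empty)
  expect_equal(bd2$n_boundaries, 0L)
})

test_that("mean_sector_size averages run lengths", {
  pos <- seq(0.5, 99.5, by = 1)
  expect_equal(mean_sector_size(sector_profile(pos, labels = rep(1L, 100),
                                               width = 100)), 1,
               tolerance = 0.01)
  lab11 <- as.integer(ceiling(seq_along(pos) / (100 / 11)))
  expect_equal(mean_sector_size(sector_profile(pos, labels = lab11,
                                               width = 100)), 1 / 11,
               tolerance = 0.01)
  lab2 <- c(rep(1L, 30), rep(2L, 70))
  expect_equal(mean_sector_size(sector_profile(pos, labels = lab2,
                                               width = 100)), 0.5,
               tolerance = 0.01)
  expect_error(mean_sector_size(sector_profile(pos,
                                               labels = rep(NA_integer_, 100),
                                               width = 100)), "unoccupied")
})

test_that("heterozygosity reproduces the printed reference values", {
  n <- 100
  even <- sector_profile(1:n, f1 = rep(0.5, n), width = n)
  expect_identical(heterozygosity(even), 0.25)
  mono <- sector_profile(1:n, f1 = rep(1, n), width = n)
  expect_identical(heterozygosity(mono), 0)
  skew <- sector_profile(1:n, f1 = rep(0.75, n), width = n)
  expect_equal(heterozygosity(skew), 0.1875)
  # bounds and the attainment condition, random profiles
  set.seed(3)
  for (i in 1:50) {
    f1 <- runif(n)
    h <- heterozygosity(sector_profile(1:n, f1 = f1, width = n))
    expect_true(h >= 0 && h <= 0.25)
  }
})

test_that("intensity_to_freqs normalizes and applies the occupancy floor", {
  out <- intensity_to_freqs(c(100, 300, 0), c(100, 100, 0))
  expect_equal(out$f1[1:2], c(0.5, 0.75))
  expect_true(is.na(out$f1[3]))
  expect_error(intensity_to_freqs(c(-1, 2), c(1, 1)), "nonnegative")
})

test_that("theory_clone_count evaluates (T + width)/T", {
  expect_equal(theory_clone_count(well_spec(period_T = 10,
                                            amplitude_A = 5))$n_clones, 11)
  t100 <- theory_clone_count(well_spec(period_T = 100, amplitude_A = 5))
  expect_equal(t100$n_clones, 2)
  expect_equal(t100$fraction, 0.5)
  expect_equal(theory_clone_count(well_spec(period_T = 50,
                                            amplitude_A = 8.7))$n_clones, 3)
  expect_error(theory_clone_count(well_spec(flat = TRUE)), "flat")
})
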