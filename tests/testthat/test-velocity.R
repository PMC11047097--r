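test_that("divergence of sampled linear fields is exact on interior bins", {
  f <- synthetic_field("linear_shear", list(g0 = 0.3), spacing = 2)
  g <- growth_rate_field(f)
  expect_equal(max(abs(g - 0.3)), 0, tolerance = 1e-12)

  r <- synthetic_field("rotation", list(omega = 0.2), spacing = 2)
  expect_equal(max(abs(growth_rate_field(r))), 0, tolerance = 1e-12)

  d <- synthetic_field("divergent", list(alpha = 0.2, beta = 0.1), spacing = 2)
  expect_equal(max(abs(growth_rate_field(d) - 0.3)), 0, tolerance = 1e-12)
})

test_that("divergence of a noisy shear field is unbiased", {
  # Monte-Carlo oracle: mean over noise draws approaches the true rate
  g0 <- 0.3
  ests <- vapply(1:100, function(s) {
    f <- synthetic_field("perturbed", list(g0 = g0, sigma = 0.05),
                         spacing = 2, seed = s)
    mean(growth_rate_field(f), na.rm = TRUE)
  }, numeric(1))
  expect_equal(mean(ests), g0, tolerance = 0.01)
  expect_lt(sd(ests), 0.02)
})

test_that("stratified profiles recover a linear shear exactly", {
  spec <- well_spec(width = 40, height = 40, flat = TRUE)
  f <- synthetic_field("linear_shear", list(g0 = 0.25), spacing = 2)
  sp <- stratified_profiles(f, spec, n_strata = 10)
  # stratum centers are bin midpoints, not occupancy-weighted means, so the
  # slope is recovered approximately; linearity itself is exact
  fit <- lm(vy ~ d, data = sp)
  expect_equal(unname(coef(fit)[2]), 0.25, tolerance = 0.1)
  expect_gt(suppressWarnings(summary(fit))$r.squared, 0.999)
  expect_true(all(sp$hfrac[!is.na(sp$hfrac)] < 1e-9))
})

test_that("velocity_field matches ids and averages displacements", {
  spec <- well_spec(width = 20, height = 20, flat = TRUE)
  cells <- data.frame(x = c(5, 15), y = c(5, 15), angle = 0, length = 2)
  s0 <- mk_state(cells, spec, time = 0)
  s1 <- s0
  s1$time <- 0.5
  s1$cells$x <- s1$cells$x + c(1, 0)
  s1$cells$y <- s1$cells$y + c(0, 2)
  f <- velocity_field(s0, s1, spacing = 4)
  occ <- which(f$mask, arr.ind = TRUE)
  expect_equal(nrow(occ), 2)
  expect_equal(sort(f$vx[f$mask]), c(0, 2))
  expect_equal(sort(f$vy[f$mask]), c(0, 4))
  # static -> zero field
  s2 <- s0; s2$time <- 1
  fz <- velocity_field(s0, s2, spacing = 4)
  expect_true(all(abs(fz$vx[fz$mask]) < 1e-12))
})

test_that("velocity field CSV round-trips exactly", {
  f <- synthetic_field("perturbed", list(g0 = 0.3, sigma = 0.1), spacing = 2,
                       seed = 9)
  path <- tempfile(fileext = ".csv")
  write_velocity_field(f, path)
  g <- read_velocity_field(path)
  expect_identical(f$vx, g$vx)
  expect_identical(f$vy, g$vy)
  expect_equal(f$counts, g$counts, ignore_attr = TRUE)
  expect_identical(f$spacing, g$spacing)
  unlink(path)
})
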