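test_that("sector fixtures plant equal sectors and known boundaries", {
  prof <- make_sector_fixture(11, width = 100, noise = 0)
  expect_equal(mean_sector_size(prof), 1 / 11, tolerance = 0.01)
  expect_length(attr(prof, "true_boundaries"), 10)

  single <- make_sector_fixture(1, width = 100)
  expect_true(boundary_density(single)$empty)

  # determinism given seed
  a <- make_sector_fixture(5, noise = 0.1, seed = 42)
  b <- make_sector_fixture(5, noise = 0.1, seed = 42)
  expect_identical(a$labels, b$labels)
})

test_that("noisy fixtures still localize boundary peaks (Monte Carlo)", {
  truth <- attr(make_sector_fixture(4, width = 100), "true_boundaries") / 100
  profs <- lapply(1:100, function(s)
    make_sector_fixture(4, width = 100, noise = 0.05, seed = s))
  bd <- boundary_density(profs, n_bins = 50)
  expect_equal(sum(bd$density * diff(bd$breaks)), 1, tolerance = 1e-9)
  # the three highest-density bins sit within one bin of the true boundaries
  top <- order(bd$density, decreasing = TRUE)[1:3]
  for (b in bd$mids[top])
    expect_lt(min(abs(b - truth)), 0.02 + 1e-9)
})

test_that("intensity fixtures reproduce the reference heterozygosities", {
  fx <- make_intensity_fixture(rep(0.5, 200), noise_sd = 0)
  fr <- intensity_to_freqs(fx$I1, fx$I2)
  prof <- sector_profile(1:200, f1 = fr$f1, f2 = fr$f2, width = 200)
  expect_equal(heterozygosity(prof), 0.25)

  fx1 <- make_intensity_fixture(rep(1, 200), noise_sd = 0)
  fr1 <- intensity_to_freqs(fx1$I1, fx1$I2)
  expect_equal(heterozygosity(sector_profile(1:200, f1 = fr1$f1,
                                             f2 = fr1$f2, width = 200)), 0)

  # noise only reduces H below the perfectly mixed maximum
  hs <- vapply(1:25, function(s) {
    fx <- make_intensity_fixture(rep(0.5, 200), noise_sd = 30, seed = s)
    fr <- intensity_to_freqs(fx$I1, fx$I2)
    heterozygosity(sector_profile(1:200, f1 = fr$f1, f2 = fr$f2, width = 200))
  }, numeric(1))
  expect_true(all(hs <= 0.25))
  expect_error(make_intensity_fixture(rep(0.5, 5), noise_sd = -1),
               "nonnegative")
})

test_that("run configs load, validate, and reject unknown keys", {
  path <- tempfile(fileext = ".json")
  write_default_config(path)
  cfg <- load_run_config(path)
  expect_s3_class(cfg$spec, "well_spec")
  expect_s3_class(cfg$params, "physics_params")
  # the shipped default simulates at least one step
  st <- sim_init(cfg$spec, cfg$params, n_cells = 5, seed = 1)
  st <- sim_step(st)
  expect_gt(st$time, 0)

  raw <- jsonlite::fromJSON(path)
  raw$wel <- raw$well
  bad1 <- tempfile(fileext = ".json")
  jsonlite::write_json(raw, bad1, auto_unbox = TRUE)
  expect_error(load_run_config(bad1), "unknown config section.*wel")

  raw2 <- jsonlite::fromJSON(path)
  raw2$well$amplitude_um <- -3
  bad2 <- tempfile(fileext = ".json")
  jsonlite::write_json(raw2, bad2, auto_unbox = TRUE)
  expect_error(load_run_config(bad2), "amplitude_um")

  expect_error(load_run_config(tempfile()), "not found")
  unlink(c(path, bad1, bad2))
})

test_that("snapshots round-trip bit-exactly through CSV", {
  spec <- well_spec(width = 30, height = 20, period_T = 10, amplitude_A = 3)
  st <- sim_init(spec, physics_params(adhesion = TRUE), n_cells = 15,
                 strain_mix = c(neutralA = 0.5, neutralB = 0.5), seed = 4)
  st <- sim_step(st, n_steps = 5)
  path <- tempfile(fileext = ".csv")
  write_snapshot(st, path)
  back <- read_snapshot(path)
  expect_identical(back$cells$x, st$cells$x)
  expect_identical(back$cells$y, st$cells$y)
  expect_identical(back$cells$angle, st$cells$angle)
  expect_identical(back$cells$length, st$cells$length)
  expect_identical(back$cells$genotype, st$cells$genotype)
  expect_identical(back$cells$strain_i, st$cells$strain_i)
  expect_identical(back$time, st$time)
  expect_identical(back$removed_count, st$removed_count)
  expect_equal(back$spec, st$spec)
  # resuming from the restored state is identical to continuing the original
  a <- sim_step(st, n_steps = 3)
  b <- sim_step(back, n_steps = 3)
  expect_identical(a$cells$x, b$cells$x)
  unlink(c(path, paste0(path, ".meta.json")))
})

test_that("fraction series and sector profiles round-trip through CSV", {
  fs <- replicator_predict(0.3, 0.1, seq(0, 10, by = 0.5))
  p1 <- tempfile(fileext = ".csv")
  write_fraction_series(fs, p1)
  back <- read_fraction_series(p1)
  expect_identical(back$fraction, fs$fraction)

  prof <- make_sector_fixture(5, width = 50, noise = 0.02, seed = 2)
  p2 <- tempfile(fileext = ".csv")
  write_sector_profile(prof, p2)
  back2 <- read_sector_profile(p2)
  expect_identical(back2$labels, prof$labels)
  unlink(c(p1, p2))
})
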