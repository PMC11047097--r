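test_that("bottom_height matches the sine profile and its invariants", {
  w <- well_spec(period_T = 10, amplitude_A = 5)
  expect_equal(bottom_height(w, 0), 0)
  expect_equal(bottom_height(w, 5), 5)    # ridge at half period
  expect_equal(bottom_height(well_spec(flat = TRUE), c(0, 13, 99)),
               c(0, 0, 0))
  # periodicity, bounds, gradient bound pi*A/T
  x <- seq(0, 90, by = 0.37)
  expect_equal(bottom_height(w, x), bottom_height(w, x + 10))
  h <- bottom_height(w, seq(0, 100, by = 0.01))
  expect_true(all(h >= 0 & h <= 5 + 1e-12))
  grad <- diff(h) / 0.01
  expect_true(max(abs(grad)) <= pi * 5 / 10 + 1e-3)
  expect_error(bottom_height(w, -1), "outside")
  expect_error(well_spec(amplitude_A = 5, period_T = 10, height = 4),
               "smaller than the well height")
})

test_that("wall_contact agrees with a dense-sampling oracle", {
  w <- well_spec(period_T = 10, amplitude_A = 5)
  wc <- wall_contact(w, c(5, 5.8))
  expect_equal(wc$distance, 0.8, tolerance = 1e-3)
  expect_equal(wc$normal, c(0, 1), tolerance = 1e-5)
  expect_identical(wc$wall, "bottom")

  flat <- well_spec(flat = TRUE)
  wcf <- wall_contact(flat, c(50, 3))
  expect_equal(wcf$distance, 3)
  expect_identical(wcf$wall, "bottom")
  wcl <- wall_contact(flat, c(1, 50))
  expect_equal(wcl$distance, 1)
  expect_equal(wcl$normal, c(1, 0))
  expect_identical(wcl$wall, "left")

  set.seed(42)
  specs <- list(w, well_spec(period_T = 20, amplitude_A = 5.1),
                well_spec(period_T = 50, amplitude_A = 8.7))
  for (spec in specs) {
    n <- 350
    px <- runif(n, 0, spec$width)
    py <- runif(n, -0.2, spec$height)
    for (i in seq_len(n)) {
      got <- wall_contact(spec, c(px[i], py[i]))$distance
      want <- oracle_wall_distance(spec, px[i], py[i])
      expect_lt(abs(got - unname(want)), 1e-3)
    }
  }
})

test_that("pocket indexing realizes the (T + width)/T count", {
  expect_equal(n_pockets(well_spec(period_T = 10, amplitude_A = 5)), 11L)
  expect_equal(n_pockets(well_spec(period_T = 100, amplitude_A = 5)), 2L)
  w50 <- well_spec(period_T = 50, amplitude_A = 8.7)
  expect_equal(pocket_index(w50, 24), 0L)   # first ridge at x = 25
  expect_equal(pocket_index(w50, 26), 1L)
  expect_error(pocket_index(well_spec(flat = TRUE), 10), "no pockets")
  # count equals (T+width)/T whenever T divides the width
  for (T in c(10, 20, 25, 50, 100)) {
    spec <- well_spec(period_T = T, amplitude_A = 3)
    expect_equal(n_pockets(spec), as.integer((T + 100) / T))
    idx <- pocket_index(spec, seq(0, 100, by = 0.25))
    expect_equal(length(unique(idx)), n_pockets(spec))
    expect_true(all(diff(idx) >= 0))
  }
})

test_that("the half-amplitude convention doubles the profile", {
  w2 <- well_spec(period_T = 10, amplitude_A = 2.5,
                  amplitude_convention = "half")
  expect_equal(bottom_height(w2, 5), 5)
})
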