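# Shared helpers: hand-built states and small reference implementations used
# as independent oracles.

# Minimal sim_state wrapper around a hand-written cell table.
mk_state <- function(cells, spec, params = physics_params(), time = 0) {
  defaults <- data.frame(
    id = seq_len(nrow(cells)), founder_id = seq_len(nrow(cells)),
    genotype = seq_len(nrow(cells)), strain_i = 1L,
    x = 0, y = 0, angle = 0, length = 2, radius = params$radius,
    growth_multiplier = 1)
  for (nm in names(cells)) defaults[[nm]] <- cells[[nm]]
  structure(list(
    time = time, cells = defaults, springs = corrugo:::empty_springs(),
    removed_count = 0L, removed_area = 0,
    next_id = nrow(defaults) + 1L, rng_hi = 0L, rng_lo = 1L,
    retagged = FALSE, spec = spec, params = params, seed = 1L),
    class = "sim_state")
}

# Brute-force nearest point on the well boundary by dense sampling: the
# independent oracle for wall_contact().
oracle_wall_distance <- function(spec, px, py, n = 200001) {
  u <- seq(0, spec$width, length.out = n)
  hb <- bottom_height(spec, u)
  d_bottom <- sqrt((px - u)^2 + (py - hb)^2)
  ib <- which.min(d_bottom)
  # sign: above or below the curve at the nearest abscissa
  sb <- if (py >= hb[ib] || d_bottom[ib] < 1e-12) 1 else -1
  cands <- c(bottom = sb * d_bottom[ib], left = px, right = spec$width - px)
  cands[which.min(cands)]
}

# Small physics profile for fast simulation tests (identical structure to
# the default desk profile, used at reduced well sizes).
test_params <- function(...) physics_params(...)

# Fast, reduced-size neutral run reused across tests.
quick_run <- function(spec, t_end, seed = 1, n_cells = 30, ...) {
  sim_run(spec, test_params(), t_end = t_end, n_cells = n_cells,
          seed = seed, ...)
}
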