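# Synthetic fixtures and the plain-text persistence layer.

#' Synthetic sector transect with planted boundaries
#'
#' Equal-width sectors of distinct labels along a transect, with optional
#' Bernoulli label noise (a flipped sample takes a uniformly random other
#' label). Ground-truth boundary positions are attached for comparison with
#' [boundary_density()].
#'
#' @param n_sectors Number of sectors (>= 1).
#' @param width Transect width, um.
#' @param noise Per-sample label-flip probability.
#' @param spacing Sample spacing, um.
#' @param seed RNG seed.
#' @return A [sector_profile()] with attribute `true_boundaries`.
#' @export
make_sector_fixture <- function(n_sectors, width = 100, noise = 0,
                                spacing = 0.5, seed = 1) {
  stopifnot(n_sectors >= 1, noise >= 0, noise < 1)
  set.seed(seed)
  pos <- seq(spacing / 2, width - spacing / 2, by = spacing)
  if (n_sectors > length(pos))
    stop("n_sectors exceeds the number of samples")
  lab <- pmin(n_sectors, floor(pos / (width / n_sectors)) + 1L)
  if (noise > 0 && n_sectors > 1) {
    flip <- runif(length(lab)) < noise
    lab[flip] <- vapply(lab[flip], function(l)
      sample(setdiff(seq_len(n_sectors), l), 1L), integer(1))
  }
  prof <- sector_profile(pos, labels = as.integer(lab), width = width)
  attr(prof, "true_boundaries") <- width / n_sectors * seq_len(n_sectors - 1)
  prof
}

#' Synthetic two-channel intensity transect
#'
#' Emulates a two-color fluorescence transect: `I1 = total * f1 + eps`,
#' `I2 = total * (1 - f1) + eps'`, with iid Gaussian noise clipped at 0.
#'
#' @param f1_profile Focal-strain frequency per position, in `[0, 1]`.
#' @param total_intensity Summed intensity scale (default 200).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed RNG seed.
#' @return List with `I1`, `I2`.
#' @export
make_intensity_fixture <- function(f1_profile, total_intensity = 200,
                                   noise_sd = 0, seed = 1) {
  stopifnot(all(f1_profile >= 0 & f1_profile <= 1))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  set.seed(seed)
  n <- length(f1_profile)
  I1 <- pmax(0, total_intensity * f1_profile + rnorm(n, 0, noise_sd))
  I2 <- pmax(0, total_intensity * (1 - f1_profile) + rnorm(n, 0, noise_sd))
  list(I1 = I1, I2 = I2)
}

# --- run configuration (strict JSON) ---------------------------------------

config_schema <- list(
  well = c("width_um", "height_um", "period_um", "amplitude_um", "flat"),
  physics = c("profile", "adhesion", "epsilon_max", "k_cell", "k_wall",
              "k_adhesion", "gamma", "dt", "elongation_rate", "l_div",
              "l_min", "radius", "division_angle_noise"),
  population = c("n_cells", "strain_mix"),
  protocol = NULL,
  output = c("directory", "snapshot_every"),
  seed = NULL,
  t_end = NULL)

#' Load and validate a run configuration
#'
#' Configurations are JSON with sections `well`, `physics`, `population`,
#' optional `protocol` (list of `{t_start_h, multipliers}`), `output`,
#' `seed` and `t_end`. Unknown keys are rejected with the offending key
#' named.
#'
#' @param path Path to a JSON config file.
#' @return List with `spec` ([well_spec()]), `params` ([physics_params()]),
#'   `n_cells`, `strain_mix`, `protocol` (or NULL), `seed`, `t_end`,
#'   `output`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(cfg), names(config_schema))) {
    allowed <- config_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  wellc <- cfg$well
  if (is.null(wellc)) stop("config is missing the 'well' section")
  if (!is.null(wellc$amplitude_um) && wellc$amplitude_um < 0)
    stop("invalid value for key 'well.amplitude_um': must be >= 0")
  flat <- isTRUE(wellc$flat) || is.null(wellc$period_um)
  spec <- well_spec(width = wellc$width_um %||% 100,
                    height = wellc$height_um %||% 100,
                    period_T = if (flat) Inf else wellc$period_um,
                    amplitude_A = if (flat) 0 else wellc$amplitude_um,
                    flat = flat)
  phys <- cfg$physics %||% list()
  prof <- phys$profile %||% "desk"
  adh <- isTRUE(phys$adhesion)
  overrides <- phys[setdiff(names(phys), c("profile", "adhesion", "epsilon_max"))]
  params <- do.call(physics_params,
                    c(list(profile = prof, adhesion = adh,
                           epsilon_max = phys$epsilon_max %||% 0.05),
                      overrides))
  pop <- cfg$population %||% list(n_cells = 100)
  mix <- pop$strain_mix
  if (is.null(mix)) mix <- c(neutralA = 1)
  mix <- unlist(mix)
  protocol <- NULL
  if (!is.null(cfg$protocol)) {
    ph <- cfg$protocol
    if (is.data.frame(ph)) {
      protocol <- fitness_protocol(lapply(seq_len(nrow(ph)), function(i)
        list(t_start = ph$t_start_h[i],
             multipliers = as.list(ph$multipliers[i, , drop = TRUE]))))
    } else {
      protocol <- fitness_protocol(lapply(ph, function(p)
        list(t_start = p$t_start_h, multipliers = as.list(p$multipliers))))
    }
  }
  list(spec = spec, params = params,
       n_cells = pop$n_cells %||% 100, strain_mix = mix,
       protocol = protocol, seed = cfg$seed %||% 1,
       t_end = cfg$t_end %||% 72, output = cfg$output)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the default shipped configuration
#'
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_default_config <- function(path) {
  cfg <- list(
    well = list(width_um = 100, height_um = 40, period_um = 10,
                amplitude_um = 5, flat = FALSE),
    physics = list(profile = "desk", adhesion = FALSE, epsilon_max = 0.05),
    population = list(n_cells = 100, strain_mix = list(neutralA = 1)),
    output = list(directory = "out", snapshot_every = 1),
    seed = 1, t_end = 72)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# --- snapshot persistence ---------------------------------------------------

#' Write/read a simulation snapshot as CSV (+ JSON sidecar)
#'
#' One row per cell: `time_h`, `id`, `founder_id`, `genotype`, `strain`,
#' `x_um`, `y_um`, `angle_rad`, `length_um`, `radius_um`. The JSON sidecar
#' (`<path>.meta.json`) stores the well spec, physics parameters, seed and
#' removal counters, so `read_snapshot()` reconstructs a state that
#' round-trips bit-exactly through the documented dialect (positions are
#' printed with full precision).
#'
#' @param state A `sim_state`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(state, path) {
  cells <- state$cells
  df <- data.frame(
    time_h = state$time, id = cells$id, founder_id = cells$founder_id,
    genotype = cells$genotype, strain = corrugo_strains[cells$strain_i],
    x_um = sprintf("%.17g", cells$x), y_um = sprintf("%.17g", cells$y),
    angle_rad = sprintf("%.17g", cells$angle),
    length_um = sprintf("%.17g", cells$length),
    radius_um = sprintf("%.17g", cells$radius))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  num <- function(v) sprintf("%.17g", v)  # doubles as strings: bit-exact
  springs <- state$springs
  meta <- list(
    time = num(state$time), removed_count = state$removed_count,
    removed_area = num(state$removed_area), next_id = state$next_id,
    rng_hi = state$rng_hi, rng_lo = state$rng_lo,
    retagged = state$retagged, seed = state$seed,
    spec = unclass(state$spec), params = unclass(state$params),
    growth_multiplier = num(cells$growth_multiplier),
    springs = list(cell_id = springs$cell_id, wall = springs$wall,
                   anchor_x = num(springs$anchor_x),
                   anchor_y = num(springs$anchor_y),
                   rest_length = num(springs$rest_length),
                   attach_frac = num(springs$attach_frac)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_snapshot
#' @param path Path of a CSV written by `write_snapshot()`.
#' @export
read_snapshot <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) stop("missing snapshot sidecar: ", meta_path)
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  spec <- meta$spec
  spec$period_T <- spec$period_T %||% Inf  # Inf serializes to null
  spec <- do.call(well_spec, spec[c("width", "height", "period_T",
                                    "amplitude_A", "depth_Z", "flat")])
  pk <- meta$params
  params <- do.call(physics_params, c(
    list(profile = pk$profile,
         adhesion = pk$k_adhesion > 0, epsilon_max = pk$epsilon_max),
    pk[c("k_cell", "k_wall", "k_adhesion", "gamma", "gamma_rot", "dt",
         "elongation_rate", "l_div", "l_min", "radius",
         "division_angle_noise")]))
  params$k_adhesion <- pk$k_adhesion
  cells <- data.frame(
    id = df$id, founder_id = df$founder_id, genotype = df$genotype,
    strain_i = match(df$strain, corrugo_strains),
    x = df$x_um, y = df$y_um, angle = df$angle_rad,
    length = df$length_um, radius = df$radius_um,
    growth_multiplier = as.numeric(meta$growth_multiplier))
  sp <- meta$springs
  if (is.null(sp) || length(sp$cell_id) == 0) {
    springs <- empty_springs()
  } else {
    springs <- data.frame(
      cell_id = as.integer(sp$cell_id), wall = as.integer(sp$wall),
      anchor_x = as.numeric(sp$anchor_x), anchor_y = as.numeric(sp$anchor_y),
      rest_length = as.numeric(sp$rest_length),
      attach_frac = as.numeric(sp$attach_frac))
  }
  structure(list(
    time = as.numeric(meta$time), cells = cells, springs = springs,
    removed_count = as.integer(meta$removed_count),
    removed_area = as.numeric(meta$removed_area),
    next_id = as.integer(meta$next_id),
    rng_hi = as.integer(meta$rng_hi), rng_lo = as.integer(meta$rng_lo),
    retagged = isTRUE(meta$retagged), spec = spec, params = params,
    seed = meta$seed), class = "sim_state")
}

#' Write/read a fraction time series as two-column CSV
#'
#' @param series A `fraction_series`.
#' @param path CSV path (`time_h`, `fraction`).
#' @return `path` (write) or a `fraction_series` (read).
#' @export
write_fraction_series <- function(series, path) {
  df <- data.frame(time_h = sprintf("%.17g", series$time),
                   fraction = sprintf("%.17g", series$fraction))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fraction_series
#' @export
read_fraction_series <- function(path) {
  df <- read.csv(path)
  structure(data.frame(time = df$time_h, fraction = df$fraction),
            class = c("fraction_series", "data.frame"))
}

#' Read a sector profile from CSV
#'
#' Two dialects: two-column `position,label` (label empty or NA =
#' unoccupied) and three-column `position,I1,I2` intensity transects, which
#' are converted to frequencies with [intensity_to_freqs()].
#'
#' @param path CSV path.
#' @param floor_frac Occupancy floor for the intensity dialect.
#' @return A [sector_profile()].
#' @export
read_sector_profile <- function(path, floor_frac = 0.05) {
  df <- read.csv(path)
  if (all(c("position", "label") %in% names(df))) {
    sector_profile(df$position, labels = as.integer(df$label))
  } else if (all(c("position", "I1", "I2") %in% names(df))) {
    fr <- intensity_to_freqs(df$I1, df$I2, floor_frac)
    sector_profile(df$position, f1 = fr$f1, f2 = fr$f2)
  } else {
    stop("unrecognized sector-profile CSV dialect: need columns ",
         "(position, label) or (position, I1, I2)")
  }
}

#' Write a sector profile to CSV
#'
#' @param profile A [sector_profile()].
#' @param path CSV path; the dialect follows the profile's contents.
#' @return `path`, invisibly.
#' @export
write_sector_profile <- function(profile, path) {
  if (!is.null(profile$labels)) {
    write.csv(data.frame(position = profile$positions,
                         label = profile$labels),
              path, row.names = FALSE)
  } else {
    write.csv(data.frame(position = profile$positions,
                         I1 = profile$f1 * 100, I2 = profile$f2 * 100),
              path, row.names = FALSE)
  }
  invisible(path)
}
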