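# Population-genetic summaries: clone censuses, sector transects,
# boundary densities, heterozygosity, founder survival.

#' Census of clones in a simulation state
#'
#' @param state A `sim_state` (or any data frame with a `genotype` column).
#' @return Object of class `clone_census`: list with `time`, `clone_sizes`
#'   (named counts), `n_clones`, `fractions`.
#' @export
clone_census <- function(state) {
  cells <- if (inherits(state, "sim_state")) state$cells else state
  if (nrow(cells) == 0) stop("cannot census an empty population")
  sizes <- table(cells$genotype)
  structure(list(
    time = if (inherits(state, "sim_state")) state$time else NA_real_,
    clone_sizes = setNames(as.integer(sizes), names(sizes)),
    n_clones = length(sizes),
    fractions = setNames(as.integer(sizes) / nrow(cells), names(sizes))),
    class = "clone_census")
}

#' @export
print.clone_census <- function(x, ...) {
  cat(sprintf("<clone_census> t=%.2f h, %d clones, mean fraction %.4f\n",
              x$time, x$n_clones, mean(x$fractions)))
  invisible(x)
}

#' Build a sector profile from explicit labels or frequencies
#'
#' A `sector_profile` is a 1D transect near the bottom of the well:
#' strictly increasing positions with, per position, a genotype label
#' (`NA` = unoccupied) and/or two-strain frequencies `f1`, `f2`
#' (`f1 + f2 = 1` where occupied, both `NA` elsewhere).
#'
#' @param positions Strictly increasing positions, um.
#' @param labels Optional integer genotype labels (`NA` for unoccupied).
#' @param f1,f2 Optional per-position strain frequencies.
#' @param width Well width, um (defaults to the position span).
#' @return Object of class `sector_profile`.
#' @export
sector_profile <- function(positions, labels = NULL, f1 = NULL, f2 = NULL,
                           width = max(positions)) {
  stopifnot(all(diff(positions) > 0))
  if (!is.null(f1)) {
    occ <- !is.na(f1)
    if (any(f1[occ] < -1e-9 | f1[occ] > 1 + 1e-9))
      stop("frequencies must lie in [0, 1]")
    if (is.null(f2)) f2 <- 1 - f1
    if (any(abs(f1[occ] + f2[occ] - 1) > 1e-6))
      stop("f1 + f2 must equal 1 at occupied positions")
  }
  structure(list(positions = positions, labels = labels, f1 = f1, f2 = f2,
                 width = width),
            class = "sector_profile")
}

#' @export
print.sector_profile <- function(x, ...) {
  n <- length(x$positions)
  occ <- if (!is.null(x$labels)) sum(!is.na(x$labels)) else sum(!is.na(x$f1))
  cat(sprintf("<sector_profile> %d positions over %.1f um, %d occupied\n",
              n, x$width, occ))
  invisible(x)
}

#' Sample a transect just above the local bottom of a simulated well
#'
#' Samples points along `y = h(x) + offset` at `spacing` um; each point is
#' assigned the genotype and strain of the nearest cell whose spherocylinder
#' surface overlaps it (distance from the centerline less than the radius).
#' Unoccupied points are `NA`.
#'
#' @param state A `sim_state`.
#' @param offset Height above the local bottom, um (default 2; must exceed
#'   the cell radius).
#' @param spacing Sample spacing, um.
#' @return A [sector_profile()] with both labels and two-strain frequencies
#'   (strain 1 = the lowest strain index present in the state).
#' @export
transect <- function(state, offset = 2, spacing = 0.5) {
  spec <- state$spec
  cells <- state$cells
  if (offset <= max(cells$radius)) stop("offset must exceed the cell radius")
  xs <- seq(0, spec$width, by = spacing)
  ys <- bottom_height(spec, xs) + offset
  ux <- cos(cells$angle); uy <- sin(cells$angle)
  hl <- cells$length / 2
  labels <- rep(NA_integer_, length(xs))
  strain <- rep(NA_integer_, length(xs))
  for (i in seq_along(xs)) {
    # point-segment distances to all centerlines
    dx <- xs[i] - cells$x; dy <- ys[i] - cells$y
    t <- pmax(-hl, pmin(hl, dx * ux + dy * uy))
    ddx <- dx - t * ux; ddy <- dy - t * uy
    d2 <- ddx^2 + ddy^2
    j <- which.min(d2)
    if (length(j) && d2[j] <= cells$radius[j]^2) {
      labels[i] <- cells$genotype[j]
      strain[i] <- cells$strain_i[j]
    }
  }
  strains_present <- sort(unique(state$cells$strain_i))
  f1 <- ifelse(is.na(strain), NA_real_,
               as.numeric(strain == strains_present[1]))
  sector_profile(xs, labels = labels, f1 = f1, f2 = 1 - f1,
                 width = spec$width)
}

profile_boundaries <- function(profile) {
  lab <- profile$labels
  pos <- profile$positions
  occ <- which(!is.na(lab))
  if (length(occ) < 2) return(numeric())
  # boundaries only between *adjacent* occupied samples with differing labels
  adj <- occ[-length(occ)][diff(occ) == 1]
  chg <- adj[lab[adj] != lab[adj + 1]]
  (pos[chg] + pos[chg + 1]) / 2
}

#' End-point probability density of sector-boundary positions
#'
#' Collects the midpoints of label changes along each profile, normalizes
#' positions by the well width, and histograms them into a density over
#' `[0, 1]` that integrates to 1.
#'
#' @param profiles A [sector_profile()] or list of them.
#' @param n_bins Number of bins over `[0, 1]` (default 50).
#' @return List with `breaks`, `mids`, `density`, `n_boundaries` and
#'   `empty` (`TRUE` when no profile contained a boundary).
#' @export
boundary_density <- function(profiles, n_bins = 50) {
  if (inherits(profiles, "sector_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1)
  xb <- unlist(lapply(profiles, function(p)
    profile_boundaries(p) / p$width))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  if (length(xb) == 0) {
    return(list(breaks = breaks, mids = (breaks[-1] + breaks[-n_bins - 1]) / 2,
                density = rep(0, n_bins), n_boundaries = 0L, empty = TRUE))
  }
  h <- hist(pmin(pmax(xb, 0), 1 - 1e-12), breaks = breaks, plot = FALSE)
  list(breaks = breaks, mids = h$mids, density = h$density,
       n_boundaries = length(xb), empty = FALSE)
}

#' Mean clonal sector size as a fraction of the well width
#'
#' Sectors are maximal runs of consecutive occupied samples with a constant
#' genotype; unoccupied gaps terminate a run. Runs shorter than `min_run`
#' samples are discarded.
#'
#' @param profile A [sector_profile()] with labels.
#' @param min_run Minimum run length in samples (default 1).
#' @return Mean run length divided by the well width (dimensionless).
#' @export
mean_sector_size <- function(profile, min_run = 1) {
  lab <- profile$labels
  pos <- profile$positions
  if (all(is.na(lab))) stop("profile is fully unoccupied")
  spacing <- median(diff(pos))
  key <- ifelse(is.na(lab), -1L, lab)
  r <- rle(key)
  keep <- r$values >= 0 & r$lengths >= min_run
  if (!any(keep)) stop("no sector run passes the min_run filter")
  mean(r$lengths[keep] * spacing) / profile$width
}

#' Mean heterozygosity along a transect
#'
#' Computes `H(x) = f1(x) f2(x) / (f1(x) + f2(x))` pointwise and averages
#' over occupied positions. With frequencies normalized to `f1 + f2 = 1`
#' this equals `f1 * f2`; both forms are computed and checked against each
#' other. `H = 0.25` for an equal mixture, `H = 0` for a single strain.
#'
#' @param profile A [sector_profile()] carrying frequencies, or a list with
#'   `f1`, `f2`.
#' @return Mean heterozygosity (dimensionless, in `[0, 0.25]`).
#' @export
heterozygosity <- function(profile) {
  f1 <- profile$f1; f2 <- profile$f2
  if (is.null(f1)) stop("profile carries no strain frequencies")
  if (is.null(f2)) f2 <- 1 - f1
  occ <- !is.na(f1) & !is.na(f2)
  if (!any(occ)) stop("profile is fully unoccupied")
  f1 <- f1[occ]; f2 <- f2[occ]
  tot <- f1 + f2
  h_literal <- ifelse(tot > 0, f1 * f2 / tot, 0)
  if (all(abs(tot - 1) < 1e-9)) {
    h_product <- f1 * f2  # equivalent form for normalized frequencies
    if (max(abs(h_literal - h_product)) > 1e-12)
      stop("internal inconsistency between heterozygosity code paths")
  }
  mean(h_literal)
}

#' Convert two-channel intensity profiles to strain frequencies
#'
#' `f_i = I_i / (I1 + I2)` pointwise; positions whose summed intensity falls
#' below `floor_frac` times the profile's maximum summed intensity are
#' flagged unoccupied (`NA`).
#'
#' @param I1,I2 Nonnegative intensity arrays (same length).
#' @param floor_frac Occupancy floor as a fraction of the maximum summed
#'   intensity (default 0.05).
#' @return List with `f1`, `f2` (NA where unoccupied).
#' @export
intensity_to_freqs <- function(I1, I2, floor_frac = 0.05) {
  stopifnot(length(I1) == length(I2))
  if (any(I1 < 0) || any(I2 < 0)) stop("intensities must be nonnegative")
  tot <- I1 + I2
  floor_val <- floor_frac * max(tot)
  occ <- tot > floor_val & tot > 0
  f1 <- ifelse(occ, I1 / tot, NA_real_)
  list(f1 = f1, f2 = ifelse(occ, I2 / tot, NA_real_))
}

#' Probability density of surviving founders over initial height
#'
#' Given a run whose cells were re-tagged at `t0` (see the `retag_at`
#' argument of [sim_run()]), computes for each `t0` cell its distance
#' `d = y - h(x)` from the local bottom, marks it surviving when its lineage
#' tag is still present at `t_end`, and returns the histogram density of
#' `d` over surviving founders (normalized to integrate to 1).
#'
#' @param run A `sim_run` (list of `sim_state` snapshots).
#' @param t0 Founder tagging time, h (a snapshot at this time must exist).
#' @param t_end Survival horizon, h (defaults to the last snapshot).
#' @param n_bins Number of histogram bins.
#' @return List with `breaks`, `mids`, `density`, plus the founder table
#'   (`d`, `survived`).
#' @export
founder_survival_density <- function(run, t0 = 2, t_end = NULL, n_bins = 20) {
  times <- vapply(run, `[[`, numeric(1), "time")
  if (is.null(t_end)) t_end <- max(times)
  i0 <- which(abs(times - t0) < 1e-9)
  i1 <- which(abs(times - t_end) < 1e-9)
  if (length(i0) != 1 || length(i1) != 1)
    stop("run must contain snapshots at t0 and t_end")
  s0 <- run[[i0]]; s1 <- run[[i1]]
  if (!s0$retagged)
    stop("run was not re-tagged at t0; pass retag_at = t0 to sim_run()")
  cells0 <- s0$cells
  d <- cells0$y - bottom_height(s0$spec, pmin(pmax(cells0$x, 0), s0$spec$width))
  survived <- cells0$founder_id %in% unique(s1$cells$founder_id)
  if (!any(survived)) stop("no founder lineage survived to t_end")
  breaks <- seq(min(0, min(d)), max(d) * (1 + 1e-9) + 1e-9,
                length.out = n_bins + 1)
  h <- hist(d[survived], breaks = breaks, plot = FALSE)
  list(breaks = breaks, mids = h$mids, density = h$density,
       founders = data.frame(d = d, survived = survived))
}

#' Theoretical clone count of a corrugated well
#'
#' Under intrapocket clonality each groove-centred pocket carries one
#' surviving clone, giving `N_clones = (T + width)/T` and a mean clone
#' fraction `f = 1/N_clones`.
#'
#' @param spec A corrugated [well_spec()].
#' @return List with `n_clones` and `fraction`.
#' @export
theory_clone_count <- function(spec) {
  stopifnot(inherits(spec, "well_spec"))
  if (spec$flat) stop("no pocket theory for a flat well")
  n <- (spec$period_T + spec$width) / spec$period_T
  list(n_clones = n, fraction = 1 / n)
}
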