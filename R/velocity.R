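# Gridded velocity fields and continuity-equation growth rates.

new_velocity_field <- function(vx, vy, counts, origin, spacing) {
  stopifnot(all(dim(vx) == dim(vy)), all(dim(vx) == dim(counts)))
  structure(list(vx = vx, vy = vy, counts = counts, mask = counts > 0,
                 origin = origin, spacing = spacing),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d x %d bins, spacing %g um, %d occupied\n",
              nrow(x$vx), ncol(x$vx), x$spacing, sum(x$mask)))
  invisible(x)
}

bin_centers <- function(field) {
  list(x = field$origin[1] + (seq_len(nrow(field$vx)) - 0.5) * field$spacing,
       y = field$origin[2] + (seq_len(ncol(field$vx)) - 0.5) * field$spacing)
}

#' Coarse-grained velocity field from two simulation snapshots
#'
#' For every cell id present in both snapshots, the velocity is the center
#' displacement divided by the time difference, assigned to the grid bin of
#' the midpoint position; bins average over their samples. Cells that
#' divided between the snapshots change id and are excluded.
#'
#' @param s0,s1 `sim_state` snapshots with `s1$time > s0$time`.
#' @param spacing Grid spacing, um (default 2, of the order of one cell
#'   length).
#' @return A `velocity_field` covering the well.
#' @export
velocity_field <- function(s0, s1, spacing = 2) {
  stopifnot(inherits(s0, "sim_state"), inherits(s1, "sim_state"),
            s1$time > s0$time)
  dt <- s1$time - s0$time
  m <- match(s0$cells$id, s1$cells$id)
  keep <- !is.na(m)
  if (!any(keep)) stop("snapshots share no cell ids")
  c0 <- s0$cells[keep, ]
  c1 <- s1$cells[m[keep], ]
  vx <- (c1$x - c0$x) / dt
  vy <- (c1$y - c0$y) / dt
  mx <- (c1$x + c0$x) / 2
  my <- (c1$y + c0$y) / 2
  spec <- s0$spec
  nx <- ceiling(spec$width / spacing)
  ny <- ceiling(spec$height / spacing)
  ix <- pmin(nx, pmax(1, floor(mx / spacing) + 1))
  iy <- pmin(ny, pmax(1, floor(my / spacing) + 1))
  idx <- (iy - 1) * nx + ix
  cnt <- matrix(0, nx, ny); sx <- matrix(0, nx, ny); sy <- matrix(0, nx, ny)
  tc <- tapply(rep(1, length(idx)), idx, sum)
  tx <- tapply(vx, idx, sum)
  ty <- tapply(vy, idx, sum)
  ii <- as.integer(names(tc))
  cnt[ii] <- tc; sx[ii] <- tx; sy[ii] <- ty
  vxm <- ifelse(cnt > 0, sx / pmax(cnt, 1), NA_real_)
  vym <- ifelse(cnt > 0, sy / pmax(cnt, 1), NA_real_)
  new_velocity_field(vxm, vym, cnt, c(0, 0), spacing)
}

#' Continuity-equation growth-rate field
#'
#' Treating the biofilm as an incompressible material with local mass
#' generation, the local growth rate is the divergence of the velocity
#' field, `g(x, y) = dvx/dx + dvy/dy`, estimated with central finite
#' differences on interior occupied bins and one-sided differences at
#' occupancy edges; bins without a usable neighborhood are `NA`.
#'
#' @param field A `velocity_field`.
#' @return Matrix of growth rates (1/h), same shape as the field.
#' @export
growth_rate_field <- function(field) {
  vx <- field$vx; vy <- field$vy
  nx <- nrow(vx); ny <- ncol(vx)
  h <- field$spacing
  deriv <- function(m, along) {
    out <- matrix(NA_real_, nx, ny)
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      if (is.na(m[i, j])) next
      if (along == 1) { im <- i - 1; ip <- i + 1; jm <- j; jp <- j }
      else { im <- i; ip <- i; jm <- j - 1; jp <- j + 1 }
      lo_ok <- im >= 1 && jm >= 1 && !is.na(m[max(im, 1), max(jm, 1)])
      hi_ok <- ip <= nx && jp <= ny && !is.na(m[min(ip, nx), min(jp, ny)])
      if (lo_ok && hi_ok) out[i, j] <- (m[ip, jp] - m[im, jm]) / (2 * h)
      else if (hi_ok) out[i, j] <- (m[ip, jp] - m[i, j]) / h
      else if (lo_ok) out[i, j] <- (m[i, j] - m[im, jm]) / h
    }
    out
  }
  deriv(vx, 1) + deriv(vy, 2)
}

#' Stratified velocity profiles over distance from the bottom
#'
#' Assigns each occupied bin its distance `d = y - h(x)` above the local
#' bottom at the bin center and returns per-stratum means of the vertical
#' velocity `vy` and of the horizontal fraction `|vx|/|v|`. Bins whose speed
#' falls below `speed_floor_frac` times the field's 95th-percentile speed
#' are excluded from the horizontal fraction (0/0 protection).
#'
#' @param field A `velocity_field`.
#' @param spec The [well_spec()] the field was measured in.
#' @param n_strata Number of equal-width strata over the observed `d` range.
#' @param speed_floor_frac Speed floor fraction (default 0.01).
#' @return Data frame with `d` (stratum center), `vy`, `vx_abs` (mean
#'   absolute horizontal velocity, um/h), `hfrac`, `n_bins`; empty strata
#'   carry `NA`.
#' @export
stratified_profiles <- function(field, spec, n_strata = 12,
                                speed_floor_frac = 0.01) {
  bc <- bin_centers(field)
  xg <- matrix(bc$x, nrow(field$vx), ncol(field$vx))
  yg <- matrix(bc$y, nrow(field$vx), ncol(field$vx), byrow = TRUE)
  occ <- field$mask
  if (!any(occ)) stop("field has no occupied bins")
  d <- yg - matrix(bottom_height(spec, pmin(pmax(bc$x, 0), spec$width)),
                   nrow(field$vx), ncol(field$vx))
  speed <- sqrt(field$vx^2 + field$vy^2)
  floor_v <- speed_floor_frac * quantile(speed[occ], 0.95, na.rm = TRUE)
  breaks <- seq(min(d[occ]), max(d[occ]) * (1 + 1e-9), length.out = n_strata + 1)
  stratum <- findInterval(d, breaks, rightmost.closed = TRUE)
  out <- data.frame(d = (breaks[-1] + breaks[-n_strata - 1]) / 2,
                    vy = NA_real_, vx_abs = NA_real_, hfrac = NA_real_,
                    n_bins = 0L)
  for (s in seq_len(n_strata)) {
    sel <- occ & stratum == s
    if (!any(sel)) next
    out$n_bins[s] <- sum(sel)
    out$vy[s] <- mean(field$vy[sel])
    out$vx_abs[s] <- mean(abs(field$vx[sel]))
    fast <- sel & speed > floor_v
    if (any(fast)) out$hfrac[s] <- mean(abs(field$vx[fast]) / speed[fast])
  }
  out
}

#' Analytic velocity fields for testing the velocity statistics
#'
#' Kinds: `"linear_shear"` is `v = (0, g0 * y)` (divergence `g0`);
#' `"rotation"` is `v = (-omega * y, omega * x)` (divergence 0);
#' `"divergent"` is `v = (alpha * x, beta * y)` (divergence `alpha + beta`);
#' `"perturbed"` is a linear shear with iid Gaussian noise of standard
#' deviation `sigma` added to both components.
#'
#' @param kind One of `"linear_shear"`, `"rotation"`, `"divergent"`,
#'   `"perturbed"`.
#' @param params Named list: `g0`, `omega`, `alpha`, `beta`, `sigma` as
#'   required by `kind`.
#' @param spacing Grid spacing, um.
#' @param width,height Extent of the sampled grid, um.
#' @param seed RNG seed for the noise (perturbed kind only).
#' @return A fully occupied `velocity_field`.
#' @export
synthetic_field <- function(kind = c("linear_shear", "rotation", "divergent",
                                     "perturbed"),
                            params = list(), spacing = 2,
                            width = 40, height = 40, seed = 1) {
  kind <- match.arg(kind)
  nx <- ceiling(width / spacing); ny <- ceiling(height / spacing)
  xc <- (seq_len(nx) - 0.5) * spacing
  yc <- (seq_len(ny) - 0.5) * spacing
  xg <- matrix(xc, nx, ny); yg <- matrix(yc, nx, ny, byrow = TRUE)
  p <- function(name, default) if (is.null(params[[name]])) default else params[[name]]
  if (kind == "linear_shear") {
    vx <- 0 * xg; vy <- p("g0", 0.3) * yg
  } else if (kind == "rotation") {
    om <- p("omega", 0.1); vx <- -om * yg; vy <- om * xg
  } else if (kind == "divergent") {
    vx <- p("alpha", 0.2) * xg; vy <- p("beta", 0.1) * yg
  } else {
    set.seed(seed)
    sigma <- p("sigma", 0.05)
    vx <- matrix(rnorm(nx * ny, 0, sigma), nx, ny)
    vy <- p("g0", 0.3) * yg + matrix(rnorm(nx * ny, 0, sigma), nx, ny)
  }
  new_velocity_field(vx, vy, matrix(1L, nx, ny), c(0, 0), spacing)
}

#' Write/read a velocity field as gridded CSV
#'
#' Columns: `x_bin`, `y_bin`, `x_um`, `y_um`, `vx`, `vy`, `count`. The
#' reader inverts the writer exactly (round-trip identity on the occupied
#' grid).
#'
#' @param field A `velocity_field`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_velocity_field <- function(field, path) {
  bc <- bin_centers(field)
  nx <- nrow(field$vx); ny <- ncol(field$vx)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  df <- data.frame(
    x_bin = rep(seq_len(nx), ny), y_bin = rep(seq_len(ny), each = nx),
    x_um = fmt(rep(bc$x, ny)), y_um = fmt(rep(bc$y, each = nx)),
    vx = fmt(as.vector(field$vx)), vy = fmt(as.vector(field$vy)),
    count = as.vector(field$counts))
  attr_line <- sprintf("# spacing=%.17g origin=%.17g,%.17g",
                       field$spacing, field$origin[1], field$origin[2])
  con <- file(path, "w")
  writeLines(attr_line, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_velocity_field
#' @export
read_velocity_field <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "spacing=([-0-9.eE+]+) origin=([-0-9.eE+]+),([-0-9.eE+]+)", hdr))[[1]]
  spacing <- as.numeric(m[2]); origin <- as.numeric(m[3:4])
  df <- read.csv(path, skip = 1)
  nx <- max(df$x_bin); ny <- max(df$y_bin)
  vx <- matrix(NA_real_, nx, ny); vy <- matrix(NA_real_, nx, ny)
  cnt <- matrix(0L, nx, ny)
  idx <- cbind(df$x_bin, df$y_bin)
  vx[idx] <- df$vx; vy[idx] <- df$vy; cnt[idx] <- df$count
  new_velocity_field(vx, vy, cnt, origin, spacing)
}
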