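# Well geometry: domain box, sine-corrugated bottom, wall queries, pockets.

#' Define a microwell geometry
#'
#' A well is a rectangle of `width` x `height` um with an open top. The
#' bottom is either flat or carries a sinusoidal corrugation of period
#' `period_T` and peak-to-trough amplitude `amplitude_A`:
#' \deqn{h(x) = (A/2)\,(1 - \cos(2\pi x / T)),}
#' so grooves (minima) sit at `x = k T` and ridges (maxima) at
#' `x = (k + 1/2) T`. With this phase convention a well whose width is a
#' multiple of `T` has half-grooves abutting both side walls and exactly
#' `(T + width)/T` groove-centred pockets, matching the pocket-counting
#' theory used for clone numbers.
#'
#' @param width Well width (X extent), um.
#' @param height Well height (Y extent, open top), um.
#' @param period_T Corrugation period, um. Ignored when `flat = TRUE`.
#' @param amplitude_A Peak-to-trough corrugation amplitude, um; `0` gives a
#'   flat bottom.
#' @param depth_Z Well depth, um. Metadata only: the model is strictly 2D.
#' @param flat Logical; force a flat bottom regardless of `amplitude_A`.
#' @param amplitude_convention Either `"peak_to_trough"` (default; the bottom
#'   profile spans `[0, A]`) or `"half"` (profile spans `[0, 2A]`).
#' @return An object of class `well_spec`.
#' @examples
#' w <- well_spec(period_T = 10, amplitude_A = 5)
#' bottom_height(w, 5)   # ridge: full amplitude
#' @export
well_spec <- function(width = 100, height = 100, period_T = Inf,
                      amplitude_A = 0, depth_Z = 7, flat = NULL,
                      amplitude_convention = c("peak_to_trough", "half")) {
  amplitude_convention <- match.arg(amplitude_convention)
  if (amplitude_convention == "half") amplitude_A <- 2 * amplitude_A
  if (is.null(flat)) flat <- (amplitude_A == 0) || !is.finite(period_T)
  stopifnot(width > 0, height > 0, amplitude_A >= 0)
  if (!flat && !(is.finite(period_T) && period_T > 0))
    stop("period_T must be positive and finite for a corrugated well")
  if (amplitude_A >= height)
    stop("amplitude_A must be smaller than the well height")
  structure(list(width = width, height = height,
                 period_T = if (flat) Inf else period_T,
                 amplitude_A = if (flat) 0 else amplitude_A,
                 depth_Z = depth_Z, flat = flat),
            class = "well_spec")
}

#' @export
print.well_spec <- function(x, ...) {
  if (x$flat) {
    cat(sprintf("<well_spec> %g x %g um, flat bottom\n", x$width, x$height))
  } else {
    cat(sprintf("<well_spec> %g x %g um, sine bottom T=%g um, A=%g um (%d pockets)\n",
                x$width, x$height, x$period_T, x$amplitude_A, n_pockets(x)))
  }
  invisible(x)
}

#' Height of the corrugated bottom profile
#'
#' @param spec A [well_spec()].
#' @param x Position(s) along the well, um; must lie in `[0, width]`.
#' @return `h(x)` in um, in `[0, A]`.
#' @export
bottom_height <- function(spec, x) {
  stopifnot(inherits(spec, "well_spec"))
  if (any(x < 0 | x > spec$width))
    stop("x outside the well domain [0, width]")
  if (spec$flat) return(rep(0, length(x)))
  0.5 * spec$amplitude_A * (1 - cos(2 * pi * x / spec$period_T))
}

#' Distance and normal to the nearest wall
#'
#' Finds the nearest of the three solid walls (corrugated/flat bottom, left,
#' right) to a point. For a sine bottom the nearest point on the curve is
#' found numerically (coarse scan plus ternary refinement, tolerance
#' ~1e-6 um). A negative distance indicates penetration; near corners the
#' nearer wall is reported.
#'
#' @param spec A [well_spec()].
#' @param point Numeric `(x, y)` in um.
#' @return List with `distance` (signed, um), `normal` (outward unit vector),
#'   `wall` (`"bottom"`, `"left"` or `"right"`) and `foot` (nearest wall
#'   point).
#' @export
wall_contact <- function(spec, point) {
  stopifnot(inherits(spec, "well_spec"), length(point) == 2)
  v <- cpp_wall_contact(spec, point[1], point[2])
  list(distance = unname(v["distance"]),
       normal = unname(v[c("nx", "ny")]),
       wall = c("bottom", "left", "right")[v["wall"] + 1],
       foot = unname(v[c("foot_x", "foot_y")]))
}

#' Pocket index of a position on the corrugated bottom
#'
#' Pockets are groove-centred intervals between consecutive ridges; with the
#' groove-at-origin phase convention the two side walls abut half-pockets, so
#' a well whose width is a multiple of `T` has `(T + width)/T` pockets,
#' indexed from 0 at the left wall.
#'
#' @param spec A corrugated [well_spec()].
#' @param x Position(s) along the well, um.
#' @return Integer pocket index (0-based).
#' @seealso [n_pockets()], [theory_clone_count()]
#' @export
pocket_index <- function(spec, x) {
  stopifnot(inherits(spec, "well_spec"))
  if (spec$flat) stop("a flat well has no pockets")
  if (any(x < 0 | x > spec$width)) stop("x outside the well domain")
  as.integer(floor(x / spec$period_T + 0.5))
}

#' Number of pockets of a corrugated well
#'
#' @param spec A corrugated [well_spec()].
#' @return Integer pocket count: `floor(width/T) + 1` (equals
#'   `(T + width)/T` when `T` divides `width`).
#' @export
n_pockets <- function(spec) {
  stopifnot(inherits(spec, "well_spec"))
  if (spec$flat) stop("a flat well has no pockets")
  as.integer(floor(spec$width / spec$period_T + 1e-9)) + 1L
}
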