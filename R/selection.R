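# Time-varying selection protocols, strain-fraction dynamics, and
# logistic-replicator fitness estimation.

#' Build a fitness protocol
#'
#' A protocol is an ordered list of phases, each with a start time and a set
#' of per-strain growth multipliers (relative fitness values applied to the
#' base elongation rate). Strains not named in a phase keep multiplier 1.
#'
#' @param phases List of lists with `t_start` (h, strictly increasing from
#'   0) and `multipliers` (named, positive).
#' @param description Free-text label.
#' @return Object of class `fitness_protocol`.
#' @export
fitness_protocol <- function(phases, description = "") {
  t0 <- vapply(phases, `[[`, numeric(1), "t_start")
  stopifnot(t0[1] == 0, all(diff(t0) > 0))
  for (ph in phases) {
    m <- unlist(ph$multipliers)
    stopifnot(all(m > 0), all(names(m) %in% corrugo_strains))
  }
  structure(list(phases = phases, description = description),
            class = "fitness_protocol")
}

#' @export
print.fitness_protocol <- function(x, ...) {
  cat(sprintf("<fitness_protocol> %s (%d phases)\n", x$description,
              length(x$phases)))
  for (ph in x$phases) {
    m <- unlist(ph$multipliers)
    cat(sprintf("  t >= %5.1f h: %s\n", ph$t_start,
                paste(sprintf("%s=%g", names(m), m), collapse = ", ")))
  }
  invisible(x)
}

#' Constant-fitness protocol
#'
#' Single phase starting at 0 with fixed per-strain multipliers; the usual
#' way to encode a two-strain mixture with relative fitness `W`.
#'
#' @param multipliers Named per-strain growth multipliers.
#' @return A [fitness_protocol()].
#' @examples
#' protocol_constant(c(neutralA = 1, neutralB = 1.5))
#' @export
protocol_constant <- function(multipliers) {
  fitness_protocol(list(list(t_start = 0, multipliers = as.list(multipliers))),
                   description = "constant fitness")
}

#' Stepwise rifampicin selection protocol
#'
#' The four-phase schedule of the antibiotic-switch experiment encoded as
#' growth multipliers for the sensitive/resistant strain pair: plain LB
#' (resistant pays ~20% fitness cost, W_R/S ~ 0.8), low-RIF (intermediate,
#' resistant-favoring; the intermediate value is not pinned down by the
#' published data and is configurable), high-RIF (sensitive barely grows,
#' W_S/R ~ 0.2), and LB recovery (as phase 1).
#'
#' @param t_lb_end Start of the low-RIF phase, h (default 40).
#' @param t_low_end Start of the high-RIF phase, h (default 90, i.e. 50 h of
#'   low RIF).
#' @param t_high_end Start of the LB recovery phase, h.
#' @param w_resistant_lb Resistant-vs-sensitive fitness in LB (default 0.8).
#' @param w_sensitive_high Sensitive-vs-resistant fitness at high RIF
#'   (default 0.2).
#' @param w_sensitive_low Sensitive multiplier at low RIF (default 0.6;
#'   config-only, not an acceptance quantity).
#' @return A [fitness_protocol()] with four phases.
#' @export
protocol_rif_stepwise <- function(t_lb_end = 40, t_low_end = 90,
                                  t_high_end = 132,
                                  w_resistant_lb = 0.8,
                                  w_sensitive_high = 0.2,
                                  w_sensitive_low = 0.6) {
  fitness_protocol(list(
    list(t_start = 0,
         multipliers = list(sensitive = 1, resistant = w_resistant_lb)),
    list(t_start = t_lb_end,
         multipliers = list(sensitive = w_sensitive_low, resistant = 1)),
    list(t_start = t_low_end,
         multipliers = list(sensitive = w_sensitive_high, resistant = 1)),
    list(t_start = t_high_end,
         multipliers = list(sensitive = 1, resistant = w_resistant_lb))),
    description = "stepwise RIF exposure (LB / low RIF / high RIF / LB)")
}

#' Strain-fraction time series from a run
#'
#' @param run A `sim_run` (list of `sim_state` snapshots).
#' @param focal Focal strain label (one of [corrugo_strains]).
#' @param well_type Optional tag describing the well geometry.
#' @return Object of class `fraction_series`: data frame with `time` and
#'   `fraction`.
#' @export
fraction_series <- function(run, focal, well_type = NULL) {
  stopifnot(focal %in% corrugo_strains)
  fi <- match(focal, corrugo_strains)
  times <- vapply(run, `[[`, numeric(1), "time")
  frac <- vapply(run, function(s) {
    if (nrow(s$cells) == 0) stop("empty snapshot at t=", s$time)
    mean(s$cells$strain_i == fi)
  }, numeric(1))
  structure(data.frame(time = times, fraction = frac),
            focal = focal, well_type = well_type,
            class = c("fraction_series", "data.frame"))
}

#' Logistic replicator prediction of a strain fraction
#'
#' Closed-form solution of `df/dt = s f (1 - f)`:
#' `f(t) = f0 e^{s t} / (1 - f0 + f0 e^{s t})`, where the selection rate is
#' `s = g (W_focal - 1)` for base growth rate `g`. This well-level
#' replicator is the package's stated stand-in for sector-expansion fitness
#' models; see the methods vignette.
#'
#' @param f0 Initial focal fraction in `(0, 1)`.
#' @param s Selection rate, 1/h.
#' @param times Times at which to evaluate, h.
#' @return A `fraction_series`.
#' @export
replicator_predict <- function(f0, s, times) {
  stopifnot(f0 > 0, f0 < 1)
  es <- exp(s * times)
  f <- f0 * es / (1 - f0 + f0 * es)
  structure(data.frame(time = times, fraction = f),
            class = c("fraction_series", "data.frame"))
}

#' Estimate relative fitness from a fraction time series
#'
#' Least-squares fit of the selection rate `s` on logit-transformed
#' fractions (linear in time under the logistic replicator), reported as
#' `W = 1 + s/g` with a bootstrap confidence interval over time points.
#' Time points with fractions at 0 or 1 are dropped (the logit is
#' undefined there).
#'
#' @param series A `fraction_series` (or data frame with `time`,
#'   `fraction`).
#' @param g Base growth rate, 1/h.
#' @param n_boot Bootstrap replicates (default 200).
#' @param conf Confidence level.
#' @return List with `W`, `s`, `ci` (on W), `fit` (the `lm`).
#' @export
fit_relative_fitness <- function(series, g, n_boot = 200, conf = 0.95) {
  d <- series[series$fraction > 0 & series$fraction < 1, , drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 time points with fractions in (0, 1)")
  lg <- log(d$fraction / (1 - d$fraction))
  fit <- lm(lg ~ d$time)
  s <- unname(coef(fit)[2])
  boots <- replicate(n_boot, {
    i <- sample(nrow(d), replace = TRUE)
    if (length(unique(d$time[i])) < 2) return(NA_real_)
    unname(coef(lm(lg[i] ~ d$time[i]))[2])
  })
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  list(W = 1 + s / g, s = s, ci = unname(1 + qs / g), fit = fit)
}

#' Selection-suppression experiment across well types
#'
#' Runs the agent-based model for each (well type, seed) combination,
#' initialized with a `mix_ratio`:1 mixture of a normal-growing focal
#' strain (`neutralA`) and a faster-growing variant (`neutralB`, relative
#' fitness `W`), and reports the final fraction of the less-fit strain.
#'
#' @param specs Named list of [well_spec()] objects (names tag well types).
#' @param params A [physics_params()].
#' @param W Relative fitness of the faster strain (default 1.5).
#' @param mix_ratio Initial less-fit : fitter ratio (default 10).
#' @param t_end Run length, h (default 72).
#' @param seeds Integer seeds (>= 3 recommended); the same seeds are used
#'   for every well type (paired design).
#' @param n_cells Founder count (default 110, i.e. 10 fitter founders at
#'   the default ratio).
#' @return Data frame with one row per (well_type, seed): `well_type`,
#'   `seed`, `lessfit_fraction`, `n_cells_final`, plus a summary attribute
#'   (mean and SEM per well type).
#' @export
suppression_experiment <- function(specs, params, W = 1.5, mix_ratio = 10,
                                   t_end = 72, seeds = 1:5, n_cells = 110) {
  stopifnot(length(specs) >= 1, length(seeds) >= 1)
  if (is.null(names(specs))) names(specs) <- paste0("well", seq_along(specs))
  mix <- c(neutralA = mix_ratio / (mix_ratio + 1),
           neutralB = 1 / (mix_ratio + 1))
  prot <- protocol_constant(c(neutralA = 1, neutralB = W))
  rows <- list()
  for (wt in names(specs)) {
    for (sd in seeds) {
      run <- sim_run(specs[[wt]], params, t_end = t_end,
                     snapshot_times = c(0, t_end), n_cells = n_cells,
                     strain_mix = mix, seed = sd, protocol = prot)
      fin <- run[[length(run)]]
      rows[[length(rows) + 1]] <- data.frame(
        well_type = wt, seed = sd,
        lessfit_fraction = mean(fin$cells$strain_i ==
                                  match("neutralA", corrugo_strains)),
        n_cells_final = nrow(fin$cells))
    }
  }
  out <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(out, out$well_type), function(d)
    data.frame(well_type = d$well_type[1],
               mean = mean(d$lessfit_fraction),
               sem = sd(d$lessfit_fraction) / sqrt(nrow(d)))))
  rownames(agg) <- NULL
  attr(out, "summary") <- agg
  out
}
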