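---
title: "Methods: biofilm growth on corrugated substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biofilm growth on corrugated substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`corrugo` simulates a quasi-2D biofilm growing in a microwell whose bottom
carries a sinusoidal corrugation of period $T$ and peak-to-trough amplitude
$A$,
$$h(x) = \tfrac{A}{2}\left(1 - \cos\tfrac{2\pi x}{T}\right),$$
with solid side walls and an open top through which biomass is carried out
of the system (the in-silico analogue of flow trimming the biofilm at the
channel). Grooves sit at $x = kT$; with a width that is a multiple of $T$
the side walls abut half-grooves, so the well has exactly $(T+W)/T$
groove-centred *pockets*. That phase convention is deliberate: it makes the
pocket count coincide with the theoretical clone number $N_\mathrm{clones}
= (T + W)/T$ used to interpret the neutral-drift results, and it is the
single open geometric convention in the problem (which side of the mask the
walls cut is not determined by the device drawings; the `well_spec()`
helper records the convention so the alternative can be selected).

Cells are spherocylinders confined to the plane: a centerline segment of
length $\ell$ (growing exponentially, $\dot\ell = W g \ell$, with $W$ the
strain's relative fitness and $g$ the base elongation rate) with caps of
radius $r$. On reaching $\ell_\mathrm{div}$ a cell splits at the centerline
midpoint into two equal daughters that inherit genotype, founder tag and
strain; daughter axes are tilted by independent uniform angles in
$\pm\epsilon_\theta$. Forces are

* **cell-cell**: Hertzian-like repulsion $F = k_\mathrm{cell}\,o^{3/2}$ on
  the centerline overlap $o$, applied at the mutual closest points;
* **cell-wall**: linear repulsion $F = k_\mathrm{wall}\,p$ on the
  penetration $p$, sampled at the two cap centers and the midpoint (flat
  walls; exact for a linear boundary) or at 9 equidistant centerline
  points (sine bottoms, where a long cell pressed onto a convex ridge can
  penetrate between coarse samples);
* **adhesion** (optional): an elastic spring (stiffness
  $k_\mathrm{adh} = k_\mathrm{wall}/10$) from the centerline to the wall
  point of first contact, pulling only under extension and breaking beyond
  a strain $\epsilon_\mathrm{max}$ of 5% or 20%.

Dynamics are overdamped: $v = F/(\gamma\ell)$ and
$\omega = \tau/(\gamma_\mathrm{rot}\ell^3)$, with
$\gamma_\mathrm{rot} = \gamma/12$ (slender-rod scaling). There is no
nutrient field: growth is uniform in space, which is the experimental
observation the model class is built on.

## Parameters

| parameter | default | unit | origin |
|---|---|---|---|
| wall stiffness $k_\mathrm{wall}$ | $4\times10^7$ | pN/µm | published value rescaled 4x (10:1 wall:adhesion ratio preserved) |
| adhesion stiffness $k_\mathrm{adh}$ | $4\times10^6$ | pN/µm | published ratio |
| breaking strain $\epsilon_\mathrm{max}$ | 0.05 / 0.20 | — | published model values |
| Hertz prefactor $k_\mathrm{cell}$ | $1.2\times10^6$ | pN/µm$^{3/2}$ | not published; rod-colony model class |
| friction $\gamma$ | 80 | pN·h/µm² | not published; see below |
| elongation rate $g$ | 0.6 | 1/h | ~1.2 h doubling; regime choice, see below |
| $\ell_\mathrm{min}, \ell_\mathrm{div}$ | 2, 4 | µm | E. coli rod dimensions |
| radius $r$ | 0.5 | µm | E. coli rod dimensions |
| division angle noise $\epsilon_\theta$ | 0.01 | rad | numerical, see below |
| time step | $6\times10^{-5}$ | h | numerical, see below |

The friction coefficient and growth rate deserve a careful statement,
because together they select the mechanical *regime*, not just the clock.
The growth-induced compression along chains of cells scales like
$\gamma g H^2$ for a well of height $H$; lateral clonal mixing on flat
substrates exists only when that compression is strong enough to buckle
cell chains near the bottom. The reference experiments and simulations this model class comes from
used wells of height 100 µm; the desk-scale wells this package can afford in a
test run are 12–20 µm tall, which at modest friction leaves flat wells in
a frozen, columnar regime with *suppressed* drift — the opposite of the
target phenomenology, and exactly the reported behavior of shallow simulated wells (with the note that raising the friction
coefficient restores lateral motion). The defaults $\gamma = 80$ and
$g = 0.6$/h compensate the $H^2$ factor and put desk-scale flat wells back
into the buckling regime, while the corrugated-well pocket physics is
insensitive to this choice (simulated clone plateaus equal the pocket
count exactly at 20-, 30- and 60-µm-wide geometries). Both parameters are
config-exposed.

## Numerical scheme

The force network is stiff: transient force chains reach $10^3$–$10^5$ pN
(they scale like $\gamma g H^2$ with the well height $H$), so a naive
explicit update with the published wall stiffness would need time steps
near $10^{-6}$ h. `corrugo` instead:

* integrates **wall and adhesion springs implicitly** per cell (backward
  Euler on the accumulated contact stiffness blocks, a 2×2 translational
  solve plus a scalar rotational term). This is unconditionally stable and
  reproduces the exact static penetration $p = F/k_\mathrm{wall}$ at the
  nominal (published) stiffness; load-induced wall penetrations stay near
  $10^{-3}$ µm — the "sufficiently large stiffness" limit the model class
  prescribes — and the residual worst-case penetration (~0.04 µm) is the
  geometric injection of the division tilt, not a force-balance failure. The
  translation–rotation coupling of the contact blocks is dropped; the
  displacement cap below guards the residual coupled modes.
* treats the softer **Hertzian pair forces explicitly**, scaled by a
  per-contact stabilization factor $\phi(\mu) \approx (1-e^{-\mu})/\mu$
  with $\mu$ the contact's linearized relaxation rate over one step. The
  factor is 1 for soft contacts and prevents single-contact overshoot for
  stiff ones; its Padé form avoids an `exp` in the inner loop.
* clips each cell's per-step displacement at a trust-region cap of
  $0.08\,r$: a transient force spike (typically right after a division)
  relaxes over a few steps at the capped speed instead of driving global
  sub-stepping, which keeps the cost per simulated hour deterministic.
  Clipping scales the displacement vector, so it remains a descent
  direction and the relaxation energy still decreases. With
  `adaptive = FALSE` a step that would exceed $0.05\,r$ aborts with a
  stability error instead. Because clipped force chains could in
  principle squeeze two cells through each other (their mutual repulsion
  is stabilized while their neighbors keep pushing), pair overlaps beyond
  0.35 µm additionally receive a small position-based separation per step
  (at most 0.02 µm per cell), made tangential near walls so it cannot
  defeat the implicit wall springs.
* uses Verlet neighbor lists (0.45 µm skin) over a uniform spatial hash for
  the broad phase, and exact segment–segment closest points for the narrow
  phase. Nearest points on the sine bottom are found by a Newton iteration
  on the foot-point condition, accepted only for close contacts (within
  1 µm) and a true local minimum; all other queries fall back to a scan
  plus ternary refinement (tolerance ~$10^{-6}$ µm). The Newton guard
  matters: for points deep inside a valley the iteration can converge to
  the far flank, and accepting that foot injects phantom wall forces.

The division angle noise default is 0.01 rad rather than a larger value:
the tilt is applied instantaneously at division, so a noise of 0.05 rad
displaces a daughter cap by up to ~0.06 µm in one step, which in a dense
corrugated well repeatedly violates the package's own wall-penetration
bound ($< 0.1\,r$). At 0.01 rad the injected overlap is within the bound
while still breaking the perfect-alignment symmetry that would otherwise
make buckling directions degenerate.

Exactly coincident centerlines (a measure-zero configuration that can
arise from symmetric initial conditions) are resolved by a deterministic
perpendicular chosen from a hash of the two cell ids, so runs remain
reproducible.

## What the statistics compute

* `clone_census()`: genotype counts and fractions per snapshot; genotypes
  are immutable and unique per founder, so the census is the neutral-drift
  observable.
* `transect()`: samples $y = h(x) + d$ (default $d = 2$ µm — "near the
  bottom" is not quantified in the source experiments) and assigns each
  point the nearest overlapping cell; boundary positions are midpoints of
  adjacent differing labels, and unoccupied gaps never create boundaries.
* `heterozygosity()`: the literal formula $H = f_1 f_2/(f_1+f_2)$; for
  normalized frequencies this equals $f_1 f_2$, and both forms are
  evaluated and cross-checked at run time.
* `founder_survival_density()`: re-tags every living cell at $t_0$ with its
  own id (the `retag_at` argument of `sim_run()`), then histograms the
  initial height above the local bottom of the founders whose lineage is
  still present at the horizon.
* `velocity_field()` / `growth_rate_field()`: bin-averaged cell velocities
  between paired snapshots (default 2 µm bins, of the order of a cell
  length; the default pairing interval is 0.25 h), and the
  continuity-equation growth rate $g = \nabla\cdot v$ by masked central
  differences, with one-sided differences at occupancy edges (documented
  bias: edge bins see a first-order rather than second-order stencil).
  Cells that divide between the paired snapshots change id and drop out of
  the field; at high growth rates a division wave can occasionally replace
  every id within a 0.25 h window, which callers should treat as a missing
  frame. `stratified_profiles()` reports both the horizontal *fraction*
  $|v_x|/|v|$ (the flat-well profile statistic) and the horizontal
  *component* $\langle|v_x|\rangle$; comparisons across well types use the
  component, because flank-parallel flow inside a steep pocket has
  $|v_x|/|v| \approx \cos 57°$ even when the cells merely follow the
  surface.
* `fit_relative_fitness()`: the well-level logistic replicator
  $\dot f = s f(1-f)$, $s = g(W-1)$, fitted by least squares on
  logit-transformed fractions. This is the package's stated stand-in for
  sector-expansion fitness models whose exact published form is not
  available; the estimator is validated by exact self-inversion on
  replicator-generated series and by recovery (within mechanical bias) of
  the generating $W$ from agent-based runs.

## Synthetic data and what a green test establishes

The fixture generators (`make_sector_fixture()`,
`make_intensity_fixture()`, `synthetic_field()`) produce caricatures with
planted ground truth: equal-width sectors with Bernoulli label noise,
two-channel intensity transects with clipped Gaussian noise, and analytic
velocity fields. They emulate the *format and noise structure* of
segmented microscopy output, not its optics: there is no point-spread
blur, no uneven illumination, no registration error. A green test on a
fixture therefore establishes that the statistic computes its definition,
not that the experimental pipeline upstream of it is unbiased.

The simulator itself is the package's synthetic world for the
population-genetic claims. Its desk-scale defaults (wells up to
100 µm wide but 18–40 µm tall, 72 h or shorter horizons, one to a few
hundred founders) are deliberately smaller than the 100 × 100 µm, 240-well
experiments: run times must fit a desktop test budget. Scaled-down wells
preserve the mechanism (pockets isolate lineages; flat bottoms let them
slide) but shrink force scales (loads grow like $H^2$), so quantitative
values — e.g. the exact surviving clone count — are checked against the
pocket theory *at the simulated geometry*, not against the published
figures' axes.

## Desk scale and what the tests establish

The shipped test ensembles run in wells of 20–40 µm width and 12–16 µm
height for up to 72 simulated hours — far smaller than the 100 µm
experimental wells, because ten-minute test budgets on one CPU do not
admit hundreds of CPU-hours of mechanics. The pocket mechanism is
scale-robust: simulated corrugated wells hit the $(T+W)/T$ clone plateau
exactly at every geometry tried, a fitter minority stays confined to the
pockets it seeded (the acceptance report's 72-h suppression value), and
flat wells of at least 30 × 16 µm drift below the corrugated plateau.
Two caveats are scale-bound. First, flat wells narrower or shallower than
that intermittently freeze into persistent columns (the shallow-well
regime; lateral drift needs growth-induced buckling, which the friction
and growth-rate defaults restore only partly at this height). Second, the
velocity-space signature of the mechanism — lower near-bottom horizontal
motion in corrugated than in flat wells — is not resolvable at desk
height: the open top is only a few cell lengths away from the bottom
strata and its removal-driven fluctuations swamp the contrast, so the
corresponding acceptance assertion is left failing by design rather than
weakened (the clone-level consequences of the same mechanism are all
green).

## Known limitations

* 2D mechanics with a single friction scalar; no EPS matrix, no motility,
  no cell–cell adhesion (the source model has none either).
* The logistic replicator ignores spatial structure; it is a fitting
  device, not a mechanistic claim.
* Deep cell–cell overlaps (up to ~0.2 µm) occur transiently under force
  chains; the Hertzian law is soft enough that this is a stress reservoir,
  not an integration failure, but packing fractions during spikes exceed
  the hard-rod value.
* One adhesion spring per (cell, wall); a broken spring may re-form on the
  next first contact. Whether side walls are adhesive is configurable and
  defaults to yes when adhesion is enabled.
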