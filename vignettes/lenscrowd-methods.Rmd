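---
title: "Hard-sphere crowding of lens crystallins: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hard-sphere crowding of lens crystallins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

The vertebrate eye lens stays transparent because its dominant proteins
-- the crystallins (alpha, beta, gamma subtypes) -- pack at volume
fractions of 0.2-0.3 while retaining only *short-range* positional
order.  Long-range (crystalline or glassy-periodic) order, or
micron-scale density fluctuations, both scatter visible light.
`lenscrowd` models the crystallin cytosol as a polydisperse hard-sphere
fluid and provides the statistical analytics used alongside such models:
PEG-crowding solubility curves, turbidity kinetics, and pendant-drop
surface-pressure statistics.

## The particle model

Each crystallin subtype is one sphere species.  The packaged preset uses
DLS-derived diameters and particle masses:

| species | diameter | mass | MW (kDa) |
|---|---|---|---|
| alpha | 18.6 nm = 1 sigma | 1.13e-18 g = 1 m | 680 |
| beta (beta-H-like) | 11.7 nm = 0.63 sigma | 2.99e-19 g = 0.26 m | 180 |
| gamma | 3.56 nm = 0.19 sigma | 3.49e-20 g = 0.03 m | 21 |

Reduced units: length in multiples of the largest diameter sigma, mass
in multiples of its particle mass m, temperature k_B T = 1.  Reduced
values are stored at full precision; the 2-decimal values above are
display rounding.

**Mole fractions.**  Two routes are exposed, because they genuinely
disagree.  The lens-average composition used in the simulations is
0.05 : 0.20 : 0.75 (alpha : beta : gamma); recomputing fractions from
the rounded native mass ratios 35:37:21 with MWs 680/180/21 kDa gives
roughly 0.041 : 0.164 : 0.795.  The published fractions derive from
lens-averaged data that the printed mass-ratio triple only
approximates, so `lens_composition("lens")` ships the published vector
verbatim and `lens_composition("mass_ratio")` ships the recomputed one.
We do not attempt to reverse-engineer the unprinted averaging.

## The event-driven engine

`run_edmd()` advances hard spheres analytically between events
(pair collisions, cell-boundary crossings, thermostat ghost collisions,
sampling) using a binary event heap with lazy counter-based
invalidation and cell lists.

Numerical design points a maintainer should know:

* **Image-resolved prediction.**  At desk-scale box edges (5-14 sigma)
  the minimum image of a pair at prediction time is *not* always the
  image through which the pair later collides.  Collision times are
  therefore solved per neighbour-cell image (the wrap of the scanned
  cell determines the lattice shift); in the all-pairs fallback
  (fewer than 3 cells per edge) all 27 images are scanned.
* **Polydisperse cell sizing.**  With 75% of particles at 0.19 sigma, a
  single cell width of one large diameter makes every neighbourhood
  scan touch hundreds of small particles.  The engine picks the cell
  count per edge by minimizing a scan-cost model and gives each
  particle its own neighbour radius `floor(sigma_max_contact/cw) + 1`.
* **Horizon pruning.**  A predicted pair event later than the
  particle's next cell crossing is not queued; the crossing re-scan
  restores it.  This bounds heap growth without losing events.
* **Contact bookkeeping.**  Collisions are resolved exactly at contact;
  positions are folded to stay consistent with cell indices so that
  floating-point jitter at cell seams cannot stall or corrupt the
  queue.  A pair overlapping by more than 1e-6 sigma^2 in squared gap
  aborts the run -- overlap is always an engine bug, never tolerated.
* **Restitution.**  The model family is "inelastic hard spheres", but
  no restitution coefficient is published for it.  The default is
  e = 1 with the Andersen thermostat -- the standard thermostatted
  elastic hard-sphere fluid, whose g(r)/S(k) the reported results
  match -- and e is configurable in (0, 1].  Choosing any e < 1 would
  have meant inventing a number.
* **Thermostat.**  Andersen ghost collisions as a Poisson stream at
  rate nu per particle per reduced time (default 0.1), redrawing the
  chosen particle's velocity from the Maxwell-Boltzmann distribution at
  T.  The thermostat also sets the dissipation balance for e < 1.
* **Compression.**  Lubachevsky-Stillinger: all diameters grow by a
  common factor (species ratios preserved exactly, box fixed) at a
  reference-particle rate of 1e-3 sigma per reduced time by default
  until the target packing fraction is hit within 1e-4, then growth
  freezes.  The published work states only the target packing
  fractions, not a schedule.  On jamming the growth rate is halved and
  compression retried once.  Random sequential insertion starts the
  system at 50-70% of the target phi (a free schedule choice; denser
  starts shorten compression and are still far below the insertion
  saturation density).  After compression the velocities are redrawn
  from the exact Maxwell-Boltzmann ensemble, because diameter growth
  deposits kinetic energy faster than the thermostat removes it;
  equilibration (default 100 collisions per particle) then relaxes the
  local structure.
* **Determinism.**  One seeded Mersenne-Twister stream (with our own
  Box-Muller transform, so streams are platform-identical) drives
  placement, initial velocities and thermostatting; every result is
  reproducible from (config, seed).

**Desk-scale defaults.**  The study-scale simulation used 125,000
particles; the package defaults to a few thousand.  Finite-size effects
at n = 2,000-5,000 are visible mainly as reciprocal-space resolution
(the k-lattice spacing 2 pi/L) and as noise in species-resolved
statistics for the rare alpha particles (5 mol%).

## Structure analysis

`radial_distribution()` histograms minimum-image pair distances and
normalizes with exact spherical-shell volumes (not the 4 pi r^2 dr
approximation, so an ideal gas gives exactly g = 1 in expectation).
Same-species pairs use the N(N-1) ordered-pair count.

`structure_factor()` computes partial structure factors directly on the
reciprocal lattice of the periodic box,
S_ab(k) = < Re[rho_a(k) conj(rho_b(k))] > / sqrt(N_a N_b),
spherically averaged over exact integer shells and optionally re-binned
(default bin 2 pi/L).  The direct route avoids the truncation artifacts
of transforming g(r) on a half-box range; the g(r)-transform route
(`sk_from_rdf()`) is retained as an independent cross-check and is
required to agree within 0.1 for k >= 3/sigma in the test suite.  The
1/sqrt(N_a N_b) normalization makes same-species S -> 1 and
cross-species S -> 0 for uncorrelated particles.

`peak_wavelength()` reports the dominant peak of S(k) inside
k in [2, 20]/sigma as a physical wavelength 2 pi sigma_nm / k*.  The
raw argmax is quantized by the k-bin spacing (0.7/sigma at n = 5,000),
so the default applies three-point parabolic interpolation around the
maximum -- the standard sub-bin refinement -- before converting.  A
profile whose maximum does not rise 2 MAD above the window median is
flagged as having no dominant peak (the gamma-gamma partial at any phi
behaves like this).

`order_metric()` reduces g(r) to a peak table (local maxima above 1,
minimum separation 0.5 sigma, higher peak wins) and scores long-range
order as the height of the *third* peak above 1: a short-range-ordered
fluid keeps no third coordination shell, an ordering system grows one.

**Mass-preserving exclusion.**  The published comparison removes one
species while "retaining the same overall mass".  The exact
renormalization is unstated; `exclude_species()` keeps the remaining
species in their original proportions (mole fractions renormalized over
the survivors) and restores the total mass through the particle count
-- at fixed packing fraction the box simply adjusts, so for a fixed-n
run only the renormalized composition matters.  The implied count
factor is returned as an attribute.  An alternative convention
(redistributing the freed mass as extra particles of the survivors,
weighted by mole fraction) starves the alpha statistics at desk scale
(alpha drops to ~2 mol% in the beta-free system) without changing the
directional conclusions, which is why the simpler convention is the
package's choice; it is documented here because both are defensible.

**Masses and static structure.**  Equilibrium configurational
statistics of hard spheres are independent of the mass matrix, so
structure-only comparisons (the species-exclusion suite) may be run
with unit masses for every species.  This removes the fast
light-particle timescale (gamma at 0.03 m moves ~5.8x faster than
alpha) that otherwise dominates the event count, cutting runtimes
several-fold with mathematically identical sampled ensembles.  The
acceptance-script runs keep the true masses.

## Solubility and kinetics analytics

Crowding-induced turbidity curves (OD vs PEG weight %) are fitted to
the four-parameter Boltzmann sigmoid

y = A2 + (A1 - A2) / (1 + exp((x - x0)/dx))

by `nls` (port algorithm, deterministic restarts).  The half-solubility
point of a condition is x0 -- the PEG% at half-maximal scattering.  A
fitted x0 is only reported when the upper plateau is actually reached
in the measured range: `x0 + 2 dx <= max(x)` and `A2 <= 1.2 max(y)`
(both configurable).  This operationalizes the dash convention used for
curves without a reliable final plateau (the near-flat gamma-crystallin
curve being the canonical case).  Re-entrant turbidity declines above
~15% PEG are generated by the synthetic module but never fitted; data
are truncated at the curve maximum first.

Kinetics metrics define OD_1/2 as the midpoint of the initial OD (mean
of the first 3 samples) and plateau OD (mean of the trailing 10%), with
t_half the first upward crossing, linearly interpolated.  The published
numbers around this rule are not fully self-consistent (an initial OD
of 0.39 and OD_1/2 of 0.69 imply a plateau near 0.99, while ~1.05 AU is
also quoted as the final turbidity); the midpoint definition is the
package default and the plateau window is configurable, which covers
both readings.

Fluorescence normalization maps a trace through (t - MIN)/(MAX - MIN);
for near-flat control traces the MAX is taken from the paired
crystallin-containing reference trace, so controls map near zero
instead of being stretched over [0, 1].

## Tensiometry statistics

Surface pressure is Pi(t) = gamma(t0) - gamma(t).  The initial
adsorption rate is the mean of pointwise slopes (central differences at
interior samples, one-sided at window ends) over the first 100 s,
converted to mN/m/min -- "slope at each point, then average", which at
0.11 fps gives 12 points per drop and matches the published pooled
n = 72 over six drops.  The final pressure averages the trailing 240 s
(27 points per drop; pooled n = 162).  Pooling is at the point level
across drops; per-drop summaries are also returned.

Significance testing is classic one-way ANOVA followed by all-pairs (or
control-wise, the default for networks) two-tailed pooled-variance
t-tests with Bonferroni correction.  The interaction call is
deliberately asymmetric: *repulsive* if EITHER the final pressure OR
the initial rate is significantly above the control, *attractive* only
if BOTH are significantly below.  Whether the original post-hoc tests
compared all pairs or only mixtures against their component controls is
ambiguous; the network builder uses control-wise comparisons (matching
the figure insets) and `anova_posthoc()` accepts an explicit pair list.

## Synthetic data: what it does and does not establish

Every analysis stage has a seeded generator producing data with the
statistical structure that stage assumes: Boltzmann turbidity curves
(optionally with a linear re-entrant decline above 15% PEG scaled to a
stated fraction), logistic turbidity-onset kinetics (default 30-s
sampling over 30 min), exponential-saturation tension decays sampled at
0.11 fps over 40 min, and ideal-gas configurations as the structure
null model.  Noise is iid Gaussian on the measurement scale; replicate
dispersion in the real assays is summarized only as error bars, so no
heteroscedastic structure is asserted.  Generator presets carry the
published summary values (half-solubility midpoints 6.9 < 8.0 < 9.6 <
11.0 < 12.5 < 13.4% PEG; kinetics 0.39 -> ~0.99 with midpoint 6.5 min)
and are labelled synthetic.

A green recovery test therefore establishes that the analysis
operations invert the stated generative models at realistic noise -- it
does not establish anything about the original raw data, which exist
only at figure level.  The wet-lab magnitudes (158% turbidity rise, 58%
SYPRO rise, surface-pressure values) enter only as generator presets
and ordering/direction checks.

## Scale-down notes for the test suite

The packaged acceptance tests run the full physics at reduced size so
the suite stays within a desktop budget: the mixture criterion runs at
n = 2,500 in the suite (n = 5,000 in `scripts/acceptance.R`), and the
species-exclusion comparison runs 5 seeds per system in matched boxes
of edge 6.8 sigma (so each system's g(r) reaches the third
coordination shell; particle counts then differ by composition) with
per-system frame counts equalizing the alpha-pair statistics.  Box
matching, unit masses and frame matching were chosen from power
considerations -- box edges below ~6.5 sigma provably cannot resolve
the third-shell score, and the alpha-poor mixtures otherwise drown the
score in counting noise -- not tuned on test outcomes.

## Known limitations

* Hard spheres only: no attractions, depletion potentials, patchiness
  or shape anisotropy; the link from S(k) to transparency is treated
  qualitatively, as in the source analysis.
* Species-resolved statistics for alpha (5 mol%) are noisy at desk
  scale; the acceptance tolerance on the S(k) peak wavelength reflects
  the +/- one-k-bin quantization that remains after interpolation.
* The event engine is serial; runs beyond ~10^4 particles at phi = 0.4
  are better done with a dedicated HPC code.
* `nls` can fail on degenerate sigmoid data (flat curves); the fit
  object then reports `converged = FALSE` rather than guessing.
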