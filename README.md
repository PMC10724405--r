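# lenscrowd

Hard-sphere crowding simulations and assay analytics for eye-lens
crystallin transparency.

## What this package is for

The vertebrate lens stays transparent because its crystallin proteins
(alpha, beta and gamma subtypes, ~90% of soluble lens protein) pack at
volume fractions phi = 0.2-0.3 with *short-range* order only: long-range
(periodic) order, and large density fluctuations, scatter light.
`lenscrowd` is for researchers who want to reproduce and extend the
computational side of that picture on a desktop:

* an **event-driven molecular dynamics (EDMD)** engine for polydisperse
  (optionally inelastic, restitution e in (0,1]) hard spheres in a cubic
  periodic box, with Lubachevsky-Stillinger compression to a target
  packing fraction and an Andersen thermostat at reduced temperature
  T = 1;
* species-resolved **radial distribution functions** g_ab(r) and
  **partial static structure factors** S_ab(k) (computed directly on the
  periodic-box reciprocal lattice), with conversion from reduced to
  physical units via sigma = 18.6 nm (the alpha-crystallin DLS diameter)
  and peak/long-range-order summaries;
* the accompanying wet-lab **statistics**: Boltzmann-sigmoid fits of
  PEG-crowding turbidity curves
  `y = A2 + (A1 - A2)/(1 + exp((x - x0)/dx))` (half-solubility = x0,
  with a plateau-reliability rule), turbidity-kinetics metrics (OD_1/2,
  t_half, percent increase), min-max fluorescence normalization with the
  control-MAX rule, and pendant-drop surface-pressure analysis
  (Pi(t) = gamma(t0) - gamma(t), initial rate over the first 100 s,
  final pressure over the last 240 s, one-way ANOVA with Bonferroni
  post-hoc t-tests, attractive/repulsive interaction calls);
* seeded **synthetic-data generators** for every assay, so the entire
  pipeline is testable offline.

The crystallin particle model (packaged presets): alpha 18.6 nm /
1.13e-18 g, beta 11.7 nm / 2.99e-19 g (0.63 sigma, 0.26 m), gamma
3.56 nm / 3.49e-20 g (0.19 sigma, 0.03 m), lens mole fractions
0.05 : 0.20 : 0.75.

## Worked example

Simulate the three-species lens mixture at phi = 0.4 and locate the
dominant alpha-alpha structure-factor peak (desk scale, a few minutes):

```r
library(lenscrowd)

set <- lens_composition()          # alpha:beta:gamma = 0.05:0.20:0.75
print(set)
#> Reduced-unit species set (sigma = 18.6 nm, m = 1.13e-18 g)
#>   name d_sigma m_ref mole_fraction
#>  alpha    1.00  1.00          0.05
#>   beta    0.63  0.26          0.20
#>  gamma    0.19  0.03          0.75

cfg <- sim_config(5000, set, target_phi = 0.4, seed = 42,
                  growth_rate = 5e-3, start_phi_fraction = 0.7)
sim <- simulate_system(cfg, n_frames = 50, sample_interval = 0.4)

sk <- structure_factor(sim$traj, "alpha", k_max = 25)
peak_wavelength(sk, k_window = c(2, 20))
#> $k_star        7.17
#> $wavelength_nm 16.3
#> $s_max         1.22
#> $dominant      TRUE
```

The dominant alpha-alpha correlation length converts to roughly 16 nm
at this desk scale (the study-scale value, at 25x more particles and
finer k resolution, is ~18 nm) -- i.e., the mixture's alpha spacing
stays near one alpha diameter, short-range-ordered, with no long-range
peaks.  A monodisperse alpha run at the same phi instead shows g(r)
peaks marching out at r = 1, 2, 3 sigma (its first maximum sits at
r = 1.01 sigma with bin width 0.02):

```r
mono <- to_reduced_units(crystallin_species()[1, ], mole_fraction = 1)
sim1 <- simulate_system(sim_config(2000, mono, 0.4, seed = 7,
                                   growth_rate = 5e-3))
g <- radial_distribution(sim1$traj, "alpha")
g$r_centers[which.max(g$g)]
#> [1] 1.01
```

Fit a synthetic solubility curve and read off the half-solubility
point:

```r
d <- gen_turbidity(a1 = 0.2, a2 = 1.6, x0 = 6.9, dx = 0.8,
                   noise_sd = 0.03, seed = 1)
fit_boltzmann(d$peg_percent, d$od)
#> Boltzmann fit: A1 = 0.200, A2 = 1.607, x0 = 6.87, dx = 0.79 (adj R2 = 0.998)
#>   1/2-solubility: 6.87 % PEG
```

## Command line

A launcher is installed at `inst/exec/lenscrowd`:

```sh
lenscrowd simulate --n 2000 --phi 0.1,0.2,0.3,0.4 --out runs/ --seed 1
lenscrowd structure sk --traj runs/traj_phi0.40.xyz --pair alpha:alpha --out sk.csv
lenscrowd assays fit-solubility --in turbidity.csv --out fits.csv
lenscrowd tension analyze --in tension.csv --out stats/ --alpha 0.05
lenscrowd synth turbidity --out demo.csv --seed 3
```

Every run writes a `manifest.txt` (config echo + package version +
seed) beside its outputs.

## Further reading

The methods vignette (`vignettes/lenscrowd-methods.Rmd`) documents the
model assumptions, every tunable parameter with units and defaults, the
numerical design of the event engine, what the synthetic generators do
and do not emulate, and known limitations.
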