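#' Synthetic PEG-turbidity curves
#'
#' Generates Boltzmann-sigmoid turbidity curves with iid Gaussian noise,
#' optionally with the re-entrant decline seen at extreme crowding:
#' above `reentrant_threshold` the noiseless value declines linearly so
#' that the value at the last grid point is reduced by
#' `reentrant_fraction` relative to the value at the threshold.
#'
#' @param a1,a2 lower/upper plateaus (absorbance units).
#' @param x0 midpoint (PEG %).
#' @param dx transition width (PEG %), positive.
#' @param x_grid PEG percentages to sample (default 0..20 by 1).
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_replicates number of noisy replicates.
#' @param reentrant_fraction optional decline fraction (e.g. 0.286);
#'   `NULL` disables the re-entrant regime.
#' @param reentrant_threshold PEG % above which the decline applies.
#' @param seed integer RNG seed.
#' @return data frame with columns `replicate`, `peg_percent`, `od`.
#' @export
gen_turbidity <- function(a1, a2, x0, dx, x_grid = seq(0, 20, by = 1),
                          noise_sd = 0, n_replicates = 1,
                          reentrant_fraction = NULL,
                          reentrant_threshold = 15, seed = 1) {
  stopifnot(dx > 0, noise_sd >= 0)
  base <- a2 + (a1 - a2) / (1 + exp((x_grid - x0) / dx))
  if (!is.null(reentrant_fraction)) {
    hi <- x_grid > reentrant_threshold
    if (any(hi)) {
      y_thr <- a2 + (a1 - a2) / (1 + exp((reentrant_threshold - x0) / dx))
      span <- max(x_grid) - reentrant_threshold
      frac <- (x_grid[hi] - reentrant_threshold) / span
      base[hi] <- y_thr * (1 - reentrant_fraction * frac)
    }
  }
  withr_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(replicate = r, peg_percent = x_grid,
                 od = base + stats::rnorm(length(x_grid), 0, noise_sd))
    }))
  })
}

#' Synthetic turbidity-kinetics trace (logistic onset)
#'
#' `OD(t) = od0 + (od_f - od0) / (1 + exp(-(t - t_half)/tau))` plus iid
#' Gaussian noise, sampled every `dt` minutes over `duration` minutes.
#' Defaults emulate a plate-reader acquisition at 30-s intervals over
#' 30 min.
#'
#' @param od0,od_f initial and final optical densities.
#' @param t_half midpoint time (minutes).
#' @param tau logistic time constant (minutes), positive.
#' @param duration total duration (minutes, default 30).
#' @param dt sampling interval (minutes, default 0.5).
#' @param noise_sd Gaussian noise SD.
#' @param seed integer RNG seed.
#' @return data frame with columns `time`, `od`.
#' @export
gen_kinetics <- function(od0, od_f, t_half, tau, duration = 30, dt = 0.5,
                         noise_sd = 0, seed = 1) {
  stopifnot(tau > 0, noise_sd >= 0)
  t <- seq(0, duration, by = dt)
  y <- od0 + (od_f - od0) / (1 + exp(-(t - t_half) / tau))
  withr_seed(seed, {
    data.frame(time = t, od = y + stats::rnorm(length(t), 0, noise_sd))
  })
}

#' Synthetic pendant-drop tension traces
#'
#' Exponential-saturation adsorption model:
#' `gamma(t) = (gamma0 - pi_final) + pi_final * exp(-t / rate_constant)`,
#' so the implied surface-pressure plateau is `pi_final` and the initial
#' pressure rise rate is `pi_final / rate_constant` (per second).
#' Sampled at the tensiometer frame rate (default 0.11 fps over 40 min).
#'
#' @param gamma0 initial surface tension (mN/m).
#' @param pi_final surface-pressure plateau (mN/m).
#' @param rate_constant adsorption time constant (s), positive.
#' @param duration total duration (s, default 2400).
#' @param fps frame rate (default 0.11).
#' @param noise_sd Gaussian noise SD on gamma.
#' @param n_drops number of replicate drops.
#' @param condition condition label.
#' @param seed integer RNG seed.
#' @return data frame with columns `condition`, `drop_id`, `time_s`,
#'   `gamma`.
#' @export
gen_tension <- function(gamma0 = 72, pi_final = 12, rate_constant = 240,
                        duration = 2400, fps = 0.11, noise_sd = 0,
                        n_drops = 1, condition = "sample", seed = 1) {
  stopifnot(rate_constant > 0, noise_sd >= 0)
  t <- seq(0, duration, by = 1 / fps)
  base <- (gamma0 - pi_final) + pi_final * exp(-t / rate_constant)
  withr_seed(seed, {
    do.call(rbind, lapply(seq_len(n_drops), function(d) {
      data.frame(condition = condition,
                 drop_id = paste0(condition, "_drop", d),
                 time_s = t,
                 gamma = base + stats::rnorm(length(t), 0, noise_sd),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Synthetic ideal-gas (Poisson) configurations
#'
#' Uniformly random, uncorrelated particle positions in a cubic periodic
#' box — the null model against which g(r) = 1 and S(k) = 1 (same
#' species) / S(k) = 0 (cross species) are checked.
#'
#' @param n_per_species integer vector of per-species counts.
#' @param box_edge cubic box edge (sigma units).
#' @param n_frames number of independent frames.
#' @param sigma_nm physical diameter of the reference species (optional
#'   metadata for unit conversion).
#' @param seed integer RNG seed.
#' @return an `hs_traj` object (see [run_edmd()]).
#' @export
gen_ideal_gas_frames <- function(n_per_species, box_edge, n_frames = 1,
                                 sigma_nm = NA_real_, seed = 1) {
  stopifnot(all(n_per_species >= 1), box_edge > 0, n_frames >= 1)
  n <- sum(n_per_species)
  species <- rep(seq_along(n_per_species), n_per_species)
  withr_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(f) {
      list(positions = matrix(stats::runif(3 * n, 0, box_edge), ncol = 3),
           time = f - 1)
    })
  })
  structure(list(frames = frames, species = as.integer(species),
                 diameters = rep(0, n), box_edge = box_edge,
                 sigma_nm = sigma_nm, phi = 0),
            class = "hs_traj")
}

## run `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Demonstration presets built from the published assay summaries
#'
#' Returns generator parameter sets whose midpoints follow the published
#' half-solubility table (alpha 6.9 < ALL-1mg 8.0 < beta_H 9.6 <
#' beta_H:beta_L 11.0 < beta_H:gamma 12.5 < beta_L 13.4 % PEG) and the
#' hydrogel kinetics summary (initial OD 0.39, plateau near 0.99,
#' midpoint 6.5 min).  All data generated from these presets are
#' synthetic stand-ins for the original figure-level measurements.
#'
#' @return list with elements `turbidity` (data frame of condition, a1,
#'   a2, x0, dx) and `kinetics` (list od0, od_f, t_half, tau).
#' @export
synthetic_presets <- function() {
  list(
    turbidity = data.frame(
      condition = c("alpha", "ALL_1mg", "beta_H", "beta_H:beta_L",
                    "beta_H:gamma", "beta_L"),
      a1 = 0.2, a2 = 1.6,
      x0 = c(6.9, 8.0, 9.6, 11.0, 12.5, 13.4),
      dx = 0.8, stringsAsFactors = FALSE),
    kinetics = list(od0 = 0.39, od_f = 0.99, t_half = 6.5, tau = 1.5)
  )
}
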