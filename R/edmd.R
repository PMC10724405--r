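#' Simulation configuration for the hard-sphere engine
#'
#' Collects the knobs of an event-driven hard-sphere run in reduced
#' units (lengths in sigma, the diameter of the largest species; masses
#' in m, its particle mass; k_B T = 1).
#'
#' @param n_particles total particle count.
#' @param species_set a `species_set` (see [to_reduced_units()]).
#' @param target_phi target packing fraction, in (0, 0.64).
#' @param temperature reduced temperature (default 1).
#' @param restitution coefficient of restitution e in (0, 1]; e = 1 is
#'   the elastic hard-sphere fluid (default; the thermostatted elastic
#'   setup is the standard reference system for g(r)/S(k) of crowded
#'   colloids, and no particular inelasticity is singled out here).
#' @param thermostat_rate Andersen ghost-collision rate per particle per
#'   reduced time (default 0.1; 0 disables the thermostat).
#' @param growth_rate compression diameter-growth rate of the reference
#'   species, sigma per reduced time (default 1e-3).
#' @param seed integer seed controlling every stochastic element.
#' @param equilibration_collisions_per_particle collisions per particle
#'   after reaching the target phi before production sampling
#'   (default 100).
#' @param start_phi_fraction packing fraction at random insertion, as a
#'   fraction of `target_phi` (default 0.5).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_particles, species_set, target_phi,
                       temperature = 1, restitution = 1,
                       thermostat_rate = 0.1, growth_rate = 1e-3,
                       seed = 1, equilibration_collisions_per_particle = 100,
                       start_phi_fraction = 0.5) {
  stopifnot(inherits(species_set, "species_set"))
  if (target_phi <= 0 || target_phi >= 0.64) stop("target_phi must be in (0, 0.64)")
  if (restitution <= 0 || restitution > 1) stop("restitution must be in (0, 1]")
  if (thermostat_rate < 0) stop("thermostat_rate must be >= 0")
  if (temperature <= 0) stop("temperature must be positive")
  if (growth_rate <= 0) stop("growth_rate must be positive")
  structure(list(n_particles = as.integer(n_particles),
                 species_set = species_set, target_phi = target_phi,
                 temperature = temperature, restitution = restitution,
                 thermostat_rate = thermostat_rate, growth_rate = growth_rate,
                 seed = as.integer(seed),
                 equilibration_collisions_per_particle =
                   equilibration_collisions_per_particle,
                 start_phi_fraction = start_phi_fraction),
            class = "sim_config")
}

#' Initialize a non-overlapping hard-sphere state
#'
#' Sizes a cubic periodic box so that the nominal reduced diameters
#' realize `target_phi`, then places the particles by random sequential
#' insertion at the dilute `start_phi` (diameters uniformly shrunk) and
#' draws Maxwell-Boltzmann velocities at the configured temperature with
#' zero total momentum.  [compress_to_phi()] grows the diameters back to
#' nominal, reaching `target_phi`.
#'
#' @param config a `sim_config`.
#' @return object of class `sim_state`: positions (n x 3, wrapped into
#'   the box), velocities, current `diameters`, `diameters_target`,
#'   masses, integer species ids, `box_edge`, `time`.
#' @export
init_state <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set <- config$species_set
  counts <- realize_counts(set, config$n_particles)
  species <- rep(seq_along(counts), counts)
  dnom <- set$reduced_diameter[species]
  masses <- set$reduced_mass[species]
  L <- box_edge_for_phi(counts, set$reduced_diameter, config$target_phi)
  start_phi <- config$start_phi_fraction * config$target_phi
  lam0 <- (start_phi / config$target_phi)^(1 / 3)
  d0 <- dnom * lam0
  ord <- order(d0, decreasing = TRUE)   # insert largest spheres first
  pos <- matrix(NA_real_, length(species), 3)
  pos[ord, ] <- cpp_place_random(d0[ord], L, config$seed, 20000L)
  vel <- withr_seed(config$seed + 1L, {
    v <- matrix(stats::rnorm(3 * length(species)), ncol = 3)
    v <- v * sqrt(config$temperature / masses)
    # remove centre-of-mass momentum
    sweep(v, 2, colSums(v * masses) / sum(masses))
  })
  structure(list(positions = pos, velocities = vel, diameters = d0,
                 diameters_target = dnom, masses = masses,
                 species = as.integer(species),
                 species_names = set$species$name,
                 sigma_nm = set$sigma_nm,
                 box_edge = L, time = 0),
            class = "sim_state")
}

#' Current packing fraction of a state
#' @param state a `sim_state`.
#' @return dimensionless phi.
#' @export
state_phi <- function(state) {
  packing_fraction(rep(1, length(state$diameters)), state$diameters,
                   state$box_edge)
}

#' Kinetic temperature of a state
#'
#' `T_kin = sum(m v^2) / (3 n)` in reduced units.
#' @param state a `sim_state`.
#' @export
kinetic_temperature <- function(state) {
  sum(state$masses * rowSums(state$velocities^2)) /
    (3 * length(state$masses))
}

#' Kinetic energy and total momentum of a state
#' @param state a `sim_state`.
#' @return list with `energy` and 3-vector `momentum`.
#' @export
state_invariants <- function(state) {
  list(energy = 0.5 * sum(state$masses * rowSums(state$velocities^2)),
       momentum = colSums(state$velocities * state$masses))
}

#' Compress a state to its target packing fraction
#'
#' Lubachevsky-Stillinger compression: all diameters grow uniformly (so
#' species diameter ratios are preserved exactly) at the configured
#' growth rate while events are processed, until the packing fraction
#' reaches the target, after which growth is frozen.  If the system jams
#' before the target (collision rate diverging), the growth rate is
#' halved and compression retried once from the jammed state; a second
#' jam is an error reporting the achieved phi.
#'
#' @param state a `sim_state` from [init_state()].
#' @param config the `sim_config`.
#' @return the compressed `sim_state` (diameters at nominal, phi at
#'   target within 1e-4).
#' @export
compress_to_phi <- function(state, config) {
  stopifnot(inherits(state, "sim_state"))
  phi_now <- state_phi(state)
  if (abs(phi_now - config$target_phi) < 1e-12) return(state)
  if (phi_now > config$target_phi) stop("state already above target phi")
  dnom <- state$diameters_target
  lam0 <- state$diameters[1] / dnom[1]
  g_lam <- config$growth_rate / max(dnom)   # lambda growth per unit time
  n <- length(state$masses)
  for (attempt in 1:2) {
    res <- cpp_edmd(state$positions, state$velocities, dnom, state$masses,
                    state$box_edge, config$restitution,
                    config$thermostat_rate, config$temperature,
                    g_lam, lam0,
                    max_collisions = Inf, t_end = Inf,
                    sample_interval = 0, max_samples = 0L,
                    jam_limit = 2e4 * n + 1e6,
                    seed = config$seed + 2L + attempt,
                    record_events = FALSE)
    state$positions <- res$positions
    state$velocities <- res$velocities
    state$diameters <- dnom * res$lambda
    state$time <- state$time + res$time
    lam0 <- res$lambda
    if (!res$jammed) break
    if (attempt == 2) {
      stop(sprintf("jamming before target phi: achieved phi = %.4f",
                   state_phi(state)))
    }
    g_lam <- g_lam / 2
  }
  if (abs(state_phi(state) - config$target_phi) > 1e-4) {
    stop(sprintf("compression missed target: phi = %.6f", state_phi(state)))
  }
  state
}

#' Run event-driven dynamics from a state
#'
#' Processes events in time order until either `n_collisions` pair
#' collisions have occurred or `duration` reduced time has elapsed
#' (whichever first; at least one must be finite unless sampling is the
#' stop criterion).  Frames may be sampled at a fixed interval into an
#' `hs_traj` trajectory.
#'
#' @param state a `sim_state` (at fixed diameters; compress first).
#' @param config the `sim_config`.
#' @param n_collisions stop after this many collisions (default Inf).
#' @param duration stop after this much reduced time (default Inf).
#' @param sample_interval reduced-time spacing of sampled frames
#'   (0 = no sampling).
#' @param max_samples cap on sampled frames.
#' @param thermostat logical; apply the Andersen thermostat at the
#'   configured rate (default TRUE).
#' @param record_events record the (time, i, j) collision stream
#'   (for validation; memory-heavy on long runs).
#' @param seed_offset added to the config seed for this phase's RNG.
#' @return list with the advanced `state`, `traj` (an `hs_traj`, possibly
#'   zero frames), `n_collisions`, `elapsed` reduced time, `virial_sum`
#'   and (optionally) `events` as a data frame with 1-based indices.
#' @export
run_edmd <- function(state, config, n_collisions = Inf, duration = Inf,
                     sample_interval = 0, max_samples = 0L,
                     thermostat = TRUE, record_events = FALSE,
                     seed_offset = 10L) {
  stopifnot(inherits(state, "sim_state"))
  if (!is.finite(n_collisions) && !is.finite(duration) && max_samples <= 0) {
    stop("no stop criterion: give n_collisions, duration or samples")
  }
  nu <- if (thermostat) config$thermostat_rate else 0
  res <- cpp_edmd(state$positions, state$velocities, state$diameters,
                  state$masses, state$box_edge, config$restitution,
                  nu, config$temperature,
                  growth_rate = 0, lam0 = 1,
                  max_collisions = n_collisions, t_end = duration,
                  sample_interval = sample_interval,
                  max_samples = as.integer(max_samples),
                  jam_limit = Inf,
                  seed = config$seed + seed_offset,
                  record_events = record_events)
  t0 <- state$time
  state$positions <- res$positions
  state$velocities <- res$velocities
  state$time <- state$time + res$time
  frames <- lapply(seq_along(res$samples), function(k) {
    list(positions = res$samples[[k]],
         velocities = res$sample_velocities[[k]],
         time = t0 + res$sample_times[[k]])
  })
  traj <- structure(list(frames = frames, species = state$species,
                         species_names = state$species_names,
                         diameters = state$diameters,
                         box_edge = state$box_edge,
                         sigma_nm = state$sigma_nm,
                         phi = state_phi(state)),
                    class = "hs_traj")
  events <- NULL
  if (record_events && !is.null(res$events)) {
    events <- data.frame(time = t0 + res$events$t,
                         i = res$events$i + 1L, j = res$events$j + 1L)
  }
  list(state = state, traj = traj,
       n_collisions = res$n_collisions, elapsed = res$time,
       virial_sum = res$virial_sum, events = events)
}

#' @export
print.hs_traj <- function(x, ...) {
  cat(sprintf("hs_traj: %d frames, %d particles, box %.3f sigma, phi %.3f\n",
              length(x$frames), length(x$species), x$box_edge, x$phi))
  invisible(x)
}

#' Full simulation pipeline: place, compress, equilibrate, sample
#'
#' Convenience driver used by the analysis examples: builds the state,
#' compresses to the target phi, equilibrates for the configured number
#' of collisions per particle under the Andersen thermostat, then runs a
#' production phase sampling `n_frames` frames `sample_interval` apart.
#'
#' @param config a `sim_config`.
#' @param n_frames production frames to sample.
#' @param sample_interval reduced-time spacing between frames
#'   (default 0.5).
#' @return list with `traj` (`hs_traj`), final `state`, and a
#'   `diagnostics` list (collision counts, kinetic temperature).
#' @export
simulate_system <- function(config, n_frames = 50, sample_interval = 0.5) {
  state <- init_state(config)
  state <- compress_to_phi(state, config)
  # compression pumps kinetic energy in faster than the thermostat drains
  # it; restart the velocities from the exact Maxwell-Boltzmann ensemble
  # so equilibration only has to relax the local structure
  state <- resample_velocities(state, config)
  eq <- run_edmd(state, config,
                 n_collisions = config$equilibration_collisions_per_particle *
                   config$n_particles,
                 seed_offset = 20L)
  pr <- run_edmd(eq$state, config,
                 sample_interval = sample_interval,
                 max_samples = n_frames, seed_offset = 30L)
  list(traj = pr$traj, state = pr$state,
       diagnostics = list(
         equilibration_collisions = eq$n_collisions,
         production_collisions = pr$n_collisions,
         production_time = pr$elapsed,
         virial_sum = pr$virial_sum,
         kinetic_temperature = kinetic_temperature(pr$state),
         phi = state_phi(pr$state)))
}

#' Redraw all velocities from the Maxwell-Boltzmann distribution
#'
#' Fresh Gaussian velocities at the configured temperature with the
#' centre-of-mass momentum removed.  Used after compression, where
#' diameter growth deposits kinetic energy faster than the thermostat
#' removes it.
#'
#' @param state a `sim_state`.
#' @param config the `sim_config` (temperature and seed).
#' @return the state with new velocities.
#' @export
resample_velocities <- function(state, config) {
  n <- length(state$masses)
  state$velocities <- withr_seed(config$seed + 5L, {
    v <- matrix(stats::rnorm(3 * n), ncol = 3) *
      sqrt(config$temperature / state$masses)
    sweep(v, 2, colSums(v * state$masses) / sum(state$masses))
  })
  state
}

#' Predict the contact time of a single sphere pair
#'
#' Solves `|dr + dv t| = (d1 + d2)/2` (minimum-image convention) for the
#' smallest positive root.  Returns `NA` if the pair never meets
#' (receding, or the discriminant is negative).
#'
#' @param r1,r2 position 3-vectors.
#' @param v1,v2 velocity 3-vectors.
#' @param d1,d2 diameters.
#' @param box_edge periodic box edge (`Inf` for free space).
#' @return earliest positive contact time, or `NA_real_`.
#' @export
predict_pair_collision <- function(r1, v1, d1, r2, v2, d2, box_edge = Inf) {
  dr <- r1 - r2
  if (is.finite(box_edge)) dr <- dr - box_edge * round(dr / box_edge)
  dv <- v1 - v2
  sig <- (d1 + d2) / 2
  A <- sum(dv * dv)
  B <- sum(dr * dv)
  C <- sum(dr * dr) - sig^2
  if (C < -1e-9 * sig^2) stop("overlapping input pair")
  if (C <= 0) return(if (B < 0) 0 else NA_real_)
  if (B >= 0) return(NA_real_)
  disc <- B^2 - A * C
  if (disc < 0) return(NA_real_)
  C / (-B + sqrt(disc))
}

#' Resolve a hard-sphere collision impulse
#'
#' Applies the restitution-e normal impulse to a pair at contact:
#' the normal relative velocity is scaled by `-e` and the impulse
#' `mu (1+e) (dv . n)` is shared by the inverse masses, conserving
#' momentum exactly (and kinetic energy when `e = 1`).
#'
#' @param v1,v2 velocity 3-vectors.
#' @param m1,m2 masses.
#' @param normal contact normal (from particle 2 to particle 1; need not
#'   be unit length).
#' @param e restitution coefficient in (0, 1].
#' @return list with updated `v1`, `v2`.
#' @export
resolve_collision <- function(v1, v2, m1, m2, normal, e = 1) {
  n <- normal / sqrt(sum(normal^2))
  vn <- sum((v1 - v2) * n)
  if (vn >= 0) stop("pair is receding; no collision to resolve")
  mu <- m1 * m2 / (m1 + m2)
  J <- -mu * (1 + e) * vn
  list(v1 = v1 + J / m1 * n, v2 = v2 - J / m2 * n)
}

#' Andersen thermostat event on one particle
#'
#' Redraws the chosen particle's velocity from the Maxwell-Boltzmann
#' distribution at the given temperature (each component Gaussian with
#' variance `T / m_i`); every other particle is untouched.  Uses R's RNG
#' stream (seed with `set.seed()` for reproducibility).
#'
#' @param state a `sim_state`.
#' @param i particle index (1-based).
#' @param temperature reduced temperature, positive (0 allowed as the
#'   zero-variance limit).
#' @return the updated `sim_state`.
#' @export
thermostat_event <- function(state, i, temperature) {
  stopifnot(inherits(state, "sim_state"), temperature >= 0)
  s <- sqrt(temperature / state$masses[i])
  state$velocities[i, ] <- stats::rnorm(3, 0, s)
  state
}
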