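# Shared, lazily-built simulation fixtures (expensive; reused across test
# files within one test run).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

mono_species <- function() {
  to_reduced_units(crystallin_species()[1, , drop = FALSE], mole_fraction = 1)
}

# monodisperse fluid at phi = 0.4 (dense; first-shell structure tests)
fixture_mono_phi04 <- function() {
  fixture("mono_phi04", function() {
    cfg <- sim_config(2000, mono_species(), 0.4, seed = 101,
                      growth_rate = 5e-3)
    simulate_system(cfg, n_frames = 50, sample_interval = 0.5)
  })
}

# monodisperse fluid at phi = 0.3 (equation-of-state / PY regime)
fixture_mono_phi03 <- function() {
  fixture("mono_phi03", function() {
    cfg <- sim_config(2000, mono_species(), 0.3, seed = 103,
                      growth_rate = 5e-3)
    st <- init_state(cfg)
    st <- compress_to_phi(st, cfg)
    st <- resample_velocities(st, cfg)
    eq <- run_edmd(st, cfg, n_collisions = 100 * 2000, seed_offset = 20)
    # production with the thermostat off so the virial route sees a
    # strictly Newtonian trajectory
    pr <- run_edmd(eq$state, cfg, sample_interval = 0.5, max_samples = 40,
                   thermostat = FALSE, seed_offset = 30)
    list(traj = pr$traj, state = pr$state, elapsed = pr$elapsed,
         virial_sum = pr$virial_sum, n_collisions = pr$n_collisions)
  })
}

# small thermostatted run for temperature-control checks
fixture_thermo_run <- function() {
  fixture("thermo_run", function() {
    cfg <- sim_config(500, mono_species(), 0.3, seed = 107,
                      growth_rate = 5e-3)
    st <- init_state(cfg)
    st <- compress_to_phi(st, cfg)
    st <- resample_velocities(st, cfg)
    eq <- run_edmd(st, cfg, n_collisions = 100 * 500, seed_offset = 20)
    # wide frame spacing: kinetic-energy fluctuations decorrelate on the
    # thermostat timescale 1/nu = 10 tau
    run_edmd(eq$state, cfg, sample_interval = 2, max_samples = 100,
             seed_offset = 30)
  })
}

# Carnahan-Starling compressibility factor for the hard-sphere fluid
cs_compressibility <- function(phi) {
  (1 + phi + phi^2 - phi^3) / (1 - phi)^3
}

# Contact value of g(r) implied by Carnahan-Starling (the Verlet-Weis
# corrected Percus-Yevick contact value), via Z = 1 + 4 phi g(contact)
cs_contact_g <- function(phi) {
  (1 - phi / 2) / (1 - phi)^3
}

# kinetic temperature of one sampled frame
frame_temperature <- function(vel, masses) {
  sum(masses * rowSums(vel^2)) / (3 * length(masses))
}

# classic sums-of-squares one-way ANOVA (test oracle, independent of lm)
ss_anova <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  n <- length(values)
  grand <- mean(values)
  means <- tapply(values, g, mean)
  sizes <- tapply(values, g, length)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((values - means[g])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}
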