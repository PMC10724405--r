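test_that("pair collision prediction: analytic, receding, marching oracle", {
  # head-on unit spheres, gap 2, closing speed 2
  expect_equal(predict_pair_collision(c(0, 0, 0), c(1, 0, 0), 1,
                                      c(3, 0, 0), c(-1, 0, 0), 1), 1.0)
  # receding
  expect_true(is.na(predict_pair_collision(c(0, 0, 0), c(-1, 0, 0), 1,
                                           c(3, 0, 0), c(1, 0, 0), 1)))
  # offset pass: compare with brute-force time marching at step 1e-6
  r1 <- c(0, 0, 0); v1 <- c(1, 0, 0)
  r2 <- c(3, 0.5, 0); v2 <- c(-1, 0, 0)
  t_pred <- predict_pair_collision(r1, v1, 1, r2, v2, 1)
  tg <- seq(0, 3, by = 1e-6)
  dx <- (r2[1] - r1[1]) + (v2[1] - v1[1]) * tg
  dy <- r2[2] - r1[2]
  hit <- which(dx^2 + dy^2 <= 1)[1]
  expect_lt(abs(t_pred - tg[hit]), 1e-5)
  # overlapping input is a corrupted state
  expect_error(predict_pair_collision(c(0, 0, 0), c(0, 0, 0), 1,
                                      c(0.5, 0, 0), c(0, 0, 0), 1),
               "overlap")
})

test_that("collision resolution conserves momentum and energy", {
  # equal masses, elastic, head-on: velocities exchange
  r <- resolve_collision(c(1, 0, 0), c(-1, 0, 0), 1, 1, c(-1, 0, 0), e = 1)
  expect_equal(r$v1, c(-1, 0, 0))
  expect_equal(r$v2, c(1, 0, 0))
  # perfectly inelastic symmetric: both stop
  r0 <- resolve_collision(c(1, 0, 0), c(-1, 0, 0), 1, 1, c(-1, 0, 0), e = 0)
  expect_equal(r0$v1, c(0, 0, 0))
  expect_equal(r0$v2, c(0, 0, 0))
  # alpha-beta masses: closed-form two-body elastic solution
  m1 <- 1; m2 <- 0.26
  rr <- resolve_collision(c(1, 0, 0), c(0, 0, 0), m1, m2, c(-1, 0, 0), e = 1)
  v1_exp <- (m1 - m2) / (m1 + m2) * 1
  v2_exp <- 2 * m1 / (m1 + m2) * 1
  expect_equal(rr$v1[1], v1_exp, tolerance = 1e-12)
  expect_equal(rr$v2[1], v2_exp, tolerance = 1e-12)
  # momentum conserved for random oblique cases, energy for e = 1
  set.seed(5)
  for (k in 1:20) {
    v1 <- rnorm(3); v2 <- rnorm(3); m1 <- runif(1, 0.1, 2); m2 <- runif(1, 0.1, 2)
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    if (sum((v1 - v2) * n) >= 0) n <- -n
    e <- runif(1)
    out <- resolve_collision(v1, v2, m1, m2, n, e = e)
    expect_equal(m1 * out$v1 + m2 * out$v2, m1 * v1 + m2 * v2,
                 tolerance = 1e-12)
    # normal relative speed reversed and scaled by e
    expect_equal(sum((out$v1 - out$v2) * n), -e * sum((v1 - v2) * n),
                 tolerance = 1e-12)
  }
  expect_error(resolve_collision(c(-1, 0, 0), c(1, 0, 0), 1, 1,
                                 c(-1, 0, 0)), "receding")
})

test_that("thermostat event redraws one particle from Maxwell-Boltzmann", {
  cfg <- sim_config(20, mono_species(), 0.2, seed = 3)
  st <- init_state(cfg)
  pos_before <- st$positions
  set.seed(1)
  st0 <- thermostat_event(st, 5, 0)        # T -> 0 limit
  expect_equal(st0$velocities[5, ], c(0, 0, 0))
  expect_equal(st0$positions, pos_before)  # positions untouched
  other <- st$velocities[-5, ]
  expect_equal(st0$velocities[-5, ], other)
  # Monte-Carlo: component variance = T/m within 3 standard errors
  set.seed(2)
  draws <- replicate(6000, thermostat_event(st, 1, 1)$velocities[1, ])
  v <- as.numeric(draws)   # 18000 components
  se <- sqrt(2 / (length(v) - 1))
  expect_lt(abs(var(v) - 1), 3 * se)
  expect_lt(abs(mean(v)), 3 / sqrt(length(v)))
})

test_that("compression reaches the target phi without overlaps and
           preserves species diameter ratios", {
  cfg <- sim_config(500, mono_species(), 0.4, seed = 9, growth_rate = 5e-3)
  st <- init_state(cfg)
  expect_equal(state_phi(st), 0.2, tolerance = 1e-9)
  st2 <- compress_to_phi(st, cfg)
  expect_lt(abs(state_phi(st2) - 0.4), 1e-4)
  gap <- lenscrowd:::cpp_min_gap(st2$positions, st2$diameters, st2$box_edge)
  expect_gte(gap, -1e-9)
  # no-op when already at target
  st3 <- compress_to_phi(st2, cfg)
  expect_identical(st3$positions, st2$positions)

  # three-species mixture: uniform growth preserves diameter ratios
  cfg3 <- sim_config(400, lens_composition(), 0.3, seed = 10,
                     growth_rate = 5e-3)
  s3 <- compress_to_phi(init_state(cfg3), cfg3)
  d_by_sp <- tapply(s3$diameters, s3$species, function(x) x[1])
  expect_equal(as.numeric(d_by_sp / d_by_sp[[1]]),
               lens_composition()$reduced_diameter, tolerance = 1e-12)
  expect_gte(lenscrowd:::cpp_min_gap(s3$positions, s3$diameters,
                                     s3$box_edge), -1e-9)
})

test_that("cell-list engine reproduces the brute-force O(N^2) engine", {
  cfg <- sim_config(20, mono_species(), 0.25, seed = 31,
                    thermostat_rate = 0)
  st <- init_state(cfg)
  ref <- ref_run_edmd(st$positions, st$velocities, st$diameters,
                      st$masses, st$box_edge, 200)
  run <- run_edmd(st, cfg, n_collisions = 200, thermostat = FALSE,
                  record_events = TRUE)
  ev <- run$events
  expect_equal(nrow(ev), 200L)
  got <- data.frame(time = ev$time, i = pmin(ev$i, ev$j),
                    j = pmax(ev$i, ev$j))
  expect_equal(got$i, ref$events$i)
  expect_equal(got$j, ref$events$j)
  # deterministic chaos amplifies last-bit arithmetic differences between
  # the two implementations exponentially: event times agree to 1e-8 over
  # the leading window and stay close throughout the identical sequence
  expect_lt(max(abs(got$time[1:100] - ref$events$time[1:100])), 1e-8)
  expect_lt(max(abs(got$time - ref$events$time)), 1e-3)
})

test_that("zero-velocity state without thermostat produces no events", {
  cfg <- sim_config(50, mono_species(), 0.2, seed = 12, thermostat_rate = 0)
  st <- init_state(cfg)
  st$velocities[] <- 0
  run <- run_edmd(st, cfg, duration = 5, thermostat = FALSE,
                  record_events = TRUE)
  expect_equal(run$n_collisions, 0)
  expect_equal(run$state$positions, st$positions)
})

test_that("elastic un-thermostatted dynamics conserve momentum and energy", {
  cfg <- sim_config(300, mono_species(), 0.35, seed = 17,
                    growth_rate = 5e-3, thermostat_rate = 0)
  st <- compress_to_phi(init_state(cfg), cfg)
  inv0 <- state_invariants(st)
  run <- run_edmd(st, cfg, n_collisions = 2e4, thermostat = FALSE)
  inv1 <- state_invariants(run$state)
  expect_lt(abs(inv1$energy - inv0$energy) / inv0$energy, 1e-9)
  expect_lt(max(abs(inv1$momentum - inv0$momentum)), 1e-10)
  expect_equal(run$n_collisions, 2e4)
})

test_that("no overlaps at any sampled frame", {
  sim <- fixture_mono_phi04()
  for (fr in sim$traj$frames[seq(1, 50, by = 7)]) {
    gap <- lenscrowd:::cpp_min_gap(fr$positions, sim$state$diameters,
                                   sim$state$box_edge)
    expect_gte(gap, -1e-9)
  }
  mix <- fixture_thermo_run()
  for (fr in mix$traj$frames[seq(1, length(mix$traj$frames), by = 15)]) {
    gap <- lenscrowd:::cpp_min_gap(fr$positions, mix$state$diameters,
                                   mix$state$box_edge)
    expect_gte(gap, -1e-9)
  }
})

test_that("Andersen thermostat holds the kinetic temperature at T = 1", {
  run <- fixture_thermo_run()
  temps <- vapply(run$traj$frames, function(fr) {
    frame_temperature(fr$velocities, run$state$masses)
  }, numeric(1))
  expect_lt(abs(mean(temps) - 1), 0.02)
})

test_that("virial route matches Carnahan-Starling at phi = 0.30", {
  fx <- fixture_mono_phi03()
  n <- length(fx$state$masses)
  tkin <- kinetic_temperature(fx$state)
  z <- 1 + fx$virial_sum / (3 * n * tkin * fx$elapsed)
  expect_lt(abs(z - cs_compressibility(0.3)) / cs_compressibility(0.3), 0.03)
})
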