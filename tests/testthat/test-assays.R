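boltzmann <- function(x, a1, a2, x0, dx) a2 + (a1 - a2) / (1 + exp((x - x0) / dx))

test_that("fit_boltzmann recovers noiseless parameters exactly", {
  x <- 0:20
  y <- boltzmann(x, 0.2, 1.6, 6.9, 0.8)
  f <- fit_boltzmann(x, y)
  expect_true(f$converged)
  expect_equal(f$a1, 0.2, tolerance = 1e-6)
  expect_equal(f$a2, 1.6, tolerance = 1e-6)
  expect_equal(f$x0, 6.9, tolerance = 1e-6)
  expect_equal(f$dx, 0.8, tolerance = 1e-6)
  expect_equal(f$adj_r2, 1, tolerance = 1e-9)
  expect_true(f$plateau_reached)
  expect_equal(f$half_solubility, 6.9, tolerance = 1e-6)
})

test_that("fit_boltzmann is equivariant under OD scaling", {
  x <- 0:20
  set.seed(4)
  y <- boltzmann(x, 0.2, 1.6, 6.9, 0.8) + stats::rnorm(21, 0, 0.03)
  f1 <- fit_boltzmann(x, y)
  f3 <- fit_boltzmann(x, 3 * y)
  expect_equal(f3$a1, 3 * f1$a1, tolerance = 1e-5)
  expect_equal(f3$a2, 3 * f1$a2, tolerance = 1e-5)
  expect_equal(f3$x0, f1$x0, tolerance = 1e-5)
  expect_equal(f3$dx, f1$dx, tolerance = 1e-5)
})

test_that("fit_boltzmann midpoint recovery under noise", {
  x <- 0:20
  errs <- vapply(1:20, function(s) {
    y <- gen_turbidity(0.2, 1.6, 6.9, 0.8, x, noise_sd = 0.05, seed = s)$od
    fit_boltzmann(x, y)$x0 - 6.9
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.3)
})

test_that("plateau-reliability rule flags curves without a final plateau", {
  x <- 0:20
  # gamma-like: transition barely starting at the top of the PEG range
  y <- boltzmann(x, 0.05, 1.5, 19, 1.5)
  f <- fit_boltzmann(x, y)
  expect_false(f$plateau_reached)
  expect_true(is.na(f$half_solubility))
})

test_that("re-entrant declines are truncated before fitting", {
  d <- gen_turbidity(0.2, 1.6, 6.9, 0.8, seq(0, 20), noise_sd = 0,
                     reentrant_fraction = 0.286, seed = 1)
  f <- fit_boltzmann(d$peg_percent, d$od)
  expect_true(f$converged)
  expect_equal(f$x0, 6.9, tolerance = 0.05)
})

test_that("kinetics metrics: constant, plateau rise, logistic midpoint", {
  t <- seq(0, 30, by = 0.5)
  const <- kinetics_metrics(t, rep(0.5, length(t)))
  expect_equal(const$percent_increase, 0)
  expect_true(is.na(const$t_half))
  expect_false(const$crossed)

  # initial 0.62 rising to plateau 1.60: +158% (nearest integer)
  tr <- gen_kinetics(0.62, 1.60, 10, 1.2, duration = 30, dt = 0.5)
  m <- kinetics_metrics(tr$time, tr$od)
  expect_equal(round(m$percent_increase), 158)

  tr2 <- gen_kinetics(0.39, 0.99, 6.5, 1.5, duration = 30, dt = 0.5)
  m2 <- kinetics_metrics(tr2$time, tr2$od)
  expect_lt(abs(m2$t_half - 6.5), 0.5)  # within one sampling interval
  expect_equal(m2$od_half, (m2$initial_od + m2$plateau_od) / 2)
})

test_that("kinetics percent increase is invariant to time rescaling", {
  tr <- gen_kinetics(0.39, 0.99, 6.5, 1.5, duration = 30, dt = 0.5)
  m1 <- kinetics_metrics(tr$time, tr$od)
  m2 <- kinetics_metrics(tr$time * 60, tr$od)  # minutes -> seconds
  expect_equal(m2$percent_increase, m1$percent_increase)
  expect_equal(m2$t_half, m1$t_half * 60)
})

test_that("normalize_fluorescence maps min->0, max->1 and honors the
           control-MAX rule", {
  v <- c(3, 8, 5, 10, 4)
  nv <- normalize_fluorescence(v)
  expect_equal(min(nv), 0)
  expect_equal(max(nv), 1)
  ramp <- normalize_fluorescence(seq(0, 10, by = 0.5))
  expect_equal(ramp, seq(0, 1, length.out = 21))
  # flat control with external reference MAX: (5-5)/(15-5) = 0 everywhere
  ctrl <- rep(5, 10)
  expect_equal(normalize_fluorescence(ctrl, reference = c(2, 15, 7)),
               rep(0, 10))
  expect_error(normalize_fluorescence(rep(1, 5)), "dynamic range")
})

test_that("delay_report measures crossing-time shifts", {
  tr <- gen_kinetics(0.39, 0.99, 6.5, 1.5, duration = 30, dt = 0.5)
  ctrl <- kinetics_metrics(tr$time, tr$od)
  same <- delay_report(ctrl, tr$time, tr$od)
  expect_equal(same$delay, 0, tolerance = 1e-12)
  shifted <- delay_report(ctrl, tr$time + 2.5, tr$od)
  expect_equal(shifted$delay, 2.5, tolerance = 1e-9)
  # slower-rate treated trace vs dense-grid crossing oracle
  slow <- gen_kinetics(0.39, 0.99, 9.0, 2.5, duration = 30, dt = 0.5)
  rep_slow <- delay_report(ctrl, slow$time, slow$od)
  dense <- gen_kinetics(0.39, 0.99, 9.0, 2.5, duration = 30, dt = 1e-3)
  t_oracle <- dense$time[which(dense$od >= ctrl$od_half)[1]]
  expect_equal(rep_slow$t_cross, t_oracle, tolerance = 0.01)
})

test_that("published half-solubility ordering is preserved under noise", {
  pres <- synthetic_presets()$turbidity
  x <- seq(0, 20, by = 1)
  n_ok <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    x0_hat <- vapply(seq_len(nrow(pres)), function(i) {
      y <- gen_turbidity(pres$a1[i], pres$a2[i], pres$x0[i], pres$dx[i],
                         x, noise_sd = 0.05, seed = r * 100 + i)$od
      fit_boltzmann(x, y)$x0
    }, numeric(1))
    if (!anyNA(x0_hat) && !is.unsorted(x0_hat, strictly = TRUE)) {
      n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok / n_rep, 0.95)
})

test_that("fit_solubility_table fits per condition from long format", {
  pres <- synthetic_presets()$turbidity[1:3, ]
  long <- do.call(rbind, lapply(seq_len(nrow(pres)), function(i) {
    d <- gen_turbidity(pres$a1[i], pres$a2[i], pres$x0[i], pres$dx[i],
                       noise_sd = 0.02, n_replicates = 3, seed = i)
    d$condition <- pres$condition[i]
    d
  }))
  tab <- fit_solubility_table(long)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$x0, pres$x0, tolerance = 0.2)
})
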