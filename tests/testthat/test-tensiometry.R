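test_that("surface pressure is the drop from the initial tension", {
  p <- to_surface_pressure(0:2, c(72, 70, 69))
  expect_equal(p$pi, c(0, 2, 3))
  expect_equal(to_surface_pressure(0:9, rep(72, 10))$pi, rep(0, 10))
  # reconstruction identity Pi(t) + gamma(t) = gamma(t0)
  g <- 72 - cumsum(runif(20, 0, 0.5))
  p2 <- to_surface_pressure(seq_along(g), g)
  expect_equal(p2$pi + g, rep(g[1], 20))
  expect_error(to_surface_pressure(c(0, 0, 1), c(1, 2, 3)), "increasing")
})

test_that("initial rate: linear, flat, and quadratic against a dense grid", {
  t <- seq(0, 300, by = 1 / 0.11)
  lin <- data.frame(time_s = t, pi = 0.05 * t)
  ir <- initial_rate(lin)
  expect_equal(ir$rate, 3.0, tolerance = 1e-9)       # mN/m/min
  expect_equal(unname(ir$se), 0, tolerance = 1e-9)
  expect_equal(initial_rate(data.frame(time_s = t, pi = rep(0, length(t))))$rate, 0)

  # quadratic Pi = a t + b t^2: mean derivative over the sampled window
  a <- 0.03; b <- 2e-4
  quad <- data.frame(time_s = t, pi = a * t + b * t^2)
  irq <- initial_rate(quad)
  tin <- t[t <= 100]
  dense <- mean(a + 2 * b * tin)  # pointwise slopes at the sample times
  expect_equal(irq$rate, dense * 60, tolerance = 0.02 * dense * 60)
  expect_error(initial_rate(data.frame(time_s = c(0, 150), pi = c(0, 1))),
               "3 samples")
})

test_that("final pressure averages the trailing 240 s", {
  t <- seq(0, 2400, by = 1 / 0.11)
  plateau <- data.frame(time_s = t, pi = ifelse(t >= 2160, 12.5, 3))
  expect_equal(final_pressure(plateau)$final, 12.5)
  lin <- data.frame(time_s = t, pi = t / 60)
  expect_equal(final_pressure(lin)$final, 38.0, tolerance = 0.1)
  short <- data.frame(time_s = t[t <= 200], pi = t[t <= 200] / 60)
  expect_error(final_pressure(short), "shorter")
})

test_that("anova_posthoc matches the sums-of-squares oracle", {
  vals <- c(1, 2, 3, 2, 3, 4, 5, 6, 7)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- anova_posthoc(vals, grp)
  oracle <- ss_anova(vals, grp)
  expect_equal(res$f, oracle$f, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_equal(nrow(res$table), 3L)
  expect_true(all(res$table$p_adj >= res$table$p))

  # property: random small instances
  set.seed(99)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    sizes <- sample(2:8, k, replace = TRUE)
    v <- stats::rnorm(sum(sizes), mean = rep(stats::runif(k, 0, 3), sizes))
    g <- rep(letters[1:k], sizes)
    got <- anova_posthoc(v, g)
    want <- ss_anova(v, g)
    expect_equal(got$f, want$f, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
    expect_equal(got$n_comparisons, choose(k, 2))
  }
})

test_that("anova_posthoc edge cases: identical groups, two groups", {
  same <- anova_posthoc(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$f, 0)
  expect_true(all(same$table$p_adj == 1))
  # two groups: t^2 == F
  v <- c(1.2, 1.9, 2.8, 4.1, 5.0, 6.2)
  g <- rep(c("a", "b"), each = 3)
  res <- anova_posthoc(v, g)
  expect_equal(res$table$t[1]^2, res$f, tolerance = 1e-10)
})

test_that("interaction classification uses OR-repulsive / AND-attractive", {
  mk <- function(cond, rate, fin) list(condition = cond, initial_rate = rate,
                                       final_pressure = fin)
  ctrl <- mk("ctrl", 3, 12)
  # final higher significant, rate n.s. -> repulsive
  expect_equal(classify_interaction(mk("m", 3.1, 15), ctrl,
                                    rate_p = 0.4, final_p = 0.001)$label,
               "repulsive")
  # both significantly lower -> attractive
  expect_equal(classify_interaction(mk("m", 1.5, 9), ctrl,
                                    rate_p = 0.01, final_p = 0.001)$label,
               "attractive")
  # rate lower only -> none (attractive needs both)
  expect_equal(classify_interaction(mk("m", 1.5, 11.8), ctrl,
                                    rate_p = 0.01, final_p = 0.6)$label,
               "none")
  # nothing significant -> none
  expect_equal(classify_interaction(mk("m", 3.2, 12.4), ctrl,
                                    rate_p = 0.9, final_p = 0.7)$label,
               "none")
})

test_that("synthetic condition set reproduces the interaction network", {
  # engineered world: beta_H:gamma plateaus below the gamma control (and
  # below beta_H) with a slower rate; every other pairing plateaus above
  # its controls
  conds <- list(
    alpha          = list(pi = 12.0, rc = 200),
    beta_H         = list(pi = 10.0, rc = 450),
    beta_L         = list(pi = 11.0, rc = 180),
    gamma          = list(pi = 12.5, rc = 170),
    `alpha:gamma`  = list(pi = 15.0, rc = 170),
    `alpha:beta_L` = list(pi = 14.5, rc = 180),
    `beta_H:beta_L` = list(pi = 14.0, rc = 200),
    `beta_H:gamma` = list(pi = 8.8,  rc = 600),
    `beta_L:gamma` = list(pi = 15.5, rc = 170))
  df <- do.call(rbind, lapply(names(conds), function(cc) {
    gen_tension(gamma0 = 72, pi_final = conds[[cc]]$pi,
                rate_constant = conds[[cc]]$rc, noise_sd = 0.15,
                n_drops = 6, condition = cc,
                seed = 1000 + match(cc, names(conds)))
  }))
  net <- interaction_network(df, alpha = 0.05)
  edges <- net$edges
  lab <- setNames(edges$label, edges$mixture)
  expect_equal(unname(lab["beta_H:gamma"]), "attractive")
  expect_equal(unname(lab["alpha:gamma"]), "repulsive")
  expect_equal(unname(lab["alpha:beta_L"]), "repulsive")
  expect_equal(unname(lab["beta_H:beta_L"]), "repulsive")
  expect_equal(unname(lab["beta_L:gamma"]), "repulsive")
  expect_equal(sum(edges$label == "attractive"), 1L)
})

test_that("pressure_stats pools per-point slopes and plateau values", {
  df <- gen_tension(gamma0 = 72, pi_final = 12, rate_constant = 240,
                    noise_sd = 0.05, n_drops = 3, condition = "x", seed = 5)
  st <- pressure_stats(df)
  s <- st[["x"]]
  # 0.11 fps: 12 samples in the first 100 s, 27 in the last 240 s, per drop
  expect_equal(s$n_rate_points, 3 * 12)
  expect_equal(s$n_final_points, 3 * 27)
  expect_equal(s$final_pressure, 12, tolerance = 0.2)
  # analytic mean derivative of the exponential at the sampled times
  tin <- seq(0, 2400, by = 1 / 0.11)
  tin <- tin[tin <= 100]
  expect_equal(s$initial_rate, mean(12 / 240 * exp(-tin / 240)) * 60,
               tolerance = 0.1)
  expect_equal(nrow(s$per_drop), 3L)
})
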