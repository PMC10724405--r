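test_that("reduced units reproduce the published crystallin table", {
  set <- to_reduced_units(crystallin_species(),
                          mole_fraction = c(0.05, 0.20, 0.75))
  expect_equal(set$sigma_nm, 18.6)
  expect_equal(set$m_ref_g, 1.13e-18)
  # alpha is the reference: exactly 1 by construction
  expect_identical(set$reduced_diameter[1], 1)
  expect_identical(set$reduced_mass[1], 1)
  # beta and gamma at 2-decimal display precision
  expect_equal(round(set$reduced_diameter[2], 2), 0.63)
  expect_equal(round(set$reduced_mass[2], 2), 0.26)
  expect_equal(round(set$reduced_diameter[3], 2), 0.19)
  expect_equal(round(set$reduced_mass[3], 2), 0.03)
})

test_that("reduced units round-trip to physical units at machine precision", {
  specs <- crystallin_species()
  set <- to_reduced_units(specs, mole_fraction = c(0.05, 0.20, 0.75))
  expect_equal(set$reduced_diameter * set$sigma_nm, specs$diameter_nm,
               tolerance = 1e-15)
  expect_equal(set$reduced_mass * set$m_ref_g, specs$mass_g,
               tolerance = 1e-15)
})

test_that("to_reduced_units validates its input", {
  expect_error(species_spec("x", -1, 1e-19), "positive")
  expect_error(species_spec("x", 1, 0), "positive")
  expect_error(to_reduced_units(crystallin_species(),
                                mole_fraction = c(0.5, 0.5, 0.5)),
               "sum to 1")
  one <- to_reduced_units(crystallin_species()[1, , drop = FALSE],
                          mole_fraction = 1)
  expect_equal(one$reduced_diameter, 1)
  expect_equal(one$reduced_mass, 1)
})

test_that("mole fractions from mass ratios", {
  expect_equal(mole_fractions_from_mass(c(1, 1), c(10, 10)), c(0.5, 0.5))
  expect_equal(mole_fractions_from_mass(5, 123), 1)
  # native mass ratios with published MWs: close to, but not exactly,
  # the published 0.05:0.20:0.75 (frozen hand arithmetic)
  f <- mole_fractions_from_mass(c(35, 37, 21), c(680, 180, 21))
  expect_equal(f, c(0.0409461, 0.1635251, 0.7955288), tolerance = 1e-6)
  expect_equal(sum(f), 1)
  # scale invariance of mass ratios
  expect_equal(mole_fractions_from_mass(c(35, 37, 21) * 7.3,
                                        c(680, 180, 21)), f)
  expect_error(mole_fractions_from_mass(c(1, 2), c(1, 2, 3)), "length")
  expect_error(mole_fractions_from_mass(c(1, -2), c(1, 2)), "positive")
})

test_that("lens composition presets expose both mole-fraction routes", {
  lens <- lens_composition("lens")
  expect_equal(lens$mole_fraction, c(0.05, 0.20, 0.75))
  mr <- lens_composition("mass_ratio")
  expect_equal(mr$mole_fraction,
               mole_fractions_from_mass(c(35, 37, 21), c(680, 180, 21)))
})

test_that("packing fraction arithmetic", {
  expect_equal(packing_fraction(1, 1, 1), pi / 6)
  expect_equal(packing_fraction(0, 1, 5), 0)
  expect_equal(packing_fraction(c(100, 100), c(1, 0.5), 10),
               (100 * pi / 6 + 100 * pi / 6 * 0.125) / 1000)
  expect_error(packing_fraction(1, 1, 0), "positive")
  # box_edge_for_phi inverts it
  L <- box_edge_for_phi(c(100, 100), c(1, 0.5), 0.3)
  expect_equal(packing_fraction(c(100, 100), c(1, 0.5), L), 0.3)
})

test_that("realize_counts: exact products, largest remainder, conservation", {
  expect_equal(realize_counts(c(0.05, 0.20, 0.75), 1000),
               c(50L, 200L, 750L))
  c10 <- realize_counts(rep(1 / 3, 3), 10)
  expect_equal(sum(c10), 10L)
  expect_true(all(c10 %in% 3:4))
  # largest-remainder by hand: ideal (0.35, 1.4, 5.25) -> floors (0,1,5),
  # remainders (0.35, 0.4, 0.25): the extra particle goes to species 2
  expect_equal(realize_counts(c(0.05, 0.20, 0.75), 7), c(0L, 2L, 5L))
  expect_error(realize_counts(c(0.5, 0.5), 0), "at least 1")
  # property: exact conservation for random fraction vectors
  set.seed(42)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    f <- stats::runif(k)
    f <- f / sum(f)
    n <- sample(1:2000, 1)
    expect_identical(sum(realize_counts(f, n)), as.integer(n))
  }
})

test_that("mass-preserving exclusion renormalizes and reports the mass
           scale factor", {
  full <- lens_composition()
  # hand arithmetic for x = (0.05, 0.20, 0.75), m = (1, 0.26, 0.03):
  # mass per particle slot of the full mixture = 0.1245
  # drop beta : x -> (0.0625, 0.9375), kept mass/slot 0.090625
  # drop gamma: x -> (0.20, 0.80),     kept mass/slot 0.408
  m_b <- 2.99e-19 / 1.13e-18          # exact reduced masses
  m_g <- 3.49e-20 / 1.13e-18
  mass_full <- 0.05 + 0.20 * m_b + 0.75 * m_g
  nb <- exclude_species(full, "beta")
  expect_equal(nb$species$name, c("alpha", "gamma"))
  expect_equal(nb$mole_fraction, c(0.0625, 0.9375))
  expect_equal(attr(nb, "n_scale"),
               mass_full / (0.0625 + 0.9375 * m_g), tolerance = 1e-12)
  ng <- exclude_species(full, "gamma")
  expect_equal(ng$species$name, c("alpha", "beta"))
  expect_equal(ng$mole_fraction, c(0.2, 0.8))
  expect_equal(attr(ng, "n_scale"),
               mass_full / (0.2 + 0.8 * m_b), tolerance = 1e-12)
  expect_error(exclude_species(full, "delta"), "unknown")
})
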