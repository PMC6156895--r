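test_that("the simulator is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_families = 30, n_regions = 3, seed = 123)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$meth, b$meth)
  expect_identical(a$samples, b$samples)
  expect_identical(a$kinship, b$kinship)
  c <- simulate_study(simulation_config(n_families = 30, n_regions = 3, seed = 124))
  expect_false(identical(a$meth, c$meth))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(probes_per_region = 0, seed = 1))
  expect_error(simulation_config(rho = 1, seed = 1))
  expect_error(simulation_config(h2 = 1, seed = 1))
  expect_error(simulation_config(seed = 1,
    causal_regions = list(list(region = 99, effect = 1))), "out of range")
  expect_error(simulation_config(n_families = 10), "seed")
})

test_that("null phenotype is independent of methylation by construction", {
  st <- simulate_study(simulation_config(n_families = 2000, n_regions = 4,
                                         probes_per_region = 3,
                                         n_null_singletons = 5, h2 = 0,
                                         seed = 7))
  M <- beta_to_m(st$meth)
  cors <- abs(cor(t(M), st$samples$phenotype))
  expect_lt(max(cors), 5.5 / sqrt(2000))   # ~5.5 sd bound over 17 probes
})

test_that("empirical probe correlation matches the generating model", {
  st <- simulate_study(simulation_config(n_families = 2000,
                                         n_regions = 2, probes_per_region = 5,
                                         rho = 0.6, seed = 11))
  M <- beta_to_m(st$meth)
  emp <- cor(t(M[1:5, ]))
  off <- emp[upper.tri(emp)]
  expect_true(all(abs(off - 0.6) < 0.05))
  # and the estimated Sigma converges to it too
  pc <- partial_correlation(M[1:5, ], st$samples)
  expect_lt(max(abs(pc$sigma[upper.tri(pc$sigma)] - 0.6)), 0.05)
})

test_that("family structures get the intended kinship blocks", {
  trio <- simulate_study(simulation_config(n_families = 2,
                                           family_structure = "trio",
                                           n_regions = 1, seed = 3))
  expect_equal(unname(trio$kinship[1:3, 1:3]),
               matrix(c(0.5, 0, 0.25, 0, 0.5, 0.25, 0.25, 0.25, 0.5), 3))
  expect_equal(unname(trio$kinship[1, 4]), 0)
  sibs <- simulate_study(simulation_config(n_families = 2,
                                           family_structure = "sibs",
                                           family_size = 3,
                                           n_regions = 1, seed = 3))
  expect_equal(unname(sibs$kinship[1:3, 1:3]),
               matrix(c(0.5, 0.25, 0.25, 0.25, 0.5, 0.25, 0.25, 0.25, 0.5), 3))
})

test_that("heritable phenotypes correlate within families", {
  st <- simulate_study(simulation_config(n_families = 600,
                                         family_structure = "sibs",
                                         h2 = 0.8, n_regions = 1,
                                         probes_per_region = 2, seed = 17))
  y <- matrix(st$samples$phenotype, nrow = 3)
  sib_cor <- cor(y[1, ], y[2, ])
  # expected sib correlation ~ h2/2 * (phenotypic var share); crude band
  expect_gt(sib_cor, 0.2)
  st0 <- simulate_study(simulation_config(n_families = 600,
                                          family_structure = "sibs",
                                          h2 = 0, n_regions = 1,
                                          probes_per_region = 2, seed = 17))
  y0 <- matrix(st0$samples$phenotype, nrow = 3)
  expect_lt(abs(cor(y0[1, ], y0[2, ])), 0.12)
})

test_that("degenerate alpha values bound the rejection rate", {
  cfg <- simulation_config(n_families = 40, n_regions = 3,
                           probes_per_region = 3, n_null_singletons = 0,
                           seed = 5)
  hi <- type_one_error_experiment(cfg, n_reps = 2, alpha = 1, seed = 2)
  expect_equal(hi$region_rate, 1)
  lo <- type_one_error_experiment(cfg, n_reps = 2, alpha = 0, seed = 2)
  expect_equal(lo$region_rate, 0)
  expect_error(type_one_error_experiment(cfg, n_reps = 1, alpha = 0.05, seed = 2),
               "n_reps")
  bad <- simulation_config(n_families = 40, seed = 1,
                           causal_regions = list(list(region = 1, effect = 1)))
  expect_error(type_one_error_experiment(bad, n_reps = 2, alpha = 0.05, seed = 2),
               "null")
})

test_that("calibration experiments are reproducible from the master seed", {
  cfg <- simulation_config(n_families = 60, n_regions = 4,
                           probes_per_region = 3, n_null_singletons = 0,
                           seed = 5)
  a <- type_one_error_experiment(cfg, n_reps = 5, alpha = 0.05, seed = 42)
  b <- type_one_error_experiment(cfg, n_reps = 5, alpha = 0.05, seed = 42)
  expect_identical(a$region_rate, b$region_rate)
  expect_identical(a$probe_rate, b$probe_rate)
})

test_that("heritable-phenotype covariance is h2 * 2phi at the family block", {
  # direct check of the generative covariance for sib triples
  cfg <- simulation_config(n_families = 3000, family_structure = "sibs",
                           h2 = 0.4, n_regions = 1, probes_per_region = 1,
                           covariate_effects = c(age = 0, sexM = 0,
                                                 centerC2 = 0,
                                                 smoking_former = 0,
                                                 smoking_current = 0),
                           seed = 29)
  st <- simulate_study(cfg)
  y <- matrix(st$samples$phenotype, nrow = 3)
  expect_equal(var(st$samples$phenotype), 1, tolerance = 0.08)
  expect_lt(abs(cor(y[1, ], y[3, ]) - 0.4 * 0.5), 0.05)
})
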