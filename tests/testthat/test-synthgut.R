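test_that("simulation is deterministic and degenerate configs work", {
  cfg <- simulation_config(seed = 5, n_taxa = 50,
                           group_sizes = c(CD_F = 4, HC_F = 4),
                           planted_discriminative = NULL,
                           planted_modules = list(),
                           trait_coupling = list())
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a, b)

  empty <- simulate_dataset(
    simulation_config(seed = 1, n_taxa = 0,
                      group_sizes = c(CD_F = 2, HC_F = 2),
                      planted_discriminative = NULL,
                      planted_modules = list(), trait_coupling = list()))
  expect_equal(nrow(empty$table), 0)
  expect_equal(nrow(empty$truth), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(
    simulation_config(group_sizes = c(CD_F = 1, HC_F = 5)),
    class = "keytaxa_config_error")
  expect_error(
    simulation_config(n_taxa = 50,
                      planted_modules = list(list(members = 45:60,
                                                  factor_sd = 1,
                                                  loading = 1)),
                      planted_discriminative = NULL,
                      trait_coupling = list()),
    class = "keytaxa_config_error")
  expect_error(
    simulation_config(n_taxa = 50, planted_modules = list(),
                      planted_discriminative = NULL,
                      trait_coupling = default_trait_coupling()),
    class = "keytaxa_config_error")
})

test_that("count columns sum exactly to the drawn depths", {
  sim <- simulate_dataset(simulation_config(seed = 2, n_taxa = 120,
                                            group_sizes = c(CD_F = 6,
                                                            HC_F = 6)))
  m <- abundance_matrix(sim$table)
  expect_true(all(m == floor(m)))
  expect_true(all(m >= 0))
  # depths are whatever was drawn; the invariant is exact integer totals
  expect_true(all(colSums(m) >= 100))
})

test_that("abundance-occupancy link induces a strong rank correlation", {
  rhos <- vapply(1:5, function(s) {
    sim <- simulate_dataset(
      simulation_config(seed = s, n_taxa = 300,
                        planted_discriminative = NULL))
    prof <- occurrence_frequency(sim$table, community = "all")
    cor(sim$truth$true_mean_abundance, prof$frequency,
        method = "spearman")
  }, numeric(1))
  expect_true(all(rhos > 0.7))
})

test_that("realized occurrence converges to the configured occupancy", {
  # a small panel sequenced deep, so detection is certain for the kept taxa
  # and the only error term is binomial sampling of presence
  devs <- vapply(1:5, function(s) {
    cfg <- simulation_config(seed = s, n_taxa = 30,
                             group_sizes = c(G1 = 100, G2 = 100),
                             depth = c(mean = 1e5, dispersion = 10),
                             planted_discriminative = NULL,
                             planted_modules = list(),
                             trait_coupling = list())
    sim <- simulate_dataset(cfg)
    prof <- occurrence_frequency(sim$table, community = "all")
    keep <- sim$truth$true_mean_abundance * 1e5 >= 10
    max(abs(prof$frequency[keep] - sim$truth$true_occupancy[keep]))
  }, numeric(1))
  expect_lt(mean(devs), 0.08)
})

test_that("planted discriminative taxa realize the configured occurrence gap", {
  gaps <- vapply(1:10, function(s) {
    sim <- simulate_dataset(simulation_config(seed = s))
    meta <- sim$metadata
    hc <- occurrence_frequency(sim$table,
                               meta$sample_id[meta$group == "HC_F"], "HC_F")
    cd <- occurrence_frequency(sim$table,
                               meta$sample_id[meta$group == "CD_F"], "CD_F")
    mean(hc$frequency[1:10] - cd$frequency[1:10])
  }, numeric(1))
  expect_lt(abs(mean(gaps) - (0.9 - 0.05)), 0.1)
})

test_that("ao point sets follow the curve and honour noise settings", {
  pts <- simulate_ao_points(0.05, 40, 50, noise_sd = 0, seed = 3)
  expect_equal(pts$frequency,
               pmin(0.05 * exp(40 * pts$mean_abundance), 1),
               tolerance = 1e-12)
  flat <- simulate_ao_points(0.3, 0, 20, noise_sd = 0, seed = 4)
  expect_equal(flat$frequency, rep(0.3, 20))
  expect_error(simulate_ao_points(0.05, 40, 10, noise_sd = -1),
               class = "keytaxa_config_error")
  expect_error(simulate_ao_points(0.05, 40, 2),
               class = "keytaxa_config_error")
})

test_that("module network blocks have the requested correlation structure", {
  net <- simulate_module_network(c(40, 40, 40), 0.8, 0, 60, seed = 3)
  expect_equal(dim(net$profiles), c(120, 60))
  cc <- cor(t(net$profiles))
  within <- c()
  between <- c()
  for (i in 1:119) for (j in (i + 1):120) {
    if (net$labels[i] == net$labels[j]) within <- c(within, cc[i, j])
    else between <- c(between, cc[i, j])
  }
  expect_gt(mean(within), 0.7)
  expect_lt(mean(within), 0.9)
  expect_lt(abs(mean(between)), 0.15)

  one <- simulate_module_network(5, 0.6, 0.2, 2000, seed = 1)
  cc1 <- cor(t(one$profiles))
  expect_lt(max(abs(cc1[upper.tri(cc1)] - 0.6)), 0.1)

  expect_error(simulate_module_network(integer(0), 0.8, 0, 10),
               class = "keytaxa_config_error")
  expect_error(simulate_module_network(c(10, 10), 0.5, 0.7, 10),
               class = "keytaxa_config_error")
})
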