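test_that("adjacency is the soft-powered absolute correlation", {
  cc <- matrix(c(1, 0.5, -0.3, 0.5, 1, 0, -0.3, 0, 1), 3, 3)
  a1 <- adjacency_matrix(cc, 1)
  expect_equal(a1[1, 2], 0.5)
  expect_equal(a1[1, 3], 0.3)
  expect_equal(diag(a1), rep(0, 3))
  a10 <- adjacency_matrix(cc, 10)
  expect_equal(a10[1, 2], 0.5^10, tolerance = 1e-12)
  expect_equal(round(a10[1, 2], 6), 0.000977)
  z <- diag(3)
  expect_equal(adjacency_matrix(z, 5), matrix(0, 3, 3))
  bad <- cc; bad[1, 2] <- 0.9
  expect_error(adjacency_matrix(bad, 2), class = "keytaxa_validation_error")
})

test_that("topological overlap matches hand values and the triple-loop oracle", {
  # zero adjacency -> identity
  z <- matrix(0, 4, 4)
  expect_equal(tom_similarity(z), diag(4))
  # equilateral triangle at 0.5: TOM_12 = (0.25 + 0.5)/(1 + 1 - 0.5)
  tri <- matrix(0.5, 3, 3); diag(tri) <- 0
  tt <- tom_similarity(tri)
  expect_equal(tt[1, 2], 0.5, tolerance = 1e-12)
  for (s in 1:3) {
    a <- random_adjacency(12, seed = s)
    expect_lt(max(abs(tom_similarity(a) - tom_oracle(a))), 1e-12)
  }
  expect_error(tom_similarity(matrix(2, 2, 2)),
               class = "keytaxa_validation_error")
})

test_that("tom output is symmetric with entries in [0, 1]", {
  a <- random_adjacency(15, seed = 9)
  tt <- tom_similarity(a)
  expect_equal(tt, t(tt), tolerance = 1e-12)
  expect_true(all(tt >= 0 & tt <= 1 + 1e-12))
})

test_that("planted blocks are recovered as modules with correct colors", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:5, function(s) {
    net <- simulate_module_network(c(40, 40, 40), 0.8, 0, 60, seed = s)
    ms <- (net$profiles - rowMeans(net$profiles)) /
      apply(net$profiles, 1, sd)
    tom <- tom_similarity(adjacency_matrix(cor(t(ms)), 6))
    lab <- detect_modules(1 - tom, min_module_size = 10)
    expect_equal(length(unique(lab$module[lab$module > 0])), 3)
    expect_true(all(table(lab$module[lab$module > 0]) >= 10))
    mclust::adjustedRandIndex(lab$module, net$labels)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("module colors follow the size-ordered canonical palette", {
  net <- simulate_module_network(c(50, 30, 15), 0.9, 0, 80, seed = 2)
  ms <- (net$profiles - rowMeans(net$profiles)) /
    apply(net$profiles, 1, sd)
  tom <- tom_similarity(adjacency_matrix(cor(t(ms)), 6))
  lab <- detect_modules(1 - tom, min_module_size = 10)
  sizes <- table(lab$color)
  expect_true(all(c("turquoise", "blue", "brown") %in% names(sizes)))
  expect_gte(sizes[["turquoise"]], sizes[["blue"]])
  expect_gte(sizes[["blue"]], sizes[["brown"]])
})

test_that("degenerate module inputs collapse as specified", {
  # near-identical profiles form a single module
  set.seed(3)
  base <- rnorm(30)
  prof <- matrix(rep(base, each = 20), nrow = 20) +
    matrix(rnorm(20 * 30, 0, 1e-6), nrow = 20)
  rownames(prof) <- sprintf("T%02d", 1:20)
  ms <- (prof - rowMeans(prof)) / apply(prof, 1, sd)
  tom <- tom_similarity(adjacency_matrix(cor(t(ms)), 6))
  lab <- detect_modules(1 - tom, min_module_size = 5)
  expect_equal(length(unique(lab$module)), 1)
  expect_true(all(lab$module == 1))

  expect_warning(out <- detect_modules(1 - tom, min_module_size = 50),
                 "unassigned")
  expect_true(all(out$module == 0))
  expect_true(all(out$color == "grey"))
})

test_that("eigengenes summarize modules and respect the orientation rule", {
  net <- simulate_module_network(c(10, 10), 0.9, 0, 40, seed = 4)
  ms <- (net$profiles - rowMeans(net$profiles)) /
    apply(net$profiles, 1, sd)
  labels <- tibble::tibble(taxon_id = rownames(ms),
                           module = net$labels,
                           color = c("turquoise", "blue")[net$labels])
  eg <- module_eigengene(ms, labels)
  expect_equal(dim(eg$eigengenes), c(2, 40))
  expect_true(all(eg$variance_explained > 0 & eg$variance_explained <= 1))

  # single-taxon module: eigengene is that profile up to scale (r = 1)
  one <- labels; one$module[1] <- 3L; one$color[1] <- "brown"
  eg1 <- module_eigengene(ms, one)
  expect_equal(abs(cor(eg1$eigengenes["brown", ], ms[1, ])), 1,
               tolerance = 1e-12)

  # duplicated profiles: 100% variance explained
  dup <- ms[c(1, 1), ]; rownames(dup) <- c("d1", "d2")
  egd <- module_eigengene(dup, tibble::tibble(taxon_id = c("d1", "d2"),
                                              module = 1L, color = "red"))
  expect_equal(unname(egd$variance_explained["red"]), 1, tolerance = 1e-12)

  # global sign flip leaves oriented eigengenes' relation to data unchanged
  egf <- module_eigengene(-ms, labels)
  m1 <- labels$taxon_id[labels$module == 1]
  expect_gte(mean(cor(eg$eigengenes["turquoise", ], t(ms[m1, ]))), 0)
  expect_gte(mean(cor(egf$eigengenes["turquoise", ], t(-ms[m1, ]))), 0)
})

test_that("module-trait correlation recovers planted couplings", {
  rs <- purrr::map_dfr(1:5, function(s) {
    sim <- simulate_dataset(simulation_config(seed = s))
    meta <- sim$metadata
    dec <- suppressWarnings(
      cooccurrence_network(sim$table, meta, beta = 6,
                           min_module_size = 10))
    mt <- dec$module_trait
    # module containing the planted taxa coupled to monocytes
    mono_members <- sim$truth$taxon_id[sim$truth$true_module == 1]
    hit <- dec$labels[dec$labels$taxon_id %in% mono_members &
                        dec$labels$module > 0, ]
    mcol <- names(sort(table(hit$color), decreasing = TRUE))[1]
    # "elsewhere" = modules with no planted member of the coupled block
    clean <- setdiff(unique(dec$labels$color[dec$labels$module > 0]),
                     unique(dec$labels$color[
                       dec$labels$taxon_id %in% mono_members]))
    tibble::tibble(
      planted_r = mt$r[mt$module == mcol & mt$trait == "monocytes"],
      other_r = {
        o <- mt$r[mt$module %in% clean & mt$trait == "monocytes" &
                    mt$testable]
        if (length(o)) max(abs(o)) else 0
      })
  })
  expect_gte(mean(rs$planted_r), 0.6)
  expect_lte(mean(rs$other_r), 0.3)
})

test_that("constant traits are untestable and self-traits correlate perfectly", {
  eg <- matrix(rnorm(2 * 20), 2, dimnames = list(c("blue", "brown"),
                                                 paste0("s", 1:20)))
  traits <- data.frame(flat = rep(5, 20), self = eg["blue", ],
                       row.names = paste0("s", 1:20))
  mt <- module_trait_correlation(eg, traits)
  flat <- mt[mt$trait == "flat", ]
  expect_true(all(!flat$testable))
  self <- mt[mt$module == "blue" & mt$trait == "self", ]
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_lt(self$p_value, 1e-12)
})

test_that("connectivity identifies hubs with lexicographic tie-break", {
  # star: center connected to 10 leaves at 0.9
  n <- 11
  a <- matrix(0, n, n)
  a[1, 2:n] <- 0.9; a[2:n, 1] <- 0.9
  ids <- c("center", sprintf("leaf%02d", 1:10))
  dimnames(a) <- list(ids, ids)
  labels <- tibble::tibble(taxon_id = ids, module = 1L, color = "turquoise")
  ch <- connectivity_and_hubs(a, labels)
  expect_equal(ch$hubs$hub_taxon, "center")
  expect_equal(ch$connectivity$k_total[1], 9)

  # clique: equal kWithin, smallest id wins
  cl <- matrix(0.5, 4, 4); diag(cl) <- 0
  ids2 <- c("bTax", "aTax", "dTax", "cTax")
  dimnames(cl) <- list(ids2, ids2)
  lab2 <- tibble::tibble(taxon_id = ids2, module = 1L, color = "blue")
  expect_equal(connectivity_and_hubs(cl, lab2)$hubs$hub_taxon, "aTax")

  # grey taxa get connectivity but no hub
  lab3 <- lab2; lab3$module <- 0L; lab3$color <- "grey"
  ch3 <- connectivity_and_hubs(cl, lab3)
  expect_equal(nrow(ch3$hubs), 0)
  expect_false(any(ch3$connectivity$is_hub))
})

test_that("edge export filters the upper triangle at the threshold", {
  a <- random_adjacency(4, seed = 6)
  all_edges <- export_edgelist(a, 0)
  expect_equal(nrow(all_edges), 6)
  none <- export_edgelist(a, 1)
  expect_equal(nrow(none), 0)
  thr <- export_edgelist(a, 0.2)
  brute <- sum(a[upper.tri(a)] >= 0.2)
  expect_equal(nrow(thr), brute)
  expect_error(export_edgelist(a, 1.5), class = "keytaxa_config_error")
})

test_that("outlier samples split off and removal is bounded", {
  set.seed(10)
  m <- matrix(rnorm(30 * 12, 10, 1), nrow = 30,
              dimnames = list(sprintf("t%02d", 1:30), sprintf("s%02d", 1:12)))
  tbl <- tibble::as_tibble(m, rownames = "taxon_id")
  res <- remove_outlier_samples(tbl)
  expect_equal(res$removed, character(0))

  m2 <- m; m2[, 1] <- m2[, 1] * 100
  tbl2 <- tibble::as_tibble(m2, rownames = "taxon_id")
  res2 <- suppressMessages(remove_outlier_samples(tbl2))
  expect_equal(res2$removed, "s01")

  expect_error(remove_outlier_samples(tbl[, 1:4]),
               class = "keytaxa_validation_error")
})

test_that("soft power scan reports fit quality and a recommendation", {
  net <- simulate_module_network(c(40, 40, 40), 0.8, 0, 60, seed = 1)
  prof <- abs(net$profiles) + 0.1  # make it abundance-like (positive)
  tbl <- tibble::as_tibble(prof, rownames = "taxon_id")
  scan <- suppressWarnings(soft_power_scan(tbl, powers = c(2, 4, 6)))
  expect_equal(nrow(scan), 3)
  expect_true(all(c("power", "r_squared", "slope",
                    "mean_connectivity") %in% names(scan)))
  expect_true(attr(scan, "recommended") %in% c(2, 4, 6))

  one <- suppressWarnings(soft_power_scan(tbl, powers = 6))
  expect_equal(attr(one, "recommended"), 6)
})

test_that("full decomposition object summarises and tidies", {
  sim <- simulate_dataset(simulation_config(seed = 6))
  dec <- suppressWarnings(
    cooccurrence_network(sim$table, sim$metadata, beta = 6,
                         min_module_size = 10))
  g <- glance(dec)
  expect_gte(g$n_modules, 3)
  td <- tidy(dec)
  expect_equal(nrow(td), g$n_taxa)
  expect_s3_class(autoplot(dec), "ggplot")
})
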