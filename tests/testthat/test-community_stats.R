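test_that("shannon diversity matches closed forms", {
  expect_equal(shannon(c(5, 0, 0)), 0)
  expect_equal(shannon(rep(3, 4)), log(4), tolerance = 1e-12)
  # H(2,1,1) = -(1/2 ln 1/2 + 2 * 1/4 ln 1/4)
  expect_equal(shannon(c(2, 1, 1)),
               -(0.5 * log(0.5) + 0.5 * log(0.25)), tolerance = 1e-12)
  expect_equal(round(shannon(c(2, 1, 1)), 4), 1.0397)
  expect_equal(shannon(c(1, 1, 1, 1), base = 2), 2)
  expect_error(shannon(c(0, 0)), class = "keytaxa_validation_error")
})

test_that("bray-curtis matches hand values and a brute-force oracle", {
  tbl <- tibble::tibble(taxon_id = c("a", "b"),
                        s1 = c(1, 1), s2 = c(1, 0), s3 = c(1, 1),
                        s4 = c(0, 2))
  d <- bray_curtis(tbl)
  expect_equal(d["s1", "s2"], 1 / 3, tolerance = 1e-12)
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s2", "s4"], 1)  # disjoint supports
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_true(all(d >= 0 & d <= 1))

  set.seed(21)
  for (rep in 1:3) {
    m <- matrix(rpois(6 * 4, 3) + 0.5, nrow = 6,
                dimnames = list(paste0("t", 1:6), paste0("s", 1:4)))
    tb <- tibble::as_tibble(m, rownames = "taxon_id")
    expect_equal(unname(bray_curtis(tb)), bray_oracle(m),
                 tolerance = 1e-12)
  }

  zz <- tibble::tibble(taxon_id = "a", s1 = 0, s2 = 1)
  expect_error(bray_curtis(zz), "s1", class = "keytaxa_validation_error")
})

test_that("permanova separates distinct clouds and rejects bad groupings", {
  set.seed(3)
  m <- cbind(matrix(rpois(20 * 10, 5), 20),
             matrix(rpois(20 * 10, 5) + 60, 20))
  colnames(m) <- paste0("s", 1:20); rownames(m) <- paste0("t", 1:20)
  tbl <- tibble::as_tibble(m, rownames = "taxon_id")
  d <- bray_curtis(tbl)
  labels <- rep(c("A", "B"), each = 10)
  res <- permanova(d, labels, B = 999, seed = 1)
  expect_equal(res$p_value, 0.001)  # minimum attainable at B = 999
  expect_gt(res$statistic, 1)

  expect_error(permanova(d, rep("A", 20), B = 99),
               class = "keytaxa_validation_error")
  expect_error(permanova(d, c("A", rep("B", 19)), B = 99),
               class = "keytaxa_validation_error")
})

test_that("permanova F is invariant under group-preserving relabeling", {
  set.seed(8)
  m <- matrix(rpois(15 * 10, 4) + 1, nrow = 15,
              dimnames = list(paste0("t", 1:15), paste0("s", 1:10)))
  tbl <- tibble::as_tibble(m, rownames = "taxon_id")
  d <- bray_curtis(tbl)
  labels <- rep(c("A", "B"), each = 5)
  f1 <- permanova(d, labels, B = 49, seed = 2)$statistic
  perm <- c(sample(1:5), sample(6:10))  # shuffle within groups
  f2 <- permanova(d[perm, perm], labels[perm], B = 49, seed = 2)$statistic
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("pairwise permanova enumerates pairs and BH never shrinks p", {
  set.seed(5)
  m <- matrix(rpois(12 * 16, 4) + 1, nrow = 12,
              dimnames = list(paste0("t", 1:12), paste0("s", 1:16)))
  tbl <- tibble::as_tibble(m, rownames = "taxon_id")
  d <- bray_curtis(tbl)
  labels <- rep(c("A", "B", "C", "D"), each = 4)
  res <- pairwise_permanova(d, labels, B = 99, seed = 1)
  expect_equal(nrow(res), 6)
  expect_true(all(res$adjusted_p >= res$p_value - 1e-12))
  expect_true(all(res$p_value >= 1 / 100))

  two <- pairwise_permanova(d[1:8, 1:8], labels[1:8], B = 99, seed = 1)
  expect_equal(nrow(two), 1)
})

test_that("welch tests match the textbook formula and apply the 0.1% filter", {
  x <- c(0.30, 0.32, 0.31, 0.29, 0.33, 0.31)
  y <- c(0.20, 0.22, 0.21, 0.19, 0.23, 0.21)
  n <- 6
  tbl <- tibble::tibble(taxon_id = c("big", "rest"))
  for (i in 1:12) {
    v <- if (i <= 6) c(x[i], 1 - x[i]) else c(y[i - 6], 1 - y[i - 6])
    tbl[[paste0("s", i)]] <- v
  }
  meta <- tibble::tibble(sample_id = paste0("s", 1:12),
                         group = rep(c("G1", "G2"), each = 6))
  res <- welch_diff(tbl, meta, c("G1", "G2"))
  row <- res[res$taxon_id == "big", ]
  # hand-evaluated Welch statistic and Satterthwaite df
  se <- sqrt(var(x) / n + var(y) / n)
  t_oracle <- (mean(x) - mean(y)) / se
  df_oracle <- (var(x) / n + var(y) / n)^2 /
    ((var(x) / n)^2 / (n - 1) + (var(y) / n)^2 / (n - 1))
  expect_equal(row$statistic, t_oracle, tolerance = 1e-9)
  expect_equal(row$df, df_oracle, tolerance = 1e-9)
  expect_equal(row$p_value, 2 * pt(-abs(t_oracle), df_oracle),
               tolerance = 1e-9)
  expect_true(row$reportable)
})

test_that("significant-but-tiny differences are excluded by min_abs_diff", {
  set.seed(13)
  tbl <- tibble::tibble(taxon_id = c("tiny", "rest"))
  for (i in 1:20) {
    # within-group scatter far below the 0.0005 shift: p tiny, diff < 0.1%
    p <- (if (i <= 10) 0.5 else 0.5005) + rnorm(1, 0, 1e-4)
    tbl[[paste0("s", i)]] <- c(p, 1 - p)
  }
  meta <- tibble::tibble(sample_id = paste0("s", 1:20),
                         group = rep(c("G1", "G2"), each = 10))
  res <- welch_diff(tbl, meta, c("G1", "G2"))
  row <- res[res$taxon_id == "tiny", ]
  expect_lt(row$p_value, 0.05)          # paired construction: strong signal
  expect_lt(abs(row$mean_diff), 0.001)  # but below the reporting threshold
  expect_false(row$reportable)
})

test_that("zero-variance taxa are flagged not testable", {
  # "const" keeps relative abundance 0.5 in every sample; the other two
  # taxa split the remaining half variably
  tbl <- tibble::tibble(taxon_id = c("const", "v1", "v2"),
                        s1 = c(2, 1, 1), s2 = c(4, 3, 1), s3 = c(6, 1, 5),
                        s4 = c(8, 2, 6))
  meta <- tibble::tibble(sample_id = paste0("s", 1:4),
                         group = rep(c("A", "B"), each = 2))
  res <- welch_diff(tbl, meta, c("A", "B"))
  expect_false(res$testable[res$taxon_id == "const"])
  expect_true(is.na(res$p_value[res$taxon_id == "const"]))
})

test_that("kruskal-wallis matches the tie-corrected rank formula", {
  vals <- c(2.1, 2.5, 2.3, 3.0, 3.2, 3.1, 2.1, 4.0, 4.1)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- kruskal_wallis(vals, grp)
  # rank-formula oracle with tie correction
  r <- rank(vals)
  n <- length(vals)
  rs <- tapply(r, grp, sum)
  ns <- tapply(r, grp, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(vals)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(res$statistic, unname(h), tolerance = 1e-9)
  expect_equal(res$p_value, pchisq(h, 2, lower.tail = FALSE),
               tolerance = 1e-9)

  same <- kruskal_wallis(rep(1, 6), rep(c("a", "b"), 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)),
               class = "keytaxa_validation_error")
})

test_that("permutation spearman honours extremes, antisymmetry and seed", {
  x <- 1:20
  res <- spearman_perm(x, x + 0.5, B = 999, seed = 1)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 0.001)
  expect_true(res$reportable)

  rev <- spearman_perm(x, -x, B = 999, seed = 1)
  expect_equal(rev$statistic, -1)

  set.seed(2); a <- rnorm(15); b <- rnorm(15)
  r1 <- spearman_perm(a, b, B = 199, seed = 7)
  r2 <- spearman_perm(a, b, B = 199, seed = 7)
  expect_identical(r1, r2)
  expect_gte(r1$p_value, 1 / 200)

  expect_error(spearman_perm(rep(1, 10), rnorm(10)),
               class = "keytaxa_validation_error")
  expect_error(spearman_perm(1:3, 1:4), class = "keytaxa_validation_error")
})
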