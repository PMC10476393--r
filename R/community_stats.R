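#' Shannon diversity of one sample
#'
#' `H = -sum(p_i log p_i)` over the sample's nonzero proportions, natural
#' log by default.
#'
#' @param counts non-negative vector of counts or abundances
#' @param base logarithm base
#' @return Shannon index
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) {
    abort("counts must be non-negative", class = "keytaxa_validation_error")
  }
  if (sum(counts) <= 0) {
    abort("all-zero sample has undefined diversity",
          class = "keytaxa_validation_error")
  }
  unname(vegan::diversity(counts, index = "shannon", base = base))
}

#' Shannon diversity of every sample in a table
#'
#' @param tbl abundance table
#' @param base logarithm base
#' @return tibble with sample_id and shannon
#' @export
shannon_per_sample <- function(tbl, base = exp(1)) {
  m <- abundance_matrix(tbl)
  tibble::tibble(sample_id = colnames(m),
                 shannon = vapply(colnames(m),
                                  function(s) shannon(m[, s], base),
                                  numeric(1)))
}

#' Bray-Curtis distance between samples
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` over taxa.
#'
#' @param tbl abundance table with at least two samples
#' @return symmetric distance matrix with sample ids as dimnames
#' @export
bray_curtis <- function(tbl) {
  validate_abundance_table(tbl)
  m <- abundance_matrix(tbl)
  if (ncol(m) < 2) {
    abort("need at least 2 samples", class = "keytaxa_validation_error")
  }
  zero <- colnames(m)[colSums(m) == 0]
  if (length(zero) > 0) {
    abort(paste0("all-zero sample(s) have undefined Bray-Curtis distance: ",
                 paste(zero, collapse = ", ")),
          class = "keytaxa_validation_error")
  }
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

new_test_result <- function(statistic, p_value, method,
                            n_permutations = NA_integer_, ...) {
  tibble::tibble(statistic = statistic, p_value = p_value, method = method,
                 n_permutations = n_permutations, ...)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic
#' from the Gower-centered partition of the distance matrix, with a
#' permutation p-value `(#{F_perm >= F_obs} + 1) / (B + 1)` under random
#' relabelling.
#'
#' @param d symmetric distance matrix (e.g. from [bray_curtis()])
#' @param labels group label per sample, aligned with `d`'s rows
#' @param B number of permutations
#' @param seed integer seed for the permutations
#' @return one-row tibble: statistic (pseudo-F), p_value, method,
#'   n_permutations, df, r_squared
#' @export
permanova <- function(d, labels, B = 999, seed = 1) {
  labels <- as.character(labels)
  if (length(labels) != nrow(d)) {
    abort("labels must align with the distance matrix",
          class = "keytaxa_validation_error")
  }
  tab <- table(labels)
  if (length(tab) < 2) {
    abort("need at least 2 groups", class = "keytaxa_validation_error")
  }
  if (any(tab < 2)) {
    abort(paste0("singleton group(s): ",
                 paste(names(tab)[tab < 2], collapse = ", ")),
          class = "keytaxa_validation_error")
  }
  df <- data.frame(group = labels)
  set.seed(seed)
  fit <- vegan::adonis2(stats::as.dist(d) ~ group, data = df,
                        permutations = B)
  new_test_result(statistic = fit$F[1], p_value = fit$`Pr(>F)`[1],
                  method = "PERMANOVA", n_permutations = B,
                  df = fit$Df[1], r_squared = fit$R2[1])
}

#' Pairwise PERMANOVA over all group pairs
#'
#' Runs [permanova()] on every unordered pair of groups and adjusts the
#' p-values (Benjamini-Hochberg by default).
#'
#' @inheritParams permanova
#' @param adjust p-adjustment method (see [stats::p.adjust()])
#' @return tibble with one row per pair: group1, group2, statistic,
#'   p_value, adjusted_p
#' @export
pairwise_permanova <- function(d, labels, B = 999, seed = 1,
                               adjust = "BH") {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2) {
    abort("need at least 2 groups", class = "keytaxa_validation_error")
  }
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  res <- purrr::map_dfr(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    keep <- labels %in% pr
    r <- permanova(d[keep, keep, drop = FALSE], labels[keep], B = B,
                   seed = seed + i)
    dplyr::bind_cols(tibble::tibble(group1 = pr[1], group2 = pr[2]), r)
  })
  res$adjusted_p <- stats::p.adjust(res$p_value, method = adjust)
  res
}

#' Per-taxon Welch tests between two groups
#'
#' Two-sided Welch t-test (unequal variances, Satterthwaite df) on relative
#' abundances for every taxon. A taxon is reportable when `p <= alpha` and
#' the absolute between-group mean difference exceeds `min_abs_diff`
#' (default 0.001, i.e. 0.1% relative abundance). Taxa with zero variance
#' in both groups are flagged not testable.
#'
#' @param tbl abundance table (converted to relative abundances internally)
#' @param metadata metadata tibble with sample_id and group
#' @param groups the two group labels to compare
#' @param min_abs_diff minimum absolute mean difference for reporting
#' @param alpha significance level for reporting
#' @return tibble per taxon: taxon_id, mean difference and group means,
#'   statistic, df, p_value, testable, reportable
#' @export
welch_diff <- function(tbl, metadata, groups, min_abs_diff = 0.001,
                       alpha = 0.05) {
  if (length(groups) != 2) {
    abort("exactly two groups required", class = "keytaxa_validation_error")
  }
  check_metadata_coverage(tbl, metadata)
  rel <- abundance_matrix(relative_abundance(tbl))
  g <- metadata$group[match(colnames(rel), metadata$sample_id)]
  s1 <- colnames(rel)[g == groups[1]]
  s2 <- colnames(rel)[g == groups[2]]
  if (length(s1) < 2 || length(s2) < 2) {
    abort("both groups need at least 2 samples",
          class = "keytaxa_validation_error")
  }
  purrr::map_dfr(rownames(rel), function(tx) {
    x <- rel[tx, s1]; y <- rel[tx, s2]
    testable <- stats::var(x) > 0 || stats::var(y) > 0
    if (!testable) {
      return(tibble::tibble(taxon_id = tx, mean_1 = mean(x), mean_2 = mean(y),
                            mean_diff = mean(x) - mean(y),
                            statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_, testable = FALSE,
                            reportable = FALSE))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    md <- mean(x) - mean(y)
    tibble::tibble(taxon_id = tx, mean_1 = mean(x), mean_2 = mean(y),
                   mean_diff = md,
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   testable = TRUE,
                   reportable = tt$p.value <= alpha &&
                     abs(md) > min_abs_diff)
  })
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected H statistic with a chi-square p-value. With all values
#' identical the statistic is 0 and p is 1.
#'
#' @param values numeric vector
#' @param groups group label per value (at least 2 groups)
#' @return one-row tibble: statistic (H), p_value, method, df
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) {
    abort("need at least 2 groups", class = "keytaxa_validation_error")
  }
  if (length(unique(values)) == 1) {
    return(new_test_result(statistic = 0, p_value = 1,
                           method = "Kruskal-Wallis",
                           df = nlevels(groups) - 1))
  }
  kt <- stats::kruskal.test(values, groups)
  new_test_result(statistic = unname(kt$statistic), p_value = kt$p.value,
                  method = "Kruskal-Wallis", df = unname(kt$parameter))
}

#' Spearman correlation with a permutation significance test
#'
#' Spearman's rho on average ranks, with a two-sided permutation p-value
#' `(#{|rho_perm| >= |rho_obs|} + 1) / (B + 1)` obtained by permuting `y`.
#' The reportable flag applies the joint rule p <= alpha and
#' |rho| >= rho_min.
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant
#' @param B number of permutations (default 999)
#' @param seed integer seed
#' @param alpha significance level for the reportable flag
#' @param rho_min minimum |rho| for the reportable flag
#' @return one-row tibble: statistic (rho), p_value, method,
#'   n_permutations, reportable
#' @export
spearman_perm <- function(x, y, B = 999, seed = 1, alpha = 0.05,
                          rho_min = 0.5) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("x and y must have equal length >= 3",
          class = "keytaxa_validation_error")
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    abort("x and y must be finite", class = "keytaxa_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("constant input has undefined rank correlation",
          class = "keytaxa_validation_error")
  }
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  set.seed(seed)
  n_ge <- 0L
  for (i in seq_len(B)) {
    rho_p <- stats::cor(rx, sample(ry))
    if (abs(rho_p) >= abs(rho_obs) - 1e-12) n_ge <- n_ge + 1L
  }
  p <- (n_ge + 1) / (B + 1)
  new_test_result(statistic = rho_obs, p_value = p,
                  method = "Spearman (permutation)", n_permutations = B,
                  reportable = p <= alpha && abs(rho_obs) >= rho_min)
}
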