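MODULE_PALETTE <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                    "grey60", "lightgreen", "lightyellow", "royalblue")

# standardize taxa (rows) across samples; constant rows are the caller's
# problem and must be removed beforehand
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  (m - mu) / sd
}

#' Detect and drop outlier samples by hierarchical clustering
#'
#' Samples are clustered by average linkage on Euclidean distances of their
#' standardized taxon profiles; the tree is cut at a quantile of its merge
#' heights and every sample outside the largest cluster is treated as an
#' outlier. Removing more than a quarter of the samples is refused.
#'
#' @param tbl abundance table with at least 4 samples
#' @param cut_height_quantile quantile of merge heights at which to cut
#' @return list with `retained` and `removed` sample-id vectors
#' @export
remove_outlier_samples <- function(tbl, cut_height_quantile = 0.99) {
  validate_abundance_table(tbl)
  m <- abundance_matrix(tbl)
  if (ncol(m) < 4) {
    abort("need at least 4 samples for outlier screening",
          class = "keytaxa_validation_error")
  }
  keep_taxa <- apply(m, 1, stats::sd) > 0
  ms <- standardize_rows(m[keep_taxa, , drop = FALSE])
  tree <- stats::hclust(stats::dist(t(ms)), method = "average")
  # a sample only counts as an outlier when it joins the tree well above
  # the bulk of the merges: the cut sits at the height quantile, floored
  # at twice the median merge height so homogeneous data are never split
  h <- max(stats::quantile(tree$height, cut_height_quantile, names = FALSE),
           2 * stats::median(tree$height))
  cl <- stats::cutree(tree, h = h)
  main <- names(which.max(table(cl)))
  retained <- colnames(m)[cl == main]
  removed <- setdiff(colnames(m), retained)
  if (length(removed) > 0.25 * ncol(m)) {
    abort(paste0("outlier cut would remove ", length(removed), " of ",
                 ncol(m), " samples (> 25%); review the data manually"),
          class = "keytaxa_outlier_error")
  }
  if (length(removed) > 0) {
    message("removed outlier sample(s): ", paste(removed, collapse = ", "))
  }
  list(retained = retained, removed = removed)
}

#' Correlation-to-adjacency transform
#'
#' Unsigned weighted-network adjacency: `a_ij = |cor_ij|^beta`, diagonal set
#' to zero so connectivity sums exclude self-edges.
#'
#' @param cor_matrix symmetric correlation matrix with entries in `[-1, 1]`
#' @param beta soft-thresholding power (positive)
#' @return adjacency matrix
#' @export
adjacency_matrix <- function(cor_matrix, beta) {
  if (!isSymmetric(unname(cor_matrix), tol = 1e-10)) {
    abort("correlation matrix must be symmetric",
          class = "keytaxa_validation_error")
  }
  if (any(abs(cor_matrix) > 1 + 1e-10)) {
    abort("correlation entries must lie in [-1, 1]",
          class = "keytaxa_validation_error")
  }
  a <- abs(cor_matrix)^beta
  diag(a) <- 0
  a
}

#' Topological overlap similarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_u a_iu a_uj` over shared neighbours and `k_i` is node i's
#' connectivity; the diagonal is 1. Two taxa have high topological overlap
#' when they are strongly connected and share the same neighbourhood.
#'
#' @param a adjacency matrix (symmetric, entries in `[0, 1]`, zero diagonal)
#' @return TOM matrix
#' @export
tom_similarity <- function(a) {
  if (any(a < -1e-12 | a > 1 + 1e-12)) {
    abort("adjacency entries must lie in [0, 1]",
          class = "keytaxa_validation_error")
  }
  if (!isSymmetric(unname(a), tol = 1e-10)) {
    abort("adjacency must be symmetric", class = "keytaxa_validation_error")
  }
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Scan soft-thresholding powers for scale-free topology
#'
#' For each candidate power, forms the adjacency, computes connectivities,
#' and regresses `log10 p(k)` on `log10 k` over equal-width connectivity
#' bins. The recommended power is the smallest whose fit has R-squared at
#' least `r2_target` with a negative slope; if none qualifies the largest
#' scanned power is recommended with a warning.
#'
#' @param tbl abundance table
#' @param powers candidate powers
#' @param correlation `"pearson"` or `"spearman"`
#' @param n_bins connectivity histogram bins for the fit
#' @param r2_target scale-free fit threshold
#' @return tibble with power, r_squared, slope, mean_connectivity;
#'   the recommended power is in attribute `"recommended"`
#' @export
soft_power_scan <- function(tbl, powers = c(1:10, 12, 14, 16, 18, 20),
                            correlation = c("pearson", "spearman"),
                            n_bins = 10, r2_target = 0.8) {
  correlation <- match.arg(correlation)
  m <- abundance_matrix(relative_abundance(tbl))
  if (nrow(m) < 3) {
    abort("need at least 3 taxa", class = "keytaxa_validation_error")
  }
  const <- apply(m, 1, stats::sd) == 0
  if (any(const)) {
    warn(paste0("excluding ", sum(const), " constant taxa from the scan"))
    m <- m[!const, , drop = FALSE]
  }
  cc <- stats::cor(t(m), method = correlation)
  rows <- purrr::map_dfr(powers, function(p) {
    a <- adjacency_matrix(cc, p)
    k <- rowSums(a)
    fit <- scale_free_fit(k, n_bins)
    tibble::tibble(power = p, r_squared = fit$r_squared, slope = fit$slope,
                   mean_connectivity = mean(k))
  })
  ok <- which(rows$r_squared >= r2_target & rows$slope < 0)
  rec <- if (length(ok) > 0) {
    rows$power[min(ok)]
  } else {
    warn("no scanned power reached the scale-free fit target; using maximum")
    max(rows$power)
  }
  attr(rows, "recommended") <- rec
  rows
}

scale_free_fit <- function(k, n_bins = 10) {
  if (length(unique(k)) < 2) return(list(r_squared = 0, slope = 0))
  bins <- cut(k, breaks = n_bins)
  dk <- tapply(k, bins, mean)
  pk <- tapply(k, bins, length) / length(k)
  keep <- !is.na(dk) & dk > 0 & pk > 0
  if (sum(keep) < 3) return(list(r_squared = 0, slope = 0))
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]))
}

#' Cut the taxon dendrogram into co-occurrence modules
#'
#' Average-linkage clustering of the topological-overlap dissimilarity,
#' cut at a fixed quantile of the tree's merge heights (a deterministic
#' simplification of dynamic tree cutting). Clusters smaller than
#' `min_module_size` are pooled into the unassigned "grey" module; the
#' remaining modules are numbered and coloured by decreasing size over the
#' canonical palette (turquoise, blue, brown, ...).
#'
#' @param dissimilarity square matrix, typically `1 - TOM`
#' @param min_module_size smallest allowed module
#' @param cut_height_quantile quantile of merge heights at which to cut
#' @return tibble with taxon_id, module (integer, 0 = grey), color; the
#'   dendrogram is kept in attribute `"tree"`
#' @export
detect_modules <- function(dissimilarity, min_module_size = 30,
                           cut_height_quantile = 0.95) {
  n <- nrow(dissimilarity)
  ids <- rownames(dissimilarity)
  if (is.null(ids)) ids <- sprintf("T%03d", seq_len(n))
  if (n < min_module_size) {
    warn("fewer taxa than min_module_size; everything is unassigned")
    return(tibble::tibble(taxon_id = ids, module = 0L, color = "grey"))
  }
  tree <- stats::hclust(stats::as.dist(dissimilarity), method = "average")
  # dissimilarity lives on an absolute [0, 1] scale: merges below a small
  # floor are noise-level, so a tree of near-identical profiles stays one
  # module instead of being split at a quantile of tiny heights
  h <- max(stats::quantile(tree$height, cut_height_quantile, names = FALSE),
           0.05)
  raw <- stats::cutree(tree, h = h)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_module_size]
  # order surviving clusters by decreasing size (ties by first appearance)
  big <- big[order(-sizes[big], as.integer(big))]
  module <- match(as.character(raw), big)
  module[is.na(module)] <- 0L
  color <- ifelse(module == 0L, "grey",
                  MODULE_PALETTE[(module - 1L) %% length(MODULE_PALETTE) + 1L])
  out <- tibble::tibble(taxon_id = ids, module = as.integer(module),
                        color = color)
  attr(out, "tree") <- tree
  attr(out, "cut_height") <- h
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right-singular vector (across
#' samples) of its standardized taxon-by-sample profile matrix, oriented so
#' that its mean correlation with the member profiles is non-negative. The
#' proportion of module variance it explains is reported alongside.
#'
#' @param profiles standardized taxa-by-samples matrix (rows z-scored)
#' @param labels tibble from [detect_modules()] (taxon_id, module, color)
#' @return list with `eigengenes` (module-color x sample matrix) and
#'   `variance_explained` (named vector, fractions)
#' @export
module_eigengene <- function(profiles, labels) {
  stopifnot(all(labels$taxon_id %in% rownames(profiles)))
  mods <- unique(labels[order(labels$module), c("module", "color")])
  egs <- matrix(NA_real_, nrow = nrow(mods), ncol = ncol(profiles),
                dimnames = list(mods$color, colnames(profiles)))
  ve <- stats::setNames(numeric(nrow(mods)), mods$color)
  for (i in seq_len(nrow(mods))) {
    member <- labels$taxon_id[labels$module == mods$module[i]]
    x <- profiles[member, , drop = FALSE]
    if (any(apply(x, 1, stats::sd) == 0)) {
      abort(paste0("module `", mods$color[i],
                   "` contains zero-variance profiles"),
            class = "keytaxa_validation_error")
    }
    sv <- svd(x)
    eg <- sv$v[, 1]
    or <- mean(stats::cor(eg, t(x)))
    if (or < 0) eg <- -eg
    egs[i, ] <- eg
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = egs, variance_explained = ve)
}

#' Correlate module eigengenes with clinical traits
#'
#' Pearson (default) or Spearman correlation of every eigengene with every
#' numeric trait, pairwise-complete, with two-sided p-values. Traits
#' constant over the usable samples (or with fewer than `min_n` complete
#' pairs) are flagged untestable.
#'
#' @param eigengenes module-by-sample matrix from [module_eigengene()]
#' @param traits data frame of numeric traits with `sample_id` column (or
#'   rownames) aligned to the eigengene columns
#' @param method correlation type
#' @param min_n minimum complete pairs
#' @return tibble: module, trait, r, p_value, n, testable
#' @export
module_trait_correlation <- function(eigengenes, traits,
                                     method = c("pearson", "spearman"),
                                     min_n = 4) {
  method <- match.arg(method)
  if ("sample_id" %in% names(traits)) {
    rn <- traits$sample_id
    traits <- traits[, setdiff(names(traits), c("sample_id", "group")),
                     drop = FALSE]
    traits <- as.data.frame(traits)
    rownames(traits) <- rn
  }
  traits <- traits[colnames(eigengenes), , drop = FALSE]
  purrr::map_dfr(rownames(eigengenes), function(mod) {
    purrr::map_dfr(names(traits), function(tr) {
      x <- eigengenes[mod, ]
      y <- traits[[tr]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < min_n || stats::sd(y[ok]) == 0 ||
          stats::sd(x[ok]) == 0) {
        return(tibble::tibble(module = mod, trait = tr, r = NA_real_,
                              p_value = NA_real_, n = sum(ok),
                              testable = FALSE))
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = method)
      )
      tibble::tibble(module = mod, trait = tr,
                     r = unname(ct$estimate), p_value = ct$p.value,
                     n = sum(ok), testable = TRUE)
    })
  })
}

#' Connectivity and hub taxa
#'
#' Total connectivity `kTotal_i = sum_j a_ij`, intramodular connectivity
#' `kWithin_i` over same-module neighbours, and per non-grey module the hub
#' taxon with maximal kWithin (ties broken by lexicographically smallest
#' taxon id).
#'
#' @param a adjacency matrix
#' @param labels module assignment tibble (taxon_id, module, color)
#' @return list with `connectivity` tibble (taxon_id, module, color,
#'   k_total, k_within, is_hub) and `hubs` tibble per module
#' @export
connectivity_and_hubs <- function(a, labels) {
  stopifnot(setequal(rownames(a), labels$taxon_id))
  a <- a[labels$taxon_id, labels$taxon_id]
  k_total <- unname(rowSums(a))
  k_within <- vapply(seq_len(nrow(a)), function(i) {
    same <- labels$module == labels$module[i]
    sum(a[i, same]) - a[i, i]
  }, numeric(1))
  conn <- tibble::tibble(taxon_id = labels$taxon_id,
                         module = labels$module, color = labels$color,
                         k_total = k_total, k_within = k_within)
  hubs <- conn %>%
    dplyr::filter(.data$module > 0) %>%
    dplyr::group_by(.data$module, .data$color) %>%
    dplyr::arrange(dplyr::desc(.data$k_within), .data$taxon_id,
                   .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::select("module", "color", hub_taxon = "taxon_id",
                  "k_within")
  conn$is_hub <- conn$taxon_id %in% hubs$hub_taxon & conn$module > 0
  list(connectivity = conn, hubs = hubs)
}

#' Export a thresholded weighted edge list
#'
#' Upper-triangle edges with weight at or above the threshold, annotated
#' with module colors and source mean abundance — the import format of
#' external network viewers.
#'
#' @param mat adjacency or TOM matrix
#' @param threshold minimum edge weight in `[0, 1]`
#' @param labels module assignment tibble
#' @param abundances named vector of per-taxon mean abundances (optional)
#' @return tibble: source, target, weight, source_module, target_module,
#'   source_mean_abundance
#' @export
export_edgelist <- function(mat, threshold, labels = NULL,
                            abundances = NULL) {
  if (threshold < 0 || threshold > 1) {
    abort("threshold must lie in [0, 1]", class = "keytaxa_config_error")
  }
  ids <- rownames(mat)
  idx <- which(upper.tri(mat) & mat >= threshold, arr.ind = TRUE)
  out <- tibble::tibble(source = ids[idx[, 1]], target = ids[idx[, 2]],
                        weight = mat[idx])
  mod_of <- if (!is.null(labels)) {
    stats::setNames(labels$color, labels$taxon_id)
  } else NULL
  out$source_module <- if (is.null(mod_of)) NA_character_ else
    unname(mod_of[out$source])
  out$target_module <- if (is.null(mod_of)) NA_character_ else
    unname(mod_of[out$target])
  out$source_mean_abundance <- if (is.null(abundances)) NA_real_ else
    unname(abundances[out$source])
  dplyr::arrange(out, dplyr::desc(.data$weight))
}

#' Full co-occurrence module decomposition
#'
#' Runs the whole network stage on an abundance table: relative abundances,
#' constant-taxon removal, correlation, soft-power adjacency, topological
#' overlap, module detection, eigengenes, module-trait correlation, and
#' connectivity/hub analysis.
#'
#' @param tbl abundance table
#' @param metadata optional metadata tibble; its numeric columns are the
#'   traits for module-trait correlation
#' @param beta soft power (default 10)
#' @param min_module_size smallest module (default 30)
#' @param correlation `"pearson"` or `"spearman"`
#' @param cut_height_quantile merge-height quantile for the tree cut
#' @param trait_method correlation type for module-trait analysis
#' @return a `module_decomposition` object: labels, colors, eigengenes,
#'   variance_explained, connectivity, hubs, module_trait, adjacency, tom
#' @export
cooccurrence_network <- function(tbl, metadata = NULL, beta = 10,
                                 min_module_size = 30,
                                 correlation = c("pearson", "spearman"),
                                 cut_height_quantile = 0.95,
                                 trait_method = c("pearson", "spearman")) {
  correlation <- match.arg(correlation)
  trait_method <- match.arg(trait_method)
  rel <- relative_abundance(tbl)
  m <- abundance_matrix(rel)
  const <- apply(m, 1, stats::sd) == 0
  if (any(const)) {
    warn(paste0("excluding ", sum(const), " constant taxa from the network"))
    m <- m[!const, , drop = FALSE]
  }
  ms <- standardize_rows(m)
  cc <- stats::cor(t(ms), method = correlation)
  a <- adjacency_matrix(cc, beta)
  tom <- tom_similarity(a)
  labels <- detect_modules(1 - tom, min_module_size, cut_height_quantile)
  eg <- module_eigengene(ms, labels)
  mt <- if (!is.null(metadata)) {
    module_trait_correlation(eg$eigengenes, metadata, method = trait_method)
  } else NULL
  ch <- connectivity_and_hubs(a, labels)
  structure(
    list(labels = labels, eigengenes = eg$eigengenes,
         variance_explained = eg$variance_explained,
         connectivity = ch$connectivity, hubs = ch$hubs,
         module_trait = mt, adjacency = a, tom = tom,
         mean_abundance = rowMeans(m),
         config = list(beta = beta, min_module_size = min_module_size,
                       correlation = correlation,
                       cut_height_quantile = cut_height_quantile)),
    class = "module_decomposition"
  )
}

#' @export
print.module_decomposition <- function(x, ...) {
  nmod <- sum(unique(x$labels$module) > 0)
  cat("Co-occurrence module decomposition\n")
  cat("  ", nrow(x$labels), " taxa in ", nmod, " module(s) + grey (",
      sum(x$labels$module == 0), " unassigned)\n", sep = "")
  cat("  beta = ", x$config$beta, ", min module size = ",
      x$config$min_module_size, "\n", sep = "")
  invisible(x)
}

#' Tidy a module decomposition
#'
#' @param x a `module_decomposition`
#' @param ... unused
#' @return per-taxon tibble of module membership and connectivity
#' @export
tidy.module_decomposition <- function(x, ...) {
  x$connectivity
}

#' One-row summary of a module decomposition
#'
#' @param x a `module_decomposition`
#' @param ... unused
#' @export
glance.module_decomposition <- function(x, ...) {
  tibble::tibble(
    n_taxa = nrow(x$labels),
    n_modules = length(unique(x$labels$module[x$labels$module > 0])),
    n_unassigned = sum(x$labels$module == 0),
    beta = x$config$beta,
    min_module_size = x$config$min_module_size,
    median_variance_explained = stats::median(x$variance_explained)
  )
}

#' Module-trait correlation heatmap
#'
#' @param object a `module_decomposition` with trait correlations
#' @param ... unused
#' @export
autoplot.module_decomposition <- function(object, ...) {
  if (is.null(object$module_trait)) {
    abort("no module-trait correlations in this decomposition",
          class = "keytaxa_validation_error")
  }
  df <- dplyr::filter(object$module_trait, .data$testable)
  ggplot2::ggplot(df, ggplot2::aes(.data$trait, .data$module,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(p=%.2g)", .data$r, .data$p_value)),
      size = 2.7) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}
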