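#' Pipeline configuration
#'
#' Collects every stage's parameters into one list. Either in-memory
#' `table` / `metadata` or file paths must be supplied when running.
#'
#' @param table abundance table (tibble), or `NULL` to read from
#'   `table_path`
#' @param metadata metadata tibble, or `NULL` to read from `metadata_path`
#' @param table_path,metadata_path TSV paths used when in-memory inputs
#'   are absent
#' @param output_dir directory for stage outputs
#' @param level collapse level when lineages are present (`NULL` to skip)
#' @param persistent_min,transient_max ecological category boundaries
#' @param fit_candidates abundance-occupancy model families to try
#' @param classify_groups the two groups the forest separates
#' @param network_group community on which the co-occurrence network is
#'   built (`NULL` for all samples)
#' @param forest list of [tune_and_train()] settings
#' @param network list of [cooccurrence_network()] settings
#' @param integration list of report settings (top_k, case_max_freq,
#'   control_min_freq, p_threshold, case, control)
#' @param edge_threshold minimum edge weight for the exported edge list
#' @param permutations permutation count for permutation tests
#' @param seed global seed; per-stage seeds are derived from it
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(table = NULL, metadata = NULL,
                            table_path = NULL, metadata_path = NULL,
                            output_dir = tempfile("keytaxa_run_"),
                            level = NULL,
                            persistent_min = 0.75, transient_max = 0.25,
                            fit_candidates = AO_FAMILIES,
                            classify_groups = c("CD_F", "HC_F"),
                            network_group = "CD_F",
                            forest = list(),
                            network = list(beta = 10, min_module_size = 30),
                            integration = list(top_k = 10,
                                               case_max_freq = 0.15,
                                               control_min_freq = 0.70,
                                               p_threshold = 0.05,
                                               case = "CD_F",
                                               control = "HC_F"),
                            edge_threshold = 0.02,
                            permutations = 999,
                            seed = 1) {
  cfg <- list(table = table, metadata = metadata, table_path = table_path,
              metadata_path = metadata_path, output_dir = output_dir,
              level = level, persistent_min = persistent_min,
              transient_max = transient_max,
              fit_candidates = fit_candidates,
              classify_groups = classify_groups,
              network_group = network_group, forest = forest,
              network = network, integration = integration,
              edge_threshold = edge_threshold,
              permutations = permutations, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Range and type checks on every field, returned as a report rather than
#' raised, so a config can be inspected before anything is computed.
#'
#' @param cfg a `pipeline_config`
#' @return tibble with columns field, ok, message (failures and warnings)
#' @export
validate_config <- function(cfg) {
  checks <- list()
  add <- function(field, ok, message) {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      field = field, ok = ok, message = message)
  }
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  add("inputs",
      !is.null(cfg$table) || (!is.null(cfg$table_path) &&
                                file.exists(cfg$table_path)),
      "abundance table missing (no in-memory table and no existing path)")
  add("metadata",
      !is.null(cfg$metadata) || (!is.null(cfg$metadata_path) &&
                                   file.exists(cfg$metadata_path)),
      "metadata missing (no in-memory metadata and no existing path)")
  add("persistent_min", in01(cfg$persistent_min),
      "persistent_min must lie in [0, 1]")
  add("transient_max", in01(cfg$transient_max),
      "transient_max must lie in [0, 1]")
  add("thresholds_ordered",
      in01(cfg$persistent_min) && in01(cfg$transient_max) &&
        cfg$transient_max < cfg$persistent_min,
      "transient_max must be below persistent_min")
  beta <- cfg$network$beta %||% 10
  add("network.beta", is.numeric(beta) && beta >= 1,
      "soft power must be >= 1")
  if (is.numeric(beta) && beta > 20) {
    add("network.beta_range", FALSE, "warning: beta > 20 is unusual")
  }
  mms <- cfg$network$min_module_size %||% 30
  add("network.min_module_size", is.numeric(mms) && mms >= 2,
      "min_module_size must be >= 2")
  add("integration.case_max_freq",
      in01(cfg$integration$case_max_freq %||% 0.15),
      "case_max_freq must lie in [0, 1]")
  add("integration.control_min_freq",
      in01(cfg$integration$control_min_freq %||% 0.70),
      "control_min_freq must lie in [0, 1]")
  add("classify_groups", length(cfg$classify_groups) == 2,
      "classify_groups must name exactly two groups")
  add("permutations", cfg$permutations >= 1,
      "permutations must be positive")
  add("seed", is.numeric(cfg$seed) && length(cfg$seed) == 1,
      "seed must be a single number")
  out <- dplyr::bind_rows(checks)
  out$message[out$ok] <- ""
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-stage seed below 2^31, derived from the global seed and
# the stage name so stages can be rerun in isolation
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Run the full key-taxa workflow
#'
#' Stages, in order: table/metadata loading and validation, optional
#' taxonomic collapse, per-community occurrence frequencies and category
#' summaries, abundance-occupancy model fitting, community statistics
#' (Shannon + Kruskal-Wallis, Bray-Curtis + pairwise PERMANOVA), the
#' random-forest classifier, the co-occurrence module decomposition with
#' module-trait correlations, and the integrated key-taxa report. All
#' stage outputs are written as TSV under `cfg$output_dir` together with a
#' JSON manifest; any stage failure aborts with the stage name.
#'
#' @param cfg a `pipeline_config`
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest
#' @export
run_pipeline <- function(cfg) {
  v <- validate_config(cfg)
  hard <- v[!v$ok & !startsWith(v$message, "warning"), ]
  if (nrow(hard) > 0) {
    abort(paste0("invalid configuration: ",
                 paste(hard$field, collapse = ", ")),
          class = "keytaxa_config_error")
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(
                     utils::packageVersion("keytaxa")),
                   config_hash = config_hash(cfg), stages = list())
  results <- list()
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      abort(paste0("stage `", name, "` failed: ", conditionMessage(e)),
            class = "keytaxa_stage_error", parent = e)
    })
    results[[name]] <<- res$value
    manifest$stages[[name]] <<- res$info
    res$value
  }

  tbl <- NULL; meta <- NULL
  run_stage("tables_io", function() {
    t <- cfg$table %||% read_abundance_table(cfg$table_path)
    m <- cfg$metadata %||% read_metadata(cfg$metadata_path)
    check_metadata_coverage(t, m)
    if (!is.null(cfg$level) && "lineage" %in% names(t)) {
      t <- collapse_taxonomy(t, cfg$level)
    }
    tbl <<- t; meta <<- m
    list(value = list(table = t, metadata = m),
         info = list(n_taxa = nrow(t), n_samples = length(sample_ids(t))))
  })

  groups <- split(meta$sample_id, meta$group)
  communities <- c(groups, list(all = meta$sample_id))

  occ <- run_stage("occupancy", function() {
    profiles <- occurrence_frequencies(
      tbl, communities, persistent_min = cfg$persistent_min,
      transient_max = cfg$transient_max)
    summaries <- purrr::imap_dfr(communities, function(s, nm) {
      p <- occurrence_frequency(tbl, s, nm, cfg$persistent_min,
                                cfg$transient_max)
      category_summary(tbl, p)
    })
    pooled <- occurrence_frequency(tbl, communities$all, "all",
                                   cfg$persistent_min, cfg$transient_max)
    pts <- abundance_occupancy_points(tbl, pooled)
    fit <- fit_abundance_occupancy(pts, cfg$fit_candidates)
    readr::write_tsv(profiles, file.path(cfg$output_dir, "occupancy.tsv"),
                     progress = FALSE)
    readr::write_tsv(summaries,
                     file.path(cfg$output_dir, "category_summary.tsv"),
                     progress = FALSE)
    readr::write_tsv(tidy(fit), file.path(cfg$output_dir, "ao_fit.tsv"),
                     progress = FALSE)
    list(value = list(profiles = profiles, summaries = summaries,
                      ao_fit = fit),
         info = list(n_communities = length(communities),
                     best_family = fit$model_family))
  })

  run_stage("community_stats", function() {
    sh <- shannon_per_sample(tbl)
    sh$group <- meta$group[match(sh$sample_id, meta$sample_id)]
    kw <- kruskal_wallis(sh$shannon, sh$group)
    d <- bray_curtis(tbl)
    labels <- meta$group[match(rownames(d), meta$sample_id)]
    pp <- pairwise_permanova(d, labels, B = cfg$permutations,
                             seed = stage_seed(cfg$seed, "permanova"))
    readr::write_tsv(sh, file.path(cfg$output_dir, "shannon.tsv"),
                     progress = FALSE)
    readr::write_tsv(pp, file.path(cfg$output_dir,
                                   "pairwise_permanova.tsv"),
                     progress = FALSE)
    list(value = list(shannon = sh, kruskal = kw, permanova = pp),
         info = list(n_pairs = nrow(pp),
                     kw_p = kw$p_value))
  })

  forest <- run_stage("rf_classifier", function() {
    keep <- meta$sample_id[meta$group %in% cfg$classify_groups]
    rel <- relative_abundance(tbl[, c("taxon_id", keep)])
    x <- t(abundance_matrix(rel))
    y <- meta$group[match(keep, meta$sample_id)]
    args <- c(list(features = x, labels = y,
                   seed = stage_seed(cfg$seed, "rf_classifier")),
              cfg$forest)
    fit <- do.call(tune_and_train, args)
    readr::write_tsv(fit$importance,
                     file.path(cfg$output_dir, "importance.tsv"),
                     progress = FALSE)
    readr::write_tsv(fit$oob_curve,
                     file.path(cfg$output_dir, "oob_curve.tsv"),
                     progress = FALSE)
    list(value = fit,
         info = list(mtry = fit$mtry, ntree = fit$ntree,
                     oob_error = fit$oob_error))
  })

  net <- run_stage("coocc_network", function() {
    samp <- if (is.null(cfg$network_group)) meta$sample_id else
      meta$sample_id[meta$group %in% cfg$network_group]
    sub <- tbl[, c("taxon_id", samp)]
    present <- rowSums(abundance_matrix(sub) > 0) > 0
    sub <- sub[present, ]
    args <- c(list(tbl = sub, metadata = meta[meta$sample_id %in% samp, ]),
              cfg$network)
    dec <- do.call(cooccurrence_network, args)
    el <- export_edgelist(dec$tom, cfg$edge_threshold, dec$labels,
                          dec$mean_abundance)
    readr::write_tsv(dec$labels, file.path(cfg$output_dir, "modules.tsv"),
                     progress = FALSE)
    readr::write_tsv(tibble::as_tibble(dec$eigengenes,
                                       rownames = "module"),
                     file.path(cfg$output_dir, "eigengenes.tsv"),
                     progress = FALSE)
    if (!is.null(dec$module_trait)) {
      readr::write_tsv(dec$module_trait,
                       file.path(cfg$output_dir, "module_trait.tsv"),
                       progress = FALSE)
    }
    readr::write_tsv(el, file.path(cfg$output_dir, "edges.tsv"),
                     progress = FALSE)
    list(value = dec,
         info = list(n_modules = length(unique(
           dec$labels$module[dec$labels$module > 0])),
           n_edges = nrow(el)))
  })

  run_stage("integration_report", function() {
    lin <- if ("lineage" %in% names(tbl)) {
      stats::setNames(tbl$lineage, tbl$taxon_id)
    } else NULL
    it <- cfg$integration
    report <- build_key_taxa_report(
      forest$importance,
      occ$profiles[occ$profiles$community != "all", ],
      net$labels, lineage = lin, top_k = it$top_k %||% 10)
    if (!is.null(net$module_trait)) {
      report <- attach_clinical_links(report, net$module_trait,
                                      it$p_threshold %||% 0.05)
    }
    report <- flag_diagnostic_candidates(
      report, it$case_max_freq %||% 0.15, it$control_min_freq %||% 0.70,
      case = it$case %||% "CD_F", control = it$control %||% "HC_F")
    out <- dplyr::select(report, -dplyr::any_of("trait_links"))
    readr::write_tsv(out,
                     file.path(cfg$output_dir, "key_taxa_report.tsv"),
                     progress = FALSE)
    list(value = report,
         info = list(n_rows = nrow(report),
                     n_flagged = sum(report$diagnostic)))
  })

  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest)))
}

# stable hash of the configuration (paths and in-memory data included)
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(cfg, digits.d = 12)), tmp)
  unname(tools::md5sum(tmp))
}
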