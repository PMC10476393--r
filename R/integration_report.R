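#' Build the integrated key-taxa report
#'
#' Cross-references the classifier's top taxa with their occurrence
#' frequency and ecological category in every community, their
#' co-occurrence module membership, and (via [attach_clinical_links()])
#' their module's significant clinical-trait correlations — the workflow's
#' headline table. Rows are sorted by mean decrease in accuracy; a taxon
#' undetected in a community is reported at frequency 0 (hence transient).
#'
#' @param importance importance tibble (taxon_id, mean_decrease_accuracy,
#'   mean_decrease_gini), e.g. from [oob_importance()]
#' @param profiles row-bound occupancy profiles over the communities of
#'   interest, from [occurrence_frequencies()]
#' @param modules module assignment tibble (taxon_id, module, color) or a
#'   `module_decomposition`; taxa absent from it are treated as grey
#' @param lineage optional named character vector of lineage strings; adds
#'   phylum/class/order/family columns
#' @param top_k number of top taxa to report
#' @return tibble: taxon_id, lineage ranks (optional), importance scores,
#'   `freq_<community>` and `category_<community>` per community, module,
#'   module_color
#' @export
build_key_taxa_report <- function(importance, profiles, modules = NULL,
                                  lineage = NULL, top_k = 10) {
  if (top_k < 1) {
    abort("top_k must be at least 1", class = "keytaxa_config_error")
  }
  top <- importance %>%
    dplyr::arrange(dplyr::desc(.data$mean_decrease_accuracy)) %>%
    utils::head(top_k)
  unmatched <- setdiff(top$taxon_id, unique(profiles$taxon_id))
  if (length(unmatched) > 0) {
    abort(paste0("taxa absent from occupancy profiles: ",
                 paste(unmatched, collapse = ", ")),
          class = "keytaxa_join_error")
  }
  freq_wide <- profiles %>%
    dplyr::filter(.data$taxon_id %in% top$taxon_id) %>%
    dplyr::select("community", "taxon_id", "frequency", "category") %>%
    tidyr::pivot_wider(names_from = "community",
                       values_from = c("frequency", "category"),
                       names_glue = "{.value}_{community}")
  out <- dplyr::left_join(top, freq_wide, by = "taxon_id")
  # a taxon filtered out of one community's table is simply never there
  for (cm in unique(profiles$community)) {
    fc <- paste0("frequency_", cm)
    cc <- paste0("category_", cm)
    out[[fc]][is.na(out[[fc]])] <- 0
    out[[cc]][is.na(out[[cc]])] <- assign_category(0)
  }
  if (!is.null(modules)) {
    if (inherits(modules, "module_decomposition")) modules <- modules$labels
    out <- dplyr::left_join(
      out, dplyr::select(modules, "taxon_id", "module",
                         module_color = "color"),
      by = "taxon_id")
    out$module[is.na(out$module)] <- 0L
    out$module_color[is.na(out$module_color)] <- "grey"
  }
  if (!is.null(lineage)) {
    ranks <- parse_lineage(unname(lineage[out$taxon_id]))
    out <- dplyr::bind_cols(
      out, ranks[, c("phylum", "class", "order", "family")])
  }
  out
}

#' Flag diagnostic-candidate taxa
#'
#' Marks taxa that occur rarely in the case community but frequently in the
#' control community — the occurrence pattern that makes a taxon a
#' promising presence/absence diagnostic marker.
#'
#' @param report key-taxa report with `frequency_<case>` and
#'   `frequency_<control>` columns
#' @param case_max_freq maximum case-community frequency (default 0.15)
#' @param control_min_freq minimum control-community frequency
#'   (default 0.70)
#' @param case,control community names (defaults CD_F / HC_F)
#' @return the report with a logical `diagnostic` column
#' @export
flag_diagnostic_candidates <- function(report, case_max_freq = 0.15,
                                       control_min_freq = 0.70,
                                       case = "CD_F", control = "HC_F") {
  if (case_max_freq < 0 || case_max_freq > 1 ||
      control_min_freq < 0 || control_min_freq > 1) {
    abort("frequency thresholds must lie in [0, 1]",
          class = "keytaxa_config_error")
  }
  fc <- paste0("frequency_", case)
  fh <- paste0("frequency_", control)
  if (!all(c(fc, fh) %in% names(report))) {
    abort(paste0("report lacks `", fc, "` / `", fh, "` columns"),
          class = "keytaxa_validation_error")
  }
  dplyr::mutate(report,
                diagnostic = .data[[fc]] <= case_max_freq &
                  .data[[fh]] >= control_min_freq)
}

#' Attach module-trait links to a key-taxa report
#'
#' Every taxon inherits its module's significant trait correlations
#' (`p <= p_threshold` among testable pairs); grey-module taxa get none.
#' Links are stored as a nested `trait_links` list-column plus a readable
#' `trait_links_str` summary.
#'
#' @param report key-taxa report with a `module_color` column
#' @param module_trait module-trait tibble from
#'   [module_trait_correlation()]
#' @param p_threshold significance threshold
#' @return the report with `trait_links` and `trait_links_str` columns
#' @export
attach_clinical_links <- function(report, module_trait,
                                  p_threshold = 0.05) {
  if (!"module_color" %in% names(report)) {
    abort("report lacks a `module_color` column (build with modules)",
          class = "keytaxa_validation_error")
  }
  sig <- module_trait %>%
    dplyr::filter(.data$testable, .data$p_value <= p_threshold) %>%
    dplyr::select("module", "trait", "r", "p_value")
  empty <- sig[0, c("trait", "r", "p_value")]
  report$trait_links <- purrr::map(report$module_color, function(col) {
    if (col == "grey") return(empty)
    dplyr::select(sig[sig$module == col, ], "trait", "r", "p_value")
  })
  report$trait_links_str <- purrr::map_chr(report$trait_links, function(l) {
    if (nrow(l) == 0) return("")
    paste(sprintf("%s (r=%.2f, p=%.3g)", l$trait, l$r, l$p_value),
          collapse = "; ")
  })
  report
}
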