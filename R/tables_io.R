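#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

RANK_PREFIXES <- c(
  domain = "d", phylum = "p", class = "c", order = "o",
  family = "f", genus = "g", species = "s"
)

TAXON_LEVELS <- c("asv", names(RANK_PREFIXES))

#' Column names of the samples in an abundance table
#'
#' An abundance table is a tibble with a `taxon_id` column, an optional
#' `lineage` column of silva-style strings (`d__...; p__...; ...`), and one
#' numeric column per sample (taxa in rows, samples in columns).
#'
#' @param tbl abundance table (tibble)
#' @return character vector of sample ids, in column order
#' @export
sample_ids <- function(tbl) {
  setdiff(names(tbl), c("taxon_id", "lineage"))
}

#' Abundance values of a table as a taxa-by-samples matrix
#'
#' @param tbl abundance table
#' @return numeric matrix with taxon ids as rownames and sample ids as colnames
#' @export
abundance_matrix <- function(tbl) {
  sids <- sample_ids(tbl)
  m <- as.matrix(tbl[, sids, drop = FALSE])
  rownames(m) <- tbl$taxon_id
  m
}

#' Validate an abundance table
#'
#' Checks the invariants every stage of the workflow relies on: unique taxon
#' and sample identifiers, numeric non-negative values, and (optionally) that
#' each sample column sums to 1 when the table is declared relative.
#'
#' @param tbl abundance table
#' @param relative if `TRUE`, require each sample column to sum to 1 (1e-9)
#' @return `tbl`, invisibly, on success
#' @export
validate_abundance_table <- function(tbl, relative = FALSE) {
  if (!is.data.frame(tbl) || !"taxon_id" %in% names(tbl)) {
    abort("abundance table must be a data frame with a `taxon_id` column",
          class = "keytaxa_format_error")
  }
  dup_t <- unique(tbl$taxon_id[duplicated(tbl$taxon_id)])
  if (length(dup_t) > 0) {
    abort(paste0("duplicate taxon id(s): ", paste(dup_t, collapse = ", ")),
          class = "keytaxa_format_error")
  }
  sids <- sample_ids(tbl)
  if (anyDuplicated(sids)) {
    abort(paste0("duplicate sample id(s): ",
                 paste(unique(sids[duplicated(sids)]), collapse = ", ")),
          class = "keytaxa_format_error")
  }
  for (s in sids) {
    v <- tbl[[s]]
    if (!is.numeric(v)) {
      abort(paste0("sample column `", s, "` is not numeric"),
            class = "keytaxa_validation_error")
    }
    bad <- which(!is.na(v) & v < 0)
    if (length(bad) > 0) {
      abort(paste0("negative abundance at taxon `", tbl$taxon_id[bad[1]],
                   "`, sample `", s, "`"),
            class = "keytaxa_validation_error")
    }
    if (anyNA(v)) {
      abort(paste0("missing abundance value in sample `", s, "`"),
            class = "keytaxa_validation_error")
    }
  }
  if (relative && length(sids) > 0) {
    cs <- colSums(abundance_matrix(tbl))
    off <- which(abs(cs - 1) > 1e-9)
    if (length(off) > 0) {
      abort(paste0("relative table columns must sum to 1; sample `",
                   sids[off[1]], "` sums to ", format(cs[off[1]])),
            class = "keytaxa_validation_error")
    }
  }
  invisible(tbl)
}

#' Read a taxon-by-sample abundance table
#'
#' Two dialects of tab-separated tables are supported. `"tsv"`: first column
#' taxon id, header row of sample ids. `"biom_tsv"`: the classic BIOM TSV
#' export, with an optional leading `# Constructed from biom file` comment
#' line, an `#OTU ID` header, and a trailing `taxonomy` column holding
#' semicolon-separated silva-style lineage strings.
#'
#' @param path path to a TSV file
#' @param dialect `"tsv"` or `"biom_tsv"`
#' @param level taxonomic rank label to attach to the result
#'   (one of asv, species, genus, family, order, class, phylum)
#' @return a validated abundance table (tibble); when lineages are present
#'   they are kept in a `lineage` column
#' @export
read_abundance_table <- function(path, dialect = c("tsv", "biom_tsv"),
                                 level = "asv") {
  dialect <- match.arg(dialect)
  level <- match.arg(level, TAXON_LEVELS)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "keytaxa_format_error")
  }
  lines <- readr::read_lines(path)
  if (dialect == "biom_tsv" && length(lines) > 0 &&
      grepl("^#\\s*Constructed from biom", lines[1])) {
    lines <- lines[-1]
  }
  raw <- readr::read_tsv(I(paste0(lines, collapse = "\n")),
                         col_types = readr::cols(),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2) {
    abort("abundance table needs a taxon id column and at least one sample",
          class = "keytaxa_format_error")
  }
  names(raw)[1] <- "taxon_id"
  raw$taxon_id <- as.character(raw$taxon_id)
  has_tax <- tolower(names(raw)[ncol(raw)]) == "taxonomy"
  if (dialect == "biom_tsv" && has_tax) {
    names(raw)[ncol(raw)] <- "lineage"
    raw$lineage <- as.character(raw$lineage)
    raw <- raw[, c("taxon_id", "lineage",
                   setdiff(names(raw), c("taxon_id", "lineage")))]
  }
  tbl <- tibble::as_tibble(raw)
  validate_abundance_table(tbl)
  attr(tbl, "level") <- level
  tbl
}

#' Write an abundance table to TSV
#'
#' Inverse of [read_abundance_table()]; lineages, when present, are written
#' as a trailing `taxonomy` column so the file round-trips through the
#' `biom_tsv` dialect.
#'
#' @param tbl abundance table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_abundance_table <- function(tbl, path) {
  out <- tbl
  if ("lineage" %in% names(out)) {
    out <- out[, c("taxon_id", sample_ids(out), "lineage")]
    names(out)[ncol(out)] <- "taxonomy"
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Parse silva-style lineage strings
#'
#' Splits strings like `"d__Bacteria; p__Firmicutes; g__Blautia"` into one
#' column per rank. Missing or empty ranks become `NA`.
#'
#' @param x character vector of lineage strings
#' @return tibble with columns domain, phylum, class, order, family, genus,
#'   species (character, `NA` where unnamed)
#' @export
parse_lineage <- function(x) {
  out <- matrix(NA_character_, nrow = length(x), ncol = length(RANK_PREFIXES),
                dimnames = list(NULL, names(RANK_PREFIXES)))
  for (i in seq_along(x)) {
    if (is.na(x[i]) || !nzchar(trimws(x[i]))) next
    parts <- trimws(strsplit(x[i], ";", fixed = TRUE)[[1]])
    for (p in parts) {
      m <- regmatches(p, regexec("^([dpcofgs])__(.*)$", p))[[1]]
      if (length(m) == 3) {
        rank <- names(RANK_PREFIXES)[match(m[2], RANK_PREFIXES)]
        if (!is.na(rank) && nzchar(m[3])) out[i, rank] <- m[3]
      }
    }
  }
  tibble::as_tibble(out)
}

# Label for each taxon at `level`, applying the fallback rule: unnamed at the
# requested rank -> finest named coarser rank, prefixed by its rank letter
# (producing the "d_Bacteria" / "f_Christensenellaceae" pseudo-taxa); nothing
# named at all -> "Unassigned".
lineage_label <- function(lineage, level) {
  ranks <- parse_lineage(lineage)
  idx <- match(level, names(RANK_PREFIXES))
  vapply(seq_len(nrow(ranks)), function(i) {
    row <- as.character(ranks[i, ])
    if (!is.na(row[idx])) return(row[idx])
    coarser <- rev(seq_len(idx - 1))
    for (j in coarser) {
      if (!is.na(row[j])) {
        return(paste0(RANK_PREFIXES[j], "_", row[j]))
      }
    }
    "Unassigned"
  }, character(1))
}

#' Collapse an abundance table to a coarser taxonomic rank
#'
#' Rows sharing the same name at `level` are summed. Taxa without a name at
#' the requested rank fall back to the finest named coarser rank, labelled
#' with its rank letter (e.g. a domain-only lineage collapses to
#' `"d_Bacteria"`); taxa with no named rank at all collapse to
#' `"Unassigned"`.
#'
#' @param tbl abundance table with a `lineage` column
#' @param level target rank (phylum, class, order, family, genus, species)
#' @return abundance table at the requested rank, taxa ordered by first
#'   appearance; total abundance per sample is conserved
#' @export
collapse_taxonomy <- function(tbl, level) {
  level <- match.arg(level, names(RANK_PREFIXES))
  validate_abundance_table(tbl)
  if (!"lineage" %in% names(tbl)) {
    abort(paste0("collapse requires lineages; missing for all ",
                 nrow(tbl), " taxa"),
          class = "keytaxa_validation_error")
  }
  missing_lin <- tbl$taxon_id[is.na(tbl$lineage)]
  if (length(missing_lin) > 0) {
    abort(paste0("missing lineage for taxa: ",
                 paste(utils::head(missing_lin, 5), collapse = ", ")),
          class = "keytaxa_validation_error")
  }
  labels <- lineage_label(tbl$lineage, level)
  sids <- sample_ids(tbl)
  out <- tbl %>%
    dplyr::mutate(taxon_id = labels) %>%
    dplyr::group_by(.data$taxon_id) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(sids), sum),
                     .groups = "drop") %>%
    dplyr::arrange(match(.data$taxon_id, labels))
  attr(out, "level") <- level
  out
}

#' Convert counts to relative abundances
#'
#' Divides each sample column by its total so columns sum to 1. Idempotent
#' and scale-invariant; a sample with no observed taxa is an error because
#' its composition is undefined.
#'
#' @param tbl abundance table (counts or already-relative values)
#' @return abundance table of per-sample fractions
#' @export
relative_abundance <- function(tbl) {
  validate_abundance_table(tbl)
  sids <- sample_ids(tbl)
  for (s in sids) {
    tot <- sum(tbl[[s]])
    if (tot <= 0) {
      abort(paste0("sample `", s, "` has zero total abundance"),
            class = "keytaxa_degenerate_sample_error")
    }
    tbl[[s]] <- tbl[[s]] / tot
  }
  tbl
}

#' Read a sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `group`, and then any number of
#' numeric clinical-trait columns (e.g. CRP, monocytes, CC3, CC4, glucose,
#' bas_ratio). Non-numeric trait cells become missing values with a warning.
#'
#' @param path path to metadata TSV
#' @return tibble with character `sample_id` and `group`, numeric traits
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "keytaxa_format_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (!all(c("sample_id", "group") %in% names(raw))) {
    abort("metadata must have `sample_id` and `group` columns",
          class = "keytaxa_format_error")
  }
  traits <- setdiff(names(raw), c("sample_id", "group"))
  for (tr in traits) {
    v <- raw[[tr]]
    num <- suppressWarnings(as.numeric(v))
    coerced <- !is.na(v) & v != "NA" & is.na(num)
    if (any(coerced)) {
      warn(paste0("trait `", tr, "`: ", sum(coerced),
                  " non-numeric cell(s) set to missing"))
    }
    raw[[tr]] <- num
  }
  if (anyDuplicated(raw$sample_id)) {
    abort("duplicate sample_id in metadata", class = "keytaxa_format_error")
  }
  raw
}

#' Check that metadata covers every sample in a table
#'
#' @param tbl abundance table
#' @param metadata metadata tibble from [read_metadata()]
#' @return invisibly `TRUE`; errors listing orphan samples otherwise
#' @export
check_metadata_coverage <- function(tbl, metadata) {
  orphans <- setdiff(sample_ids(tbl), metadata$sample_id)
  if (length(orphans) > 0) {
    abort(paste0("samples missing from metadata: ",
                 paste(orphans, collapse = ", ")),
          class = "keytaxa_join_error")
  }
  invisible(TRUE)
}
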