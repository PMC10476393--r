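CATEGORY_LEVELS <- c("persistent", "intermittent", "transient")

#' Assign ecological categories from occurrence frequencies
#'
#' Taxa are classified by how often they occur across a community's samples:
#' persistent at frequency >= 0.75, transient at frequency <= 0.25, and
#' intermittent strictly in between. Both boundaries are inclusive for the
#' outer categories, so 0.75 is persistent and 0.25 is transient.
#'
#' @param freq numeric vector of occurrence frequencies in `[0, 1]`
#' @param persistent_min lower (inclusive) bound of the persistent category
#' @param transient_max upper (inclusive) bound of the transient category
#' @return character vector of categories
#' @export
assign_category <- function(freq, persistent_min = 0.75,
                            transient_max = 0.25) {
  if (any(!is.finite(freq)) || any(freq < 0 | freq > 1)) {
    abort("occurrence frequencies must lie in [0, 1]",
          class = "keytaxa_validation_error")
  }
  dplyr::case_when(
    freq >= persistent_min ~ "persistent",
    freq <= transient_max ~ "transient",
    TRUE ~ "intermittent"
  )
}

#' Occurrence frequency of each taxon within a community
#'
#' A taxon is present in a sample when its value is greater than zero; its
#' occurrence frequency is the fraction of the community's samples in which
#' it is present. Taxa absent from every community sample are flagged
#' undetected (they are excluded from category summaries and fits, not
#' reported as frequency-0 members).
#'
#' @param tbl abundance table
#' @param samples sample ids defining the community; `NULL` for all samples
#' @param community label for the community (e.g. "CD_F", "group-FM")
#' @param persistent_min,transient_max category boundaries, see
#'   [assign_category()]
#' @return tibble with columns community, taxon_id, n_present, n_total,
#'   frequency, category, detected
#' @export
occurrence_frequency <- function(tbl, samples = NULL, community = "all",
                                 persistent_min = 0.75,
                                 transient_max = 0.25) {
  validate_abundance_table(tbl)
  all_samples <- sample_ids(tbl)
  if (is.null(samples)) samples <- all_samples
  if (length(samples) == 0) {
    abort(paste0("community `", community, "` is empty"),
          class = "keytaxa_validation_error")
  }
  missing <- setdiff(samples, all_samples)
  if (length(missing) > 0) {
    abort(paste0("community samples not in table: ",
                 paste(missing, collapse = ", ")),
          class = "keytaxa_validation_error")
  }
  m <- abundance_matrix(tbl)[, samples, drop = FALSE]
  n_present <- unname(rowSums(m > 0))
  n_total <- length(samples)
  freq <- n_present / n_total
  out <- tibble::tibble(
    community = community,
    taxon_id = tbl$taxon_id,
    n_present = as.integer(n_present),
    n_total = as.integer(n_total),
    frequency = freq,
    category = assign_category(freq, persistent_min, transient_max),
    detected = n_present > 0
  )
  attr(out, "samples") <- samples
  out
}

#' Occurrence frequencies for several communities at once
#'
#' @param tbl abundance table
#' @param communities named list of sample-id vectors
#' @param ... passed to [occurrence_frequency()]
#' @return row-bound tibble of per-community profiles
#' @export
occurrence_frequencies <- function(tbl, communities, ...) {
  purrr::imap_dfr(communities,
                  function(s, nm) occurrence_frequency(tbl, s, nm, ...))
}

#' Summarise ecological categories of a community
#'
#' For the taxa detected in a community, reports per category the taxon
#' count, the proportion of all detected taxa, and the cumulative mean
#' relative abundance (sum over member taxa of their mean relative abundance
#' across the community's samples, as a percentage). Proportions sum to 1
#' and cumulative abundances to 100%.
#'
#' @param tbl abundance table (counts or relative)
#' @param profile occupancy profile from [occurrence_frequency()] for one
#'   community
#' @return tibble with columns community, category, taxon_count,
#'   taxon_proportion, cumulative_mean_abundance_pct
#' @export
category_summary <- function(tbl, profile) {
  validate_abundance_table(tbl)
  if (length(unique(profile$community)) != 1) {
    abort("profile must describe a single community",
          class = "keytaxa_validation_error")
  }
  if (!setequal(profile$taxon_id, tbl$taxon_id)) {
    abort("profile and table cover different taxa",
          class = "keytaxa_validation_error")
  }
  samples <- attr(profile, "samples")
  # the community's samples are recoverable from the profile row counts only
  # if stored; recompute from the table when all samples were used
  n_total <- profile$n_total[1]
  sids <- sample_ids(tbl)
  if (is.null(samples)) {
    if (n_total != length(sids)) {
      abort("pass the community's table (or a profile over all its samples)",
            class = "keytaxa_validation_error")
    }
    samples <- sids
  }
  rel <- abundance_matrix(relative_abundance(tbl[, c("taxon_id", samples)]))
  mean_rel <- rowMeans(rel)
  det <- profile[profile$detected, c("taxon_id", "community", "category")]
  det$mean_rel <- mean_rel[det$taxon_id]
  total_det <- nrow(det)
  total_abund <- sum(det$mean_rel)
  out <- det %>%
    dplyr::group_by(.data$community, .data$category) %>%
    dplyr::summarise(taxon_count = dplyr::n(),
                     cumulative = sum(.data$mean_rel), .groups = "drop") %>%
    dplyr::mutate(
      taxon_proportion = .data$taxon_count / total_det,
      cumulative_mean_abundance_pct = 100 * .data$cumulative / total_abund
    ) %>%
    dplyr::select("community", "category", "taxon_count",
                  "taxon_proportion", "cumulative_mean_abundance_pct")
  # report all three categories even when empty
  tidyr::complete(out, community = out$community[1],
                  category = CATEGORY_LEVELS,
                  fill = list(taxon_count = 0L, taxon_proportion = 0,
                              cumulative_mean_abundance_pct = 0)) %>%
    dplyr::mutate(category = factor(.data$category, CATEGORY_LEVELS)) %>%
    dplyr::arrange(.data$category)
}

#' Abundance-occupancy points for a community
#'
#' Pairs each detected taxon's mean relative abundance across the
#' community's samples (zeros included in the mean) with its occurrence
#' frequency; the input to [fit_abundance_occupancy()].
#'
#' @param tbl abundance table
#' @param profile occupancy profile of one community
#' @param samples the community's sample ids; `NULL` for all table samples
#' @return tibble with taxon_id, mean_abundance, frequency
#' @export
abundance_occupancy_points <- function(tbl, profile, samples = NULL) {
  if (is.null(samples)) samples <- attr(profile, "samples")
  if (is.null(samples)) samples <- sample_ids(tbl)
  rel <- abundance_matrix(relative_abundance(tbl[, c("taxon_id", samples)]))
  mean_rel <- rowMeans(rel)
  det <- profile[profile$detected, ]
  tibble::tibble(taxon_id = det$taxon_id,
                 mean_abundance = mean_rel[det$taxon_id],
                 frequency = det$frequency)
}

AO_FAMILIES <- c("linear", "logarithmic", "power", "exponential")

fit_one_family <- function(family, x, y) {
  res <- switch(
    family,
    linear = {
      fit <- stats::lm(y ~ x)
      list(params = c(a = unname(stats::coef(fit)[1]),
                      b = unname(stats::coef(fit)[2])),
           fitted = stats::fitted(fit))
    },
    logarithmic = {
      fit <- stats::lm(y ~ log(x))
      list(params = c(a = unname(stats::coef(fit)[1]),
                      b = unname(stats::coef(fit)[2])),
           fitted = stats::fitted(fit))
    },
    power = {
      pos <- y > 0
      if (sum(pos) < 3) stop("too few positive frequencies")
      start_fit <- stats::lm(log(y[pos]) ~ log(x[pos]))
      start <- list(a = exp(unname(stats::coef(start_fit)[1])),
                    b = unname(stats::coef(start_fit)[2]))
      fit <- minpack.lm::nlsLM(y ~ a * x^b, start = start,
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      list(params = c(a = unname(stats::coef(fit)["a"]),
                      b = unname(stats::coef(fit)["b"])),
           fitted = stats::fitted(fit))
    },
    exponential = {
      pos <- y > 0
      if (sum(pos) < 3) stop("too few positive frequencies")
      start_fit <- stats::lm(log(y[pos]) ~ x[pos])
      start <- list(a = exp(unname(stats::coef(start_fit)[1])),
                    b = unname(stats::coef(start_fit)[2]))
      fit <- minpack.lm::nlsLM(y ~ a * exp(b * x), start = start,
                               control = minpack.lm::nls.lm.control(maxiter = 200))
      list(params = c(a = unname(stats::coef(fit)["a"]),
                      b = unname(stats::coef(fit)["b"])),
           fitted = stats::fitted(fit))
    },
    stop("unknown family")
  )
  ss_res <- sum((y - res$fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot <= .Machine$double.eps) {
    if (ss_res <= 1e-12) 1 else -Inf
  } else {
    1 - ss_res / ss_tot
  }
  list(family = family, params = res$params, r_squared = r2,
       fitted = res$fitted)
}

#' Fit candidate abundance-occupancy models and select the best
#'
#' Fits each candidate family by least squares on the untransformed
#' frequency scale (nonlinear least squares for the power and exponential
#' families) and selects the family with the largest R-squared; exact ties
#' go to the simpler family (linear < logarithmic < power < exponential).
#' Candidates that fail to converge are dropped with a warning.
#'
#' Families: linear `y = a + b x`, logarithmic `y = a + b ln x`, power
#' `y = a x^b`, exponential `y = a exp(b x)`.
#'
#' @param points data frame with `mean_abundance` and `frequency` columns
#'   (e.g. from [abundance_occupancy_points()] or [simulate_ao_points()])
#' @param candidates subset of families to try
#' @param x_definition label recording which abundance statistic `x` is
#' @return an `ao_fit` object; see [tidy.ao_fit()], [glance.ao_fit()],
#'   [autoplot.ao_fit()]
#' @export
fit_abundance_occupancy <- function(points,
                                    candidates = AO_FAMILIES,
                                    x_definition = "mean relative abundance") {
  candidates <- match.arg(candidates, AO_FAMILIES, several.ok = TRUE)
  x <- points$mean_abundance
  y <- points$frequency
  if (length(x) < 3) {
    abort("need at least 3 points", class = "keytaxa_validation_error")
  }
  if (any(x <= 0)) {
    abort("abundances must be positive", class = "keytaxa_validation_error")
  }
  fits <- list()
  for (fam in candidates) {
    f <- tryCatch(fit_one_family(fam, x, y), error = function(e) {
      warn(paste0("candidate `", fam, "` failed to converge: ",
                  conditionMessage(e)))
      NULL
    })
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (length(fits) == 0) {
    abort("no candidate model could be fit", class = "keytaxa_fit_error")
  }
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  complexity <- match(names(fits), AO_FAMILIES)
  best <- names(fits)[order(-r2, complexity)][1]
  win <- fits[[best]]
  structure(
    list(model_family = win$family,
         params = win$params,
         r_squared = win$r_squared,
         n_points = length(x),
         x_definition = x_definition,
         candidates = tibble::tibble(
           family = names(fits),
           a = vapply(fits, function(f) f$params[["a"]], numeric(1)),
           b = vapply(fits, function(f) f$params[["b"]], numeric(1)),
           r_squared = r2
         ),
         data = tibble::tibble(mean_abundance = x, frequency = y)),
    class = "ao_fit"
  )
}

#' @export
print.ao_fit <- function(x, ...) {
  cat("Abundance-occupancy fit (", x$n_points, " taxa)\n", sep = "")
  cat("  best family: ", x$model_family,
      sprintf("  (a = %.4g, b = %.4g, R^2 = %.4f)\n",
              x$params[["a"]], x$params[["b"]], x$r_squared), sep = "")
  invisible(x)
}

#' Tidy an abundance-occupancy fit
#'
#' @param x an `ao_fit`
#' @param ... unused
#' @return one row per candidate family with parameters and R-squared;
#'   the selected family is flagged
#' @export
tidy.ao_fit <- function(x, ...) {
  dplyr::mutate(x$candidates, selected = .data$family == x$model_family)
}

#' One-row summary of an abundance-occupancy fit
#'
#' @param x an `ao_fit`
#' @param ... unused
#' @export
glance.ao_fit <- function(x, ...) {
  tibble::tibble(model_family = x$model_family,
                 a = x$params[["a"]], b = x$params[["b"]],
                 r_squared = x$r_squared, n_points = x$n_points,
                 x_definition = x$x_definition)
}

ao_predict <- function(family, params, x) {
  a <- params[["a"]]; b <- params[["b"]]
  switch(family,
         linear = a + b * x,
         logarithmic = a + b * log(x),
         power = a * x^b,
         exponential = a * exp(b * x))
}

#' Plot an abundance-occupancy fit
#'
#' @param object an `ao_fit`
#' @param ... unused
#' @return ggplot of the points with the selected curve
#' @export
autoplot.ao_fit <- function(object, ...) {
  grid <- tibble::tibble(
    mean_abundance = exp(seq(log(min(object$data$mean_abundance)),
                             log(max(object$data$mean_abundance)),
                             length.out = 200))
  )
  grid$frequency <- ao_predict(object$model_family, object$params,
                               grid$mean_abundance)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$mean_abundance, .data$frequency)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean relative abundance",
                  y = "occurrence frequency",
                  title = paste0("Best fit: ", object$model_family,
                                 sprintf(" (R² = %.3f)",
                                         object$r_squared))) +
    ggplot2::theme_minimal()
}

#' Plot category summaries across communities
#'
#' @param summaries row-bound output of [category_summary()]
#' @return stacked bar chart of cumulative mean abundance per category
#' @export
plot_category_summary <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(.data$community,
                               .data$cumulative_mean_abundance_pct,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "cumulative mean relative abundance (%)",
                  fill = "category") +
    ggplot2::theme_minimal()
}
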