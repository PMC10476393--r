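#' Configuration for the synthetic gut-community generator
#'
#' Builds the configuration consumed by [simulate_dataset()]. Defaults encode
#' the study design the workflow targets: four communities (CD and healthy
#' feces, uninflamed and inflamed mucosa) with sample sizes 38/14/23/22, a
#' lognormal taxon mean-abundance distribution, an exponential link between
#' mean abundance and occupancy probability, compositional counts at a
#' negative-binomial sequencing depth, a block of taxa whose occurrence
#' separates the two fecal groups, three planted co-occurrence modules, and
#' clinical traits linearly coupled to the module latent factors.
#'
#' @param seed integer seed controlling all randomness
#' @param group_sizes named integer vector, samples per group
#' @param n_taxa number of taxa
#' @param abundance_logmean_sd mean and sd (natural-log scale) of the
#'   lognormal draw of true mean relative abundances
#' @param occupancy_link `c(a, b)`: occupancy probability is
#'   `min(1, a * exp(b * log10(mean abundance)))`
#' @param depth `c(mean, dispersion)` of the negative-binomial sequencing
#'   depth per sample (dispersion is the NB `size` parameter)
#' @param within_sd sd of per-sample lognormal abundance noise (natural log)
#' @param planted_discriminative data frame with a `taxon` index column and
#'   one column per group giving that group's presence probability; `NULL`
#'   for none
#' @param planted_modules list of `list(members =, factor_sd =, loading =)`
#'   describing co-occurring taxon blocks; member sets must be disjoint
#' @param trait_coupling list of `list(trait =, module =, coefficient =,
#'   noise_sd =)`; traits listed in `extra_traits` are generated as pure
#'   noise
#' @param extra_traits character vector of uncoupled trait names
#' @return a `sim_config` list
#' @export
simulation_config <- function(seed = 1,
                              group_sizes = c(CD_F = 38, HC_F = 14,
                                              Uinf_M = 23, Inf_M = 22),
                              n_taxa = 300,
                              abundance_logmean_sd = c(0, 2),
                              occupancy_link = c(a = 3, b = 0.7),
                              depth = c(mean = 20000, dispersion = 10),
                              within_sd = 1,
                              planted_discriminative = default_discriminative(),
                              planted_modules = default_modules(n_taxa),
                              trait_coupling = default_trait_coupling(),
                              extra_traits = c("CC4", "glucose", "bas_ratio")) {
  if (missing(trait_coupling) && length(planted_modules) == 0) {
    trait_coupling <- list()
  }
  cfg <- list(seed = seed, group_sizes = group_sizes, n_taxa = n_taxa,
              abundance_logmean_sd = abundance_logmean_sd,
              occupancy_link = occupancy_link, depth = depth,
              within_sd = within_sd,
              planted_discriminative = planted_discriminative,
              planted_modules = planted_modules,
              trait_coupling = trait_coupling,
              extra_traits = extra_traits)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname simulation_config
#' @export
default_discriminative <- function() {
  # ten taxa nearly absent from CD feces but prevalent in healthy feces,
  # intermediate on the mucosa
  tibble::tibble(taxon = 1:10, CD_F = 0.05, HC_F = 0.9,
                 Uinf_M = 0.3, Inf_M = 0.3)
}

#' @rdname simulation_config
#' @export
default_modules <- function(n_taxa = 300) {
  if (n_taxa < 130) return(list())
  list(
    list(members = 21:60,  factor_sd = 1, loading = 1),
    list(members = 61:95,  factor_sd = 1, loading = 1),
    list(members = 96:125, factor_sd = 1, loading = 1)
  )
}

#' @rdname simulation_config
#' @export
default_trait_coupling <- function() {
  list(
    list(trait = "monocytes", module = 1, coefficient = 0.9, noise_sd = 0.4),
    list(trait = "CRP",       module = 2, coefficient = 0.9, noise_sd = 0.4),
    list(trait = "CC3",       module = 3, coefficient = 0.9, noise_sd = 0.4)
  )
}

validate_sim_config <- function(cfg) {
  if (any(cfg$group_sizes < 2)) {
    abort("all group sizes must be >= 2", class = "keytaxa_config_error")
  }
  if (cfg$n_taxa < 0) {
    abort("n_taxa must be non-negative", class = "keytaxa_config_error")
  }
  pd <- cfg$planted_discriminative
  if (!is.null(pd) && nrow(pd) > 0) {
    probs <- as.matrix(pd[, setdiff(names(pd), "taxon"), drop = FALSE])
    if (any(probs < 0 | probs > 1)) {
      abort("presence probabilities must lie in [0, 1]",
            class = "keytaxa_config_error")
    }
    if (any(pd$taxon < 1 | pd$taxon > max(cfg$n_taxa, 1))) {
      abort("planted_discriminative taxon index out of range",
            class = "keytaxa_config_error")
    }
  }
  members <- unlist(lapply(cfg$planted_modules, `[[`, "members"))
  if (anyDuplicated(members)) {
    abort("planted module member sets must be disjoint",
          class = "keytaxa_config_error")
  }
  if (length(members) > 0 && max(members) > cfg$n_taxa) {
    abort("planted module member index out of range",
          class = "keytaxa_config_error")
  }
  for (tc in cfg$trait_coupling) {
    if (tc$module < 1 || tc$module > max(length(cfg$planted_modules), 0)) {
      abort(paste0("trait `", tc$trait, "` couples to unknown module ",
                   tc$module),
            class = "keytaxa_config_error")
    }
  }
  invisible(cfg)
}

#' Simulate a synthetic gut microbiome dataset with ground truth
#'
#' Draws true mean relative abundances lognormally, converts them to
#' occupancy probabilities through the exponential abundance-occupancy link,
#' realises per-sample presence and lognormal conditional abundances, adds
#' shared latent factors to planted module members, and converts each sample
#' to counts by a multinomial draw at its negative-binomial depth (so counts
#' are compositional and column sums equal the drawn depths exactly).
#' Clinical traits are linear functions of module latent factors plus noise.
#'
#' @param cfg a `sim_config` from [simulation_config()]
#' @return list with `table` (count abundance table), `metadata`
#'   (sample_id, group, traits), `truth` (per-taxon true mean abundance,
#'   occupancy probability, category, module label, discriminative flag),
#'   and `latent` (module latent factors per sample, for diagnostics)
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  n_s <- length(groups)
  sample_names <- paste0(groups, "_", unlist(lapply(cfg$group_sizes, seq_len)))
  taxa <- sprintf("T%03d", seq_len(cfg$n_taxa))

  if (cfg$n_taxa == 0) {
    tbl <- tibble::tibble(taxon_id = character(0))
    for (s in sample_names) tbl[[s]] <- numeric(0)
    return(list(table = tbl,
                metadata = tibble::tibble(sample_id = sample_names,
                                          group = groups),
                truth = tibble::tibble(taxon_id = character(0),
                                       true_mean_abundance = numeric(0),
                                       true_occupancy = numeric(0),
                                       true_category = character(0),
                                       true_module = integer(0),
                                       discriminative = logical(0)),
                latent = NULL))
  }

  m_raw <- exp(stats::rnorm(cfg$n_taxa, cfg$abundance_logmean_sd[1],
                            cfg$abundance_logmean_sd[2]))
  pd <- cfg$planted_discriminative
  if (!is.null(pd) && nrow(pd) > 0) {
    # planted taxa carry their signal through occurrence, not rarity: give
    # them at least median abundance so presence survives the count draw
    m_raw[pd$taxon] <- pmax(m_raw[pd$taxon], stats::median(m_raw))
  }
  mod_members <- unlist(lapply(cfg$planted_modules, `[[`, "members"))
  if (length(mod_members) > 0) {
    # module members are core taxa: co-abundance, not patchy occurrence,
    # is the structure being planted, so they are kept detectable
    m_raw[mod_members] <- pmax(m_raw[mod_members], stats::median(m_raw))
  }
  m <- m_raw / sum(m_raw)
  a <- cfg$occupancy_link[[1]]
  b <- cfg$occupancy_link[[2]]
  occ <- pmin(1, pmax(0, a * exp(b * log10(m))))

  # presence probability per taxon x group (planted overrides)
  pres_prob <- matrix(occ, nrow = cfg$n_taxa, ncol = length(cfg$group_sizes),
                      dimnames = list(taxa, names(cfg$group_sizes)))
  disc <- rep(FALSE, cfg$n_taxa)
  if (!is.null(pd) && nrow(pd) > 0) {
    disc[pd$taxon] <- TRUE
    for (g in intersect(names(pd), colnames(pres_prob))) {
      pres_prob[pd$taxon, g] <- pd[[g]]
    }
  }
  if (length(mod_members) > 0) pres_prob[mod_members, ] <- 1

  module_of <- rep(0L, cfg$n_taxa)
  for (k in seq_along(cfg$planted_modules)) {
    module_of[cfg$planted_modules[[k]]$members] <- k
  }

  n_mod <- length(cfg$planted_modules)
  latent <- if (n_mod > 0) {
    matrix(stats::rnorm(n_mod * n_s), nrow = n_mod,
           dimnames = list(NULL, sample_names))
  } else NULL
  if (!is.null(latent)) {
    for (k in seq_len(n_mod)) {
      latent[k, ] <- latent[k, ] * cfg$planted_modules[[k]]$factor_sd
    }
  }

  depths <- stats::rnbinom(n_s, size = cfg$depth[[2]], mu = cfg$depth[[1]])
  depths <- pmax(depths, 100L)

  counts <- matrix(0L, nrow = cfg$n_taxa, ncol = n_s,
                   dimnames = list(taxa, sample_names))
  for (s in seq_len(n_s)) {
    g <- groups[s]
    z <- stats::rbinom(cfg$n_taxa, 1, pres_prob[, g])
    logw <- log(m) + stats::rnorm(cfg$n_taxa, 0, cfg$within_sd)
    if (n_mod > 0) {
      for (k in seq_len(n_mod)) {
        mem <- cfg$planted_modules[[k]]$members
        logw[mem] <- logw[mem] +
          cfg$planted_modules[[k]]$loading * latent[k, s]
      }
    }
    w <- z * exp(logw)
    if (sum(w) == 0) w[which.max(m)] <- m[which.max(m)]
    counts[, s] <- stats::rmultinom(1, depths[s], w)[, 1]
  }

  tbl <- tibble::as_tibble(counts, rownames = "taxon_id")

  meta <- tibble::tibble(sample_id = sample_names, group = groups)
  for (tc in cfg$trait_coupling) {
    meta[[tc$trait]] <- tc$coefficient * latent[tc$module, ] +
      stats::rnorm(n_s, 0, tc$noise_sd)
  }
  for (tr in cfg$extra_traits) {
    meta[[tr]] <- stats::rnorm(n_s)
  }

  truth <- tibble::tibble(
    taxon_id = taxa,
    true_mean_abundance = m,
    true_occupancy = occ,
    true_category = assign_category(occ),
    true_module = module_of,
    discriminative = disc
  )
  list(table = tbl, metadata = meta, truth = truth, latent = latent)
}

#' Simulate abundance-occupancy point sets
#'
#' Generates `(mean abundance, occurrence frequency)` pairs on an exponential
#' curve `y = a * exp(b * x)` (clipped to `[0, 1]`) with Gaussian noise, the
#' setting in which the model-fitting stage is benchmarked. Abundances are
#' drawn log-uniformly over `x_range`.
#'
#' @param a,b curve parameters
#' @param n number of points (at least 3)
#' @param noise_sd Gaussian noise sd added to the frequency
#' @param seed integer seed
#' @param x_range abundance range (log-uniform draw)
#' @return tibble with `mean_abundance` and `frequency`
#' @export
simulate_ao_points <- function(a, b, n, noise_sd = 0, seed = 1,
                               x_range = c(1e-4, 0.06)) {
  if (noise_sd < 0) {
    abort("noise_sd must be non-negative", class = "keytaxa_config_error")
  }
  if (n < 3) {
    abort("need at least 3 points", class = "keytaxa_config_error")
  }
  set.seed(seed)
  x <- 10^stats::runif(n, log10(x_range[1]), log10(x_range[2]))
  y <- pmin(pmax(a * exp(b * x), 0), 1) + stats::rnorm(n, 0, noise_sd)
  tibble::tibble(mean_abundance = x, frequency = y)
}

#' Simulate block-structured abundance-like profiles
#'
#' Latent-factor Gaussian blocks: taxa in the same block share a block
#' factor, all taxa share a global factor, so the expected pairwise
#' correlation is `within_cor` inside a block and `between_cor` across
#' blocks. Used to benchmark module detection.
#'
#' @param block_sizes integer vector of block sizes
#' @param within_cor expected correlation within a block
#' @param between_cor expected correlation across blocks
#'   (`0 <= between_cor < within_cor <= 1`)
#' @param n_samples number of samples
#' @param seed integer seed
#' @return list with `profiles` (taxa x samples matrix) and `labels`
#'   (integer block label per taxon)
#' @export
simulate_module_network <- function(block_sizes, within_cor, between_cor,
                                    n_samples, seed = 1) {
  if (length(block_sizes) == 0) {
    abort("block_sizes must be non-empty", class = "keytaxa_config_error")
  }
  if (!(between_cor >= 0 && between_cor < within_cor && within_cor <= 1)) {
    abort("need 0 <= between_cor < within_cor <= 1",
          class = "keytaxa_config_error")
  }
  set.seed(seed)
  n_taxa <- sum(block_sizes)
  labels <- rep(seq_along(block_sizes), block_sizes)
  g <- stats::rnorm(n_samples)
  f <- matrix(stats::rnorm(length(block_sizes) * n_samples),
              nrow = length(block_sizes))
  profiles <- matrix(0, nrow = n_taxa, ncol = n_samples,
                     dimnames = list(sprintf("T%03d", seq_len(n_taxa)),
                                     sprintf("S%03d", seq_len(n_samples))))
  for (i in seq_len(n_taxa)) {
    k <- labels[i]
    profiles[i, ] <- sqrt(between_cor) * g +
      sqrt(within_cor - between_cor) * f[k, ] +
      sqrt(1 - within_cor) * stats::rnorm(n_samples)
  }
  list(profiles = profiles, labels = labels)
}

#' Write a simulated dataset to TSV files
#'
#' @param sim result of [simulate_dataset()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(table = file.path(dir, "abundance.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_abundance_table(sim$table, paths["table"])
  readr::write_tsv(sim$metadata, paths["metadata"], progress = FALSE)
  readr::write_tsv(sim$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}
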