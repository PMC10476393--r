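# small in-code fixtures shared across tests

tiny_table <- function() {
  tibble::tibble(
    taxon_id = c("taxA", "taxB", "taxC"),
    s1 = c(2, 1, 1),
    s2 = c(0, 3, 1),
    s3 = c(5, 0, 0),
    s4 = c(1, 1, 2)
  )
}

lineage_table <- function() {
  tibble::tibble(
    taxon_id = c("asv1", "asv2", "asv3", "asv4", "asv5"),
    lineage = c(
      "d__Bacteria; p__Firmicutes; c__Clostridia; o__Lachnospirales; f__Lachnospiraceae; g__Blautia",
      "d__Bacteria; p__Firmicutes; c__Clostridia; o__Lachnospirales; f__Lachnospiraceae; g__Blautia",
      "d__Bacteria",
      "",
      "d__Bacteria; p__Firmicutes; c__Clostridia; o__Christensenellales; f__Christensenellaceae"
    ),
    s1 = c(1, 2, 3, 4, 5),
    s2 = c(5, 4, 3, 2, 1)
  )
}

# reference occurrence counts for ten key genera of a Crohn's/control gut
# cohort, across the four communities (n = 38, 14, 23, 22)
keygenus_counts <- function() {
  tibble::tribble(
    ~genus, ~CD_F, ~HC_F, ~Uinf_M, ~Inf_M,
    "Escherichia-Shigella", 38, 12, 21, 19,
    "Prevotella", 9, 9, 12, 10,
    "Faecalibacterium", 20, 14, 20, 14,
    "Roseburia", 6, 12, 4, 9,
    "Subdoligranulum", 9, 12, 10, 8,
    "Ruminococcus", 2, 11, 3, 4,
    "[Eubacterium]_coprostanoligenes_group", 4, 12, 3, 4,
    "UCG-002", 4, 11, 8, 9,
    "Lachnospira", 7, 12, 4, 5,
    "Christensenellaceae_R-7_group", 2, 10, 3, 4
  )
}

keygenus_group_sizes <- function() {
  c(CD_F = 38L, HC_F = 14L, Uinf_M = 23L, Inf_M = 22L)
}

# presence/absence abundance table realizing those counts exactly:
# each genus is present (value 1) in the first n_present samples of each
# community
keygenus_fixture <- function() {
  counts <- keygenus_counts()
  sizes <- keygenus_group_sizes()
  samples <- unlist(lapply(names(sizes),
                           function(g) paste0(g, "_", seq_len(sizes[g]))))
  tbl <- tibble::tibble(taxon_id = counts$genus)
  for (g in names(sizes)) {
    for (i in seq_len(sizes[g])) {
      col <- paste0(g, "_", i)
      tbl[[col]] <- as.numeric(i <= counts[[g]])
    }
  }
  communities <- lapply(names(sizes),
                        function(g) paste0(g, "_", seq_len(sizes[g])))
  names(communities) <- names(sizes)
  list(table = tbl, communities = communities)
}

# brute-force topological overlap, straight from the definition
tom_oracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# brute-force Bray-Curtis
bray_oracle <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(abs(m[, i] - m[, j])) / sum(m[, i] + m[, j])
    }
  }
  d
}

random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("T%02d", 1:n), sprintf("T%02d", 1:n))
  a
}
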