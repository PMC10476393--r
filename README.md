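# keytaxa

Abundance alone misses half the story of gut-microbiome dysbiosis: a genus
can matter not because its abundance shifts but because it stops *occurring*
in patients while remaining near-universal in healthy controls. `keytaxa` is
an R package for finding such key taxa in 16S feature tables. It integrates
four views of a taxon-by-sample table:

1. **Occurrence frequency and ecological categories.** Within a community
   (e.g. patient feces, control feces, inflamed/uninflamed mucosa), each
   taxon's occurrence frequency is the fraction of samples where it is
   detected. Taxa are classified as **persistent** (frequency ≥ 75%),
   **intermittent** (25–75%, exclusive) or **transient** (≤ 25%), and the
   relationship between mean relative abundance x̄ and occurrence frequency
   F is fit by least squares over four candidate families — linear
   `F = a + b·x̄`, logarithmic `F = a + b·ln x̄`, power `F = a·x̄^b` and
   exponential `F = a·e^{b·x̄}` — selecting the family with maximal R².
2. **Community statistics.** Shannon diversity, Bray–Curtis distances,
   global and pairwise PERMANOVA (permutation p-values with the +1
   correction), per-taxon two-sided Welch tests with a minimum effect-size
   filter, Kruskal–Wallis, and Spearman correlation with a permutation
   significance test.
3. **Random-forest classification.** A two-group classifier tuned entirely
   by out-of-bag (OOB) error: `mtry` by lowest average OOB error over
   repeated fits, `ntree` as the smallest tree count at which the OOB curve
   has stabilised. Taxa are ranked by OOB-permutation importance
   (MeanDecreaseAccuracy) alongside MeanDecreaseGini.
4. **Weighted co-occurrence networks.** Adjacency `a_ij = |cor_ij|^β`
   (soft power β, default 10), topological overlap
   `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`, average-linkage
   tree cut into modules (minimum size 30 by default, smaller clusters
   pooled into grey), module eigengenes (first singular vector), eigengene
   correlation with clinical traits (CRP, monocytes, complement C3/C4, …),
   intramodular connectivity kWithin, and hub identification.

The integration product is a ranked key-taxa report: the classifier's top
taxa annotated with per-community occurrence, ecological category, module
color, significant module–trait links, and a diagnostic-candidate flag for
taxa rare in cases (frequency ≤ 0.15) but common in controls (≥ 0.70).

Because every stage needs data with known structure to be testable, the
package ships a synthetic-data generator (`simulate_dataset()`) producing
compositional count tables with a lognormal abundance distribution, an
exponential abundance–occupancy link, planted between-group occurrence
differences, planted co-occurring taxon blocks, traits coupled to the block
latent factors — and the ground truth for all of it.

## Worked example

```r
library(keytaxa)

sim <- simulate_dataset(simulation_config(seed = 42))
run <- run_pipeline(pipeline_config(
  table = sim$table, metadata = sim$metadata,
  output_dir = "demo_run",
  network = list(beta = 6, min_module_size = 10),
  permutations = 199, seed = 42))

glance(run$occupancy$ao_fit)
#> # A tibble: 1 × 6
#>   model_family     a     b r_squared n_points x_definition
#> 1 logarithmic   1.51 0.125     0.654      296 mean relative abundance

glance(run$rf_classifier)
#> # A tibble: 1 × 5
#>    mtry ntree oob_error n_features classes
#> 1    34   100         0        300 CD_F/HC_F

run$integration_report[1:5, c("taxon_id", "mean_decrease_accuracy",
                              "frequency_CD_F", "frequency_HC_F",
                              "category_CD_F", "diagnostic")]
#> # A tibble: 5 × 6
#>   taxon_id mean_decrease_accuracy frequency_CD_F frequency_HC_F category_CD_F diagnostic
#> 1 T003                     0.0515         0.0263          0.929 transient     TRUE
#> 2 T001                     0.0351         0.0526          0.929 transient     TRUE
#> 3 T007                     0.0331         0.0789          1     transient     TRUE
#> 4 T006                     0.0328         0               0.857 transient     TRUE
#> 5 T002                     0.0246         0               0.786 transient     TRUE
```

Reading the output: the classifier separates the two fecal groups with 0%
OOB error, and its top-ranked taxa are exactly the planted discriminative
taxa (T001–T010) — rare or absent in the case community but present in
more than three quarters of controls, hence flagged as diagnostic
candidates. On this dataset's pooled abundance–occupancy cloud the
logarithmic family wins model selection (R² = 0.65); on point sets
generated directly from an exponential law the exponential family is
selected and both parameters are recovered (see the tests and acceptance
script). Each `run$<stage>` object has `tidy()` / `glance()` /
`autoplot()` methods, and every stage's table is also written as TSV under
`output_dir` with a JSON manifest.

Individual stages compose with pipes:

```r
prof <- occurrence_frequency(sim$table, community = "all")
category_summary(sim$table, prof)
abundance_occupancy_points(sim$table, prof) |> fit_abundance_occupancy()
```

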