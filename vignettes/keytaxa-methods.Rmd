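---
title: "Methods: occurrence, networks, and key-taxon integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: occurrence, networks, and key-taxon integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keytaxa)
```

`keytaxa` identifies key gut bacteria by cross-referencing four signals
computed from one taxon-by-sample table: occurrence frequency (with
ecological categories), the abundance–occupancy relationship,
random-forest feature importance, and membership in co-occurrence network
modules correlated with clinical traits. This vignette records the models,
the parameters that matter, the numerical choices, and what the synthetic
benchmark does and does not demonstrate.

## Ecological categories and the abundance–occupancy model

Within a community of $n$ samples, a taxon is *detected* in a sample when
its value is strictly positive — no abundance threshold is applied, and no
prevalence filter is applied by default, since detection thresholds are a
property of the upstream bioinformatics, not of this analysis. Occurrence
frequency is $F = n_\text{present}/n$, computed exactly as a ratio of
counts. Categories follow the core/satellite tradition:

* **persistent**: $F \ge 0.75$
* **transient**: $F \le 0.25$
* **intermittent**: strictly between

Both outer boundaries are inclusive; the intermittent band is open. The
boundaries are arguments (`persistent_min`, `transient_max`) wherever they
are used. Taxa absent from *every* sample of a community are flagged
undetected and excluded from that community's summaries and fits — a
frequency-zero taxon is not a member of the community, and counting it
would deflate the category proportions.

Category summaries report, per category, the taxon count, the proportion
of all detected taxa, and the *cumulative mean relative abundance*: the
sum over member taxa of their mean relative abundance across the
community's samples (zeros included), expressed in percent. Proportions
sum to 1 and cumulative abundances to 100% by construction (tested to
1e-9 and 1e-6). An abundance-weighted alternative was considered and
rejected: summing per-taxon means keeps the three category bars exactly
decomposable into taxon contributions.

The abundance–occupancy relationship is fit on pairs
$(\bar{x}_i, F_i)$ where $\bar{x}_i$ is the taxon's mean relative
abundance in the community — the mean includes zeros, so rare-but-present
taxa are not inflated. Four candidate families are fit by least squares
*on the untransformed frequency scale* (`minpack.lm::nlsLM` for the power
and exponential families, started from log-scale linear fits):

| family | model | parameters |
|---|---|---|
| linear | $F = a + b\bar{x}$ | intercept, slope |
| logarithmic | $F = a + b\ln\bar{x}$ | intercept, slope |
| power | $F = a\bar{x}^{\,b}$ | scale, exponent |
| exponential | $F = a e^{b\bar{x}}$ | scale, rate |

$R^2 = 1 - SS_\text{res}/SS_\text{tot}$ is computed on the same
untransformed scale for all families so the comparison is fair; the
winner is the family with maximal $R^2$, with exact ties going to the
simpler family in the order linear < logarithmic < power < exponential.
Fitting on the frequency scale (rather than log-transforming) matters:
log-scale least squares would weight rare taxa heavily and silently
change the selected family. A constant-frequency input has
$SS_\text{tot}=0$; every family fits it perfectly and the tie-break
returns the linear family with slope 0. Candidates that fail to converge
are dropped with a warning; only if all fail is an error raised.

## Community statistics

Shannon diversity, Bray–Curtis distance and PERMANOVA are delegated to
`vegan` (`diversity`, `vegdist`, `adonis2`); Welch and Kruskal–Wallis
tests to `stats`. Permutation p-values always use the +1 correction,
$p = (\#\{T_\text{perm} \ge T_\text{obs}\} + 1)/(B + 1)$, so $p \ge
1/(B+1)$ and the test is valid at any $B$. Pairwise PERMANOVA p-values
are Benjamini–Hochberg adjusted by default.

Per-taxon Welch tests run on relative abundances and report a taxon only
when $p \le 0.05$ **and** the absolute between-group mean difference
exceeds 0.1% (0.001 on the relative-abundance scale, configurable) — a
pure significance criterion would flood the report with statistically
detectable but biologically negligible shifts. Taxa with zero variance in
both groups are flagged untestable rather than given a fabricated p.

The permutation Spearman test (`spearman_perm`) computes $\rho$ on
average ranks and permutes one margin $B = 999$ times by default. The
reportable rule is joint: $p \le 0.05$ *and* $|\rho| \ge 0.5$. The
magnitude threshold is deliberately a lower bound — selecting
*weak* correlations would contradict the purpose of the screen — and both
thresholds are arguments.

## Random-forest classifier

Classification is binary (case vs control feces; inflamed vs uninflamed
mucosa), via `randomForest`. Both hyperparameters are chosen by OOB
error, which needs no held-out data:

* `mtry`: for each candidate in the grid
  $\{\lfloor\sqrt p\rfloor/2, \lfloor\sqrt p\rfloor, 2\lfloor\sqrt
  p\rfloor, p/3\}$ (clipped to $[1, p]$), the OOB error at the largest
  scheduled tree count is averaged over 5 refits; the argmin wins, ties
  to the smaller value (cheaper, less variance-prone).
* `ntree`: the smallest scheduled count whose OOB error is within
  `stability_epsilon` (default 0.01) of the error at the full schedule —
  the point where adding trees stops changing the estimate.

Importance is the classical pair: MeanDecreaseAccuracy (per-tree OOB
permutation, unscaled so that values are in accuracy units and a
pure-noise feature sits at 0) and MeanDecreaseGini. The final model is
refit at the chosen values under a fixed seed, so the whole procedure is
deterministic given data and seed.

## Co-occurrence modules

The network stage is authored in this package on top of base R
clustering and SVD primitives, following the weighted-correlation-network
tradition:

1. **Outlier screening.** Samples are clustered by average linkage on
   Euclidean distances of standardized profiles. The cut sits at the
   0.99 quantile of merge heights, *floored at twice the median merge
   height*: a bare quantile always severs the top merges, so homogeneous
   data would always lose a sample. Everything outside the largest
   cluster is removed; removing more than 25% of samples aborts with a
   request for manual review.
2. **Adjacency.** Unsigned: $a_{ij} = |\mathrm{cor}_{ij}|^\beta$ with
   Pearson correlation on standardized relative abundances by default
   (Spearman available). Unsigned is the right default here because hub
   taxa are reported through positive associations and no sign
   convention is imposed on the input. The default $\beta = 10$ reflects
   the operating point for genus-level tables of this kind;
   `soft_power_scan()` reports scale-free fit $R^2$ and slope per power
   (log–log regression over 10 equal-width connectivity bins) and
   recommends the smallest power reaching $R^2 \ge 0.8$ with negative
   slope.
3. **Topological overlap.**
   $\mathrm{TOM}_{ij} = (l_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 -
   a_{ij})$ with $l_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj}$, diagonal 1,
   implemented with a single matrix product and verified against a
   triple-loop oracle to 1e-12.
4. **Tree cut.** Average-linkage clustering of $1-\mathrm{TOM}$, cut at
   a fixed quantile of the tree's merge heights (default 0.95), with
   clusters smaller than `min_module_size` (default 30) pooled into
   grey. This is a deterministic, seedless simplification of dynamic
   hybrid tree cutting: fully specifiable, hence fully testable. The
   0.95 default was set by examining where block-joining merges sit in
   dendrograms of latent-block data embedded in a realistic background
   of uncorrelated taxa — the top few percent of merges join true
   modules to each other, so the cut must fall just below them; 0.99
   separates only clean block-structured matrices, while 0.95 also
   resolves modules embedded in full tables. The cut height is floored
   at 0.05 absolute dissimilarity so that a table of near-identical
   profiles forms one module instead of being split at a quantile of
   noise-level heights.
5. **Eigengenes.** First right-singular vector across samples of the
   module's standardized taxon matrix, sign-oriented so its mean
   correlation with member profiles is non-negative (making results
   invariant to global sign flips); variance explained is
   $d_1^2/\sum d_k^2$.
6. **Module–trait correlation.** Pearson by default, pairwise-complete,
   two-sided p, at least 4 complete pairs; constant traits are flagged
   untestable. P-values are unadjusted by default (BH is available):
   with a handful of modules and traits the screen is exploratory and
   adjustment choices belong to the caller.
7. **Connectivity.** $k^\text{total}_i = \sum_j a_{ij}$,
   $k^\text{within}_i$ over same-module neighbours; each non-grey
   module's hub is the member with maximal $k^\text{within}$, ties
   broken by lexicographically smallest taxon id so reruns are
   reproducible.

Module colors follow the canonical size-ordered palette (turquoise,
blue, brown, yellow, green, red, black, pink, …) with grey reserved for
unassigned taxa. Module merging by eigengene similarity is deliberately
out of scope.

## Integration and diagnostic candidates

`build_key_taxa_report()` takes the classifier's top `top_k` taxa
(sorted by MeanDecreaseAccuracy) and annotates each with occurrence
frequency and category in every community, module membership, and — via
`attach_clinical_links()` — its module's trait correlations at
$p \le 0.05$. Grey taxa inherit no links. A taxon undetected in some
community appears there at frequency 0 (hence transient), because the
report's contract is one row per taxon with every community represented.

`flag_diagnostic_candidates()` encodes the verbal pattern "rare in
cases, common in controls" as
$F_\text{case} \le 0.15 \land F_\text{control} \ge 0.70$. The defaults separate
the two regimes cleanly: on the reference occurrence fixture used in the
test suite (ten key genera across four gut communities), the rule flags
exactly the four genera showing the rare-in-cases, common-in-controls
pattern. Both thresholds are exposed and the flag is monotone in each.

## The synthetic generator: what it emulates, what it does not

`simulate_dataset()` generates the study conditions the workflow
targets: four communities with sample sizes 38 (case feces), 14 (control
feces), 23 (uninflamed mucosa), 22 (inflamed mucosa); 300 taxa with
lognormal true mean abundances ($\sigma_{\ln} = 2$, spanning roughly
four orders of magnitude); occupancy probabilities
$\min(1, a\,e^{b\log_{10}\bar{x}})$ with $a = 3$, $b = 0.7$, giving a
realistic spread of rare-to-universal taxa; per-sample lognormal
conditional abundances ($\sigma_{\ln} = 1$); counts drawn
multinomially at a negative-binomial depth (mean 20000, size 10), so
the data are compositional and column sums equal the drawn depths
exactly.

Planted structure, with full ground truth returned:

* **Discriminative taxa** (defaults: taxa 1–10) have their presence
  probability overridden per group — 0.05 in case feces, 0.9 in control
  feces, 0.3 on the mucosa. Their mean abundances are floored at the
  panel median: their signal is *occurrence*, and a taxon in the deep
  abundance tail cannot realize a 0.9 presence at finite sequencing
  depth (its counts round to zero), which would turn a planted
  occurrence contrast into a depth artifact.
* **Co-occurrence modules** (defaults: three blocks of 40/35/30 taxa)
  share a per-sample latent factor added to member log-abundances with
  loading 1. Members are treated as core taxa — presence probability 1
  and abundance floored at the median — because the planted structure is
  *co-abundance*; random absences would mask the latent correlation with
  zeros. Loading 1 puts realized raw-scale pairwise correlations in a
  moderate, realistic range; larger loadings make module members swing
  so much of the multinomial total that closure induces spurious
  anti-correlations between *other* modules and the coupled traits.
* **Traits**: monocytes, CRP and CC3 are `0.9·latent + N(0, 0.4)` on
  modules 1–3; CC4, glucose and bas_ratio are pure noise.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: phylogenetic correlation among
taxa, overdispersed zero inflation beyond the occupancy link, batch and
library-preparation effects, taxa whose abundance (not occurrence)
carries the group signal, and any relationship between the mucosal and
fecal communities of the same subject. Benchmarks on this generator
demonstrate correctness of the machinery under the stated statistical
structure, not clinical validity.

## Numerical choices and degenerate inputs

* Relative-abundance columns must sum to 1 within 1e-9; write→read
  round-trips preserve values to 1e-12; an all-zero sample is an error
  naming the sample (its composition is undefined).
* Collapse to a coarser rank conserves per-sample totals to 1e-9. Taxa
  unnamed at the requested rank are labelled by their finest named
  coarser rank prefixed with the rank letter (`d_Bacteria`,
  `f_Christensenellaceae`); fully unannotated lineages become
  `Unassigned`. This reproduces the pseudo-taxa that genus-level gut
  surveys report.
* TOM is validated against the brute-force definition to 1e-12; its
  input must be symmetric with entries in [0, 1].
* All permutation tests are seeded; identical seeds give identical
  results, and the pipeline derives per-stage seeds from one global seed
  by hashing stage names, so stages can be rerun in isolation.
* The pipeline manifest records the configuration hash, seed, package
  version and per-stage row counts; reruns under the same configuration
  are byte-identical.

## Problem sizes in the test suite

The suite exercises the workflow at sizes where each property is
sharply testable: the occupancy-convergence check uses a 30-taxon panel
at depth $10^5$ over 200 samples — at that depth detection is certain
for the taxa kept (expected reads ≥ 10), so the only error term is
binomial presence sampling, whose expected maximum over a 30-taxon panel
stays under the 0.08 bound, while panels of 150+ taxa would exceed it on
sampling error alone. Module recovery uses three 40-taxon blocks
(within-correlation 0.8) over 60 samples at $\beta = 6$; null
calibration of the permutation tests uses 500 replicates at $B = 199$;
classifier benchmarks run at the study's fecal sample sizes (38 vs 14).
The complete suite runs in about a minute on one CPU.

## Known limitations

* The tree cut is a static-height simplification; branch-shape-aware
  dynamic cutting can recover nested modules that a single height
  misses.
* Unsigned networks conflate positive and negative co-occurrence;
  signed topologies are not implemented.
* Multiclass classification, probability calibration and external
  validation are out of scope; OOB error is an internal estimate, not a
  substitute for an independent cohort.
* Compositional closure is inherent to relative abundances: strong
  abundance swings in one taxon group induce opposite swings elsewhere,
  which correlation-based networks partially absorb. Interpret
  module–trait signs with this in mind.
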