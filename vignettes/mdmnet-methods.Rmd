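---
title: "Quantifying the structural role of microbial dark matter in co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the structural role of microbial dark matter in co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmnet)
```

## The problem

Most 16S rRNA surveys of microbial communities, extreme environments in
particular, are dominated by taxa that cannot be assigned a name at one or
more taxonomic ranks: lineages annotated as "uncultured", "Unassigned",
"Ambiguous taxa" or simply absent from the reference database.  This
"microbial dark matter" (MDM) is usually discarded or ignored, which begs
the question the package addresses: do unclassified taxa occupy structural
positions in community co-occurrence networks that classified taxa do not,
and can network position be used to prioritize which dark-matter taxa are
worth targeted follow-up (e.g. mining metagenome scaffolds around them for
adaptation-related operons)?

`mdmnet` implements the full chain: Unknown labeling from lineage strings,
sparse network inference from OTU count tables, a three-way network
comparison that isolates the contribution of Unknown taxa, hub-score
prioritization, and operon mining over scaffold gene tables, plus a
synthetic-data generator that plants every ground truth the pipeline is
supposed to recover.

## Unknown labeling

An OTU is Unknown *at a rank* when its label at that rank (after stripping
SILVA-style prefixes, case-insensitively, treating `_` and space alike) is
empty, missing, or one of: `uncultured`, `uncultured bacterium`,
`Unknown`, `Unassigned`, `Ambiguous taxa`, `NA`.  Unknown status
propagates downward: an OTU that cannot be named at family level is
Unknown at family *and* genus, whatever deeper fields claim.  Networks are
analyzed at each rank from phylum to genus; nodes always remain OTUs and
only their Known/Unknown display label changes with the rank
(`collapse_to_rank(aggregate = "relabel")`, the default).  A summing
aggregation is available behind `aggregate = "sum"` for users who want
rank-level composite nodes, but all shipped analyses use relabeling, which
matches per-rank Unknown *node* counts over a common OTU node set.

## Network inference

Counts are prevalence-filtered (default: present in at least 30% of
samples, inclusive threshold, `ceiling` rounding of fractional cutoffs),
CLR-transformed with pseudocount 1, and a conditional-dependence graph is
estimated by Meinshausen-Buhlmann neighborhood selection: each OTU's CLR
column is lasso-regressed on all others and the supports are symmetrized
with the "or" rule.  The penalty is chosen by StARS: over 20 random
subsamples of size `min(floor(10*sqrt(n)), floor(0.8*n))`, per-edge
selection frequencies `theta` give instabilities `2*theta*(1-theta)`;
their mean over all node pairs is monotonized from the sparse end of a
30-point log-spaced path (from the maximum absolute correlation down to 1%
of it) and the densest penalty with monotonized instability at or below
0.05 is refit on the full data.

Numerical notes:

* CLR columns are standardized with variance denominator `n` so that the
  all-zero lasso solution appears exactly at the maximum absolute
  correlation; the single-predictor case uses the soft-threshold closed
  form rather than a degenerate two-column fit.
* Constant (zero-variance) columns get empty neighborhoods.
* If no penalty meets the instability bound the sparsest one is returned
  with a warning flag in the `stars` element.

SparCC (classic basis-variance estimator with iterative strong-pair
exclusion, averaged over 20 Dirichlet fraction draws) and Pearson
correlation on CLR data are provided as alternate methods.  The original
analyses never state the cutoff used to binarize correlation matrices;
`correlation_network()`'s default of |r| >= 0.3 with two-sided p <= 0.05
is a documented convention, not a reproduction, and should be treated as a
tuning parameter.  The Pearson input scale (CLR) is likewise this
package's choice.

## Centralities

Degree, betweenness (raw shortest-path counts, unnormalized — medians are
compared across networks of different sizes, so users should be aware the
scale is size-dependent), closeness (per connected component, reciprocal
of summed distances to reachable nodes, undefined for isolated nodes) and
the Kleinberg hub score.  For an undirected graph the hub score is the
principal eigenvector of the adjacency matrix scaled to maximum 1; it is
computed by power iteration (tolerance 1e-10, all-ones start) with a dense
symmetric eigensolver as fallback when the iteration oscillates, as it can
on bipartite-like spectra.  This is implemented in-package because the
HITS implementation in current igraph operates on `A^T A`, which is
degenerate for undirected graphs (it zeroes the odd part of the spectrum;
on a 3-node path it assigns the endpoints score 0 instead of `1/sqrt(2)`).

## The Original / Without-Unknown / Bootstrap comparison

The core experiment asks whether the network *changes more* when Unknown
taxa are removed than when an equal number of random Known taxa are
removed:

1. **Original** — network on the filtered table.
2. **Without-Unknown** — all OTUs Unknown at the chosen rank are removed
   from the *count table* and inference is re-run with identical
   parameters and seed.  This is deliberate: deleting vertices from the
   original graph would only mechanically truncate it, whereas
   re-inference measures the community structure as it would have been
   estimated had the dark matter never been observed.
3. **Bootstrap** — `n_bootstrap` (default 100) replicates each remove a
   uniformly random Known subset of the same size and re-infer; node-level
   centralities from all replicates are pooled into one null distribution
   (per-replicate medians are retained as a sensitivity view).

Each metric is compared across the three pairwise contrasts with
two-sided Wilcoxon rank-sum tests, Holm-adjusted within the family of
three contrasts per metric.  Direction is read from the mean-rank shift of
the pooled ordering rather than the median difference: centrality
distributions are tie-heavy (most nodes have degree 0 or 1) and group
medians are frequently equal even when the rank test is decisively
one-sided.  The StARS seed is held fixed across all networks so that
differences reflect node removal rather than subsampling noise.

A caveat worth knowing: removing a hub from the *data* and re-inferring
does not simply delete its edges.  Three mechanisms push back against the
expected decrease:

1. **Marginalization fill-in.**  Integrating a variable out of a Gaussian
   graphical model adds dependencies among its former neighbors (a
   Schur-complement clique with strength roughly the square of the
   original edge).  With enough samples these become detectable and
   partially rebuild the removed hub's neighborhood as a mesh.
2. **Penalty re-selection.**  StARS picks the *densest stable* graph, so
   on the reduced table it tends to re-select a smaller penalty,
   compensating for the lost edges.  `mdm_compare(reuse_lambda = TRUE)`
   suppresses this by refitting Without-Unknown and Bootstrap networks at
   the Original's selected penalty — but because StARS parks the penalty
   just above the fill-in correlation scale by construction, fill-in then
   sits at the threshold and estimation noise still promotes part of it.
3. **Compositional re-closure.**  Re-CLR-ing the reduced table changes
   every remaining value (the per-sample log-mean loses the removed
   taxa), which injects shared variation and spurious associations among
   the survivors.

The removal effect is therefore a *detection-window* phenomenon — direct
edges above the detection threshold, fill-in below — and the window
narrows as sample size grows.  These are honest properties of
re-inference-based comparisons, not artifacts of this implementation;
they are also why the power of the planted-hub validation experiment
saturates well below 1 at desk scale (the validation script
`scripts/acceptance.R` reports the measured rates).

## The synthetic-data generator

`generate_community()` implements a logistic-normal-multinomial model: a
latent Gaussian draw with covariance `cov2cor(solve(I - strength*A +
bump))` over a planted graph `A`, shifted by per-taxon base abundances,
softmax-mapped to compositions and multinomially sampled at fixed depth.
Zeros arise only from depth and composition; the spread of base
abundances is calibrated by bisection so the expected zero fraction
matches `target_sparsity`.

Design choices, made once:

* **Hub topology with bounded hub degree.**  Partial correlations at a
  degree-d node cannot exceed `1/sqrt(d)` in any positive-definite model,
  so hubs of unbounded degree would make their own edges vanishingly weak.
  Half the non-hub nodes attach round-robin to the `n_hubs` (default 4)
  hubs (degree ~6 at p=50); a sparse Erdos-Renyi background (edge
  probability `1/p`) keeps the graph from being a pure star forest so
  betweenness is informative.  `band` and `random` topologies are also
  available.
* **Effect size** `edge_strength = 0.38`, close to the largest value the
  hub spectral radius admits without a large diagonal bump; the realized
  per-edge partial correlation is ~0.3.
* **`target_sparsity = 0.15`** by default.  Real filtered 16S tables are
  sparser, but at a fixed depth of 5e4 over 50 taxa every additional
  percent of zeros is bought by making some taxa so rare that their CLR
  column is pseudocount noise, destroying the very signal the planted
  graph is supposed to carry.  0.15 keeps a realistic tail of rare taxa
  (the generator reproduces the long-tail prevalence profile of real
  surveys — most taxa in less than 20% of samples — when asked for
  `target_sparsity ~ 0.8`) while the planted graph stays recoverable.
  What passing recovery tests at 0.15 shows about real data is therefore
  limited: real tables sit deeper in the attenuation regime, and recovery
  there will be worse than the synthetic figures.
* **Unknown labels** are planted on hub nodes with probability
  `hub_unknown_prob` (default 0.8) and the remainder of the
  `unknown_fraction` is spread uniformly; `plant_unknown_hubs = FALSE`
  gives the uniform-label null used for type-I checks.

Calibrating the comparison experiment deserves a note.  Its two desiderata
pull against each other: a large Unknown fraction makes the planted
contrast easy but also makes the *null* contrast significant (removing
40% of all taxa, hubs included by chance, genuinely shrinks a re-inferred
network), while a small fraction starves the planted contrast.  The
validation scenario uses p=40, n=200, depth 2e4, `unknown_fraction` 0.25
and `hub_unknown_prob = 1` — the sharpest version of the hypothesis "the
Unknowns are the hubs" — with full penalty re-selection (the faithful
default), and checks the null at the same removal size with uniform
labels.  These sizes also keep the full experiment (10 planted replicates
with 20 bootstrap networks each, plus 100 null runs) inside ordinary
desktop runtimes; they are the package's validation conditions, not a
claim about any particular dataset.

The scaffold generator lays out genes left-to-right independently per
strand, with within-operon gaps drawn at or below the 5000-bp rule and
between-operon gaps strictly above it, so planted operon memberships are
exactly recoverable; products are drawn from hypothetical/adaptation/
filler vocabularies with configurable probabilities, and explicit operon
templates can be planted for motif-level tests.

## Operon mining

BLAST tabular hits (outfmt 6, with or without a 13th query-coverage
column; coverage otherwise computed from the absolute query span) are
filtered at >= 95% identity and >= 95% coverage (inclusive), scaffolds at
>= 50 genes (inclusive).  Same-strand genes sorted by start are chained
into operons when consecutive intergenic gaps (`start_next - end_prev -
1`, floored at 0, overlaps clipped with a warning) are at most 5000 bp —
equivalent to cutting a single-linkage dendrogram on the gap distance.
"Ten genes within 5000 bp" is interpreted as a neighbor-window cap during
adaptation calling, not a hard operon-size cap: an operon is a putative
adaptation operon when some hypothetical gene has an adaptation-annotated
gene among its 10 nearest same-operon neighbors (nearest by intergenic
gap, ties broken by gene order then id, each neighbor within 5000 bp).
Both the gap boundary (<= vs <) and the window interpretation are
configurable.  The shipped keyword list (`extdata/adaptation_keywords.txt`)
is a starter seeded with oxidative/temperature/osmotic stress gene
families; it is meant to be replaced by a domain-specific list.

## Statistical conventions

* Fisher's exact test (two-sided) for Unknown-fraction enrichment between
  environments; degenerate margins return p = 1 with a warning.
* Welch's t-test (two-sided) for Known-vs-Unknown hub scores; the pooled
  variant is available via `var_equal = TRUE`.  The choice of variant is
  this package's, as the original analysis names only "Student's t test".
* Holm adjustment within each metric's three contrasts; the family could
  also be defined across ranks, which would be more conservative — the
  per-metric family matches reporting one panel per rank.
* Permutation p-values use the add-one estimator `(1 + #exceed) / (n + 1)`.

## Known limitations

* The generator does not simulate read-level artifacts (chimeras,
  clustering errors), taxonomic mislabeling, or sample covariates; passing
  tests say nothing about robustness to those.
* Betweenness is unnormalized, so cross-network median comparisons carry a
  size component; the bootstrap contrast controls for it by matching the
  removal size.
* SparCC p-values are not computed analytically; thresholding at |r| is
  the supported binarization (a bootstrap option would be a natural
  extension).
* Correlation-network cutoffs are conventions (see above); conclusions
  sensitive to them should be checked across a cutoff sweep, as the
  prevalence-threshold sweep (`threshold_sweep()`) does for the filter.
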