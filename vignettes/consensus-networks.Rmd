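---
title: "Methods: consensus co-expression networks and their null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus co-expression networks and their null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consnet)
```

This vignette is the package's account of its methods: the models and
procedures, the parameters that matter and why their defaults are what they
are, the numerical conventions, and the places where a design was genuinely
open and a choice had to be made. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The relevance-network model

Co-expression between genes $i$ and $j$ is measured by the Pearson
product-moment correlation $r_{ij}$ of their expression vectors
(log-scale intensities; at least 3 samples, genes with constant expression
excluded because their correlation is undefined). A *relevance network*
places an undirected, unweighted edge wherever $r_{ij} \ge \tau$. Two
readings of "correlated above a threshold" are defensible — signed
($r \ge \tau$) or absolute ($|r| \ge \tau$) — and the source text of the
underlying method does not disambiguate. `build_network()` defaults to
**signed**, the literal reading, and exposes `mode = "absolute"`; every
downstream stage is agnostic to the choice. Genes left without any edge are
excluded from the node set, so node counts vary with $\tau$.

The two-sided significance of a single correlation, when wanted, is the
exact $t$ reference: $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of
freedom; boundary values $|r| = 1$ return $p = 0$ and are flagged rather
than silently clipped.

## Automated threshold selection

The threshold is the one free parameter that decides everything downstream,
so it is chosen by a topological criterion rather than a significance
cut-off: for each $\tau$ on a grid in $[0.50, 1.0]$, compare the average
clustering coefficient of the real network with the mean over $R$
degree-preserving rewirings. Correlated modules produce triangles that
rewiring destroys, so structured data give a positive difference
$C_\text{real}(\tau) - C_\text{rand}(\tau)$; pure noise gives a difference
near zero (both facts are properties checked in the test suite).
`select_threshold()` picks the **first interior local maximum** of the
difference — the smallest grid point strictly above its left neighbour and
at least its right neighbour. Endpoints are ineligible; if no interior
maximum exists the argmax is returned with `fallback = TRUE` rather than
failing, and an all-flat curve is an error.

Defaults and rationale:

- `grid_step = 0.01` — matches the resolution at which the difference curve
  is smooth on cohorts of tens to hundreds of samples; coarser grids are
  fine for exploration and are what the test suite uses.
- `rewires = 10` replicates per grid point — the source procedure says only
  "random networks"; averaging a handful of rewirings tames the null's
  sampling noise at modest cost. One instance is recovered with
  `rewires = 1`.
- Grid points whose network has fewer than 3 edges record a difference of 0
  and are flagged; clustering coefficients there are not meaningful.

## Maslov–Sneppen rewiring and the intersection null

The null model throughout is degree-preserving edge rewiring: draw two
distinct edges, exchange endpoints (choosing one of the two pairings at
random), reject any attempt that would create a self-loop or duplicate
edge. **Attempts, not successes, count toward the budget**, whose default is
$4\,|E|$ — so a network with 134735 edges receives 538940 swap attempts.
The core is ~60 lines of Rcpp using R's own RNG stream, so results are
reproducible under `set.seed()` and a 2000-edge network rewires in
milliseconds. Degree preservation is asserted on every call, not assumed.
Graphs admitting no valid swap at all (a triangle is the canonical case)
come back unchanged and flagged `saturated`; identity pairings — proposals
that would recreate the two edges just removed — are rejected rather than
counted as successful swaps, which is what makes that flag meaningful.

The *randomized-intersection null* addresses the consensus directly: rewire
every study network independently, intersect, record the shared link count
and shared gene count; repeat (`n_reps = 200` by default, following the
repetition count of the original procedure). The consensus gene count is
defined as the number of distinct endpoints of shared links — a shared
label without any shared link carries no co-expression evidence — which
keeps the "genes" and "links" statistics consistent. Significance is the
plain z-score; both statistics are reported, links being the headline one.
Each (network, repetition) pair derives its own seed, so adding a network
or repetition never perturbs the others.

## Consensus and comparison across studies

`intersect_networks()` is exact edge-set intersection (associative,
commutative, idempotent — tested as properties). Pairwise overlaps report
both shared labels and shared links. `degree_profile_pca()` compares whole
networks: form the networks × common-genes degree matrix, centre each gene
column, and project onto the first two principal axes by SVD. Columns are
deliberately **not** variance-scaled: degrees share a scale, and scaling
would erase exactly the connectivity-magnitude differences the projection
is meant to display. Component signs are fixed by making each axis's
largest-magnitude loading positive, so coordinates are deterministic.

`partition_overlap_jaccard()` compares two partitions (for instance, from a
full run and a tumour-only rerun): for every cluster of the first partition
with more than `min_size = 10` genes, the best-match Jaccard coefficient
over the second partition's clusters. The tumour-only rerun is not a
special code path — it is the same pipeline on subsetted samples.

## Topology

Conventions, chosen once and used everywhere:

- Average clustering includes degree-<2 nodes as 0 — the common convention
  for co-expression networks, and the one consistent with reproducing
  published summary tables from an edge list.
- Diameter is computed on the **largest connected component**. A fragmented
  consensus network (giant fraction well below 1) has no all-pairs
  diameter; the per-component reading is the only consistent one.
- Betweenness is unnormalized shortest-path pair counting. All downstream
  comparisons are rank-based, so normalization would not change any
  conclusion; absolute per-gene betweenness values are therefore
  convention-dependent and are not asserted anywhere.
- Assortativity is the Pearson correlation of endpoint degrees over both
  orientations of the edge list; when every degree is equal it is reported
  as `NA` (undefined), never as 0.
- The rank-sum comparison uses midranks and **exact enumeration** of all
  group reassignments when $\binom{n_1+n_2}{n_1} \le 2\times10^5$, and the
  tie-corrected, continuity-corrected normal approximation otherwise. The
  exact branch makes small-sample contracts testable (identical samples
  give exactly $p = 1$; three-versus-three separated samples give exactly
  $p = 0.1$); the approximate branch is cross-checked against
  `stats::wilcox.test` in the tests.

`topology_vs_null()` packages the rewired-null comparison for global
metrics. Mean degree has a degenerate null by construction (the rewiring
preserves every degree), so its z-score is `NA` — reported that way
deliberately, as the built-in negative control.

## Discrete power-law fitting

The fit follows the Clauset–Shalizi–Newman recipe for integer data:
candidate cut-offs $x_{min}$ are the observed degree values (requiring at
least 5 tail points and excluding the maximum); for each candidate,
$\alpha$ is estimated by maximum likelihood; $x_{min}$ minimizes the KS
distance between the empirical tail CDF and the fitted CDF normalized by
the Hurwitz zeta function $\zeta(\alpha, x_{min})$ (computed by direct
summation with an Euler–Maclaurin tail, accurate far beyond the tolerances
in play). Ties in KS go to the smallest $x_{min}$.

One estimator decision was forced by the package's own validation. The
closed continuous-approximation MLE,
$\hat\alpha = 1 + n\left[\sum_i \ln\frac{x_i}{x_{min}-1/2}\right]^{-1}$,
is accurate for large cut-offs but biased low near $x_{min} = 1$ — on the
package's generator (α = 2.5, $x_{min} = 1$, n = 5000) it violates the
±0.1 recovery the package promises. The default is therefore the **exact
discrete MLE** (numeric maximization of the zeta-normalized likelihood,
which the tests pin against a dense-grid likelihood oracle to $10^{-3}$),
with the approximation retained as `alpha_method = "approximation"`.

Goodness of fit is the semi-parametric bootstrap: each replicate draws the
tail from the fitted law (inverse-CDF sampling with a far-tail continuous
fallback) and resamples the head empirically, then refits from scratch
including the $x_{min}$ scan; the p-value is the fraction of replicates
whose KS distance exceeds the observed one. `n_boot = 1000` by default
(`p > 0.1`: plausible). Degenerate inputs — all degrees equal with a free
cut-off — are an error; with a forced cut-off the fit proceeds.

## Partitions and functional coherence

Louvain (via igraph's multi-level modularity optimization, with the node
order permuted under the caller's seed so runs are reproducible and the
seed-sensitivity is measurable) and MCL (authored here: column-stochastic
adjacency with unit self-loops, expansion by squaring, inflation by
entrywise power with renormalization, convergence when the maximum entry
change drops below $10^{-8}$ or 200 iterations, clusters read from the
connected components of the limit matrix's non-zero pattern; entries below
$10^{-12}$ are pruned for sparsity). Inflation defaults to 2.0; higher
values never coarsen the clustering on the test fixtures, which is checked
as a property. Every partition carries its Newman–Girvan modularity, and
the stored value is required to match an independent recomputation to
$10^{-10}$.

Functional coherence compares the mean Jaccard similarity of annotation
term sets over co-clustered gene pairs against `n_random` size-matched
random partitions (gene labels permuted across cluster slots — cluster
sizes preserved exactly). Two open questions had to be settled here:

- *Which pairs to score.* Restricting to same-cluster pairs that are also
  network edges seems natural, but it is provably unable to separate a good
  partition from its own permutation null: a random label permutation
  co-clusters a random **subset of edges**, whose mean Jaccard equals the
  all-edge mean, so the fold ratio is bounded by the reciprocal of the
  intra-cluster edge fraction (≈1.2–1.9 for any partition worth having) —
  far below the order-of-magnitude separations this comparison is meant to
  expose. The default therefore scores **all same-cluster pairs** whose
  both members carry at least one term (`pairs = "all"`), with
  `pairs = "edges"` available. Unannotated genes are excluded from pairs
  (Jaccard is undefined on empty sets) but retained in enrichment
  references; a cluster set with no eligible pair reports `NA`, never 0.
- *What "random clusters with identical numbers of genes and links" means.*
  Label permutation (chosen: it holds the network fixed and randomizes
  exactly the assignment under test) versus network rewiring; the rewiring
  alternative remains available by composing `maslov_sneppen()` with the
  same scoring.

Annotation catalogues are filtered to terms with 5–50 genes **after**
restriction to the analysis universe (bounds inclusive); the filter
presumes a universe much larger than 50, which also guides the synthetic
fixtures (below). Enrichment of a cluster of $n$ genes against a term with
$K$ of $N$ reference genes is the hypergeometric upper tail $P(X \ge k)$
(`phyper`, numerically stable), Benjamini–Hochberg adjusted per cluster
across its tested terms — matching the per-analysis correction of typical
enrichment reports — with a global-correction switch.

## The synthetic-data generator

`generate_multi_study()` emulates the statistical structure the pipeline
assumes: several studies over a shared gene universe, some gene modules
genuinely co-expressed in **every** study, some private to one study, the
rest independent noise. Gene $g$ in a module with target correlation
$\rho$ is $x_g = w f + \varepsilon_g$ with a per-sample latent factor
$f \sim N(0,1)$, noise $\varepsilon_g \sim N(0, \sigma^2)$, and
$w = \sigma\sqrt{\rho/(1-\rho)}$, so the expected pairwise correlation is
exactly $\rho$; $\rho = 1$ or $\sigma = 0$ collapse to the factor itself
(exact unit correlations, the degenerate limit the tests pin). Only this
second-moment structure matters to a correlation-threshold pipeline, which
is why nothing more elaborate is simulated. Shared modules reuse identical
gene labels across studies; private-module labels are study-qualified and
can never collide; each study draws from its own stream derived from
`(seed, study_index)`, so adding studies never perturbs earlier ones.
Modules may be marked `condition = "normal"`, making their factor active
only in designated normal samples — the device used to test that a
tumour-only rerun loses normal-tissue modules.

Generator defaults — 3 studies, 150 genes, 100 samples, shared modules of
20 and 15 genes and one private module of 15 per study at within-module
correlation 0.9, unit noise — are the package's standing study conditions:
three cohorts of moderate size, strong planted modules, most genes
uninformative. What the generator does **not** emulate: probe-level
effects, normalization artefacts, batch effects, correlated noise between
modules, heavy-tailed expression, or clinical covariates. Passing the
synthetic suite therefore demonstrates that the machinery recovers planted
second-moment structure and calibrates its nulls — not that any particular
biological dataset will yield a meaningful consensus.

`sample_powerlaw_degrees()` draws exactly from the zeta-normalized discrete
power law by inverse CDF (table lookup grown on demand, continuous
approximation beyond $2^{20}$ table entries), giving the fitter a generator
to round-trip against; $\alpha \le 1$ is rejected as non-normalizable.

## Problem sizes and reproducibility

The test suite runs on deliberately small instances: study matrices of
24–150 genes × 20–100 samples, networks of tens of nodes, 200 rewired
replicates where a null distribution is measured, 50-seed Monte-Carlo
averages for calibration checks, bootstrap sizes of 50–300 inside tests
(the fitter's default remains 1000). These sizes make every distributional
claim in the suite a few seconds' work while leaving the asserted effects
far from their decision boundaries. `scripts/acceptance.R` re-runs the full
design from one `--seed` and writes every headline number to JSON;
`run_pipeline()` writes a manifest recording every parameter and seed, and
re-running a configuration reproduces its outputs byte for byte.

## Known limitations

- Pearson correlation only; rank or information-theoretic association
  measures are out of scope, as are weighted networks.
- The consensus is a hard intersection: a link missing from one study for
  purely technical reasons is lost. No rank-aggregation softening is
  provided.
- MCL cluster granularity depends on inflation, and published cluster
  counts for any particular dataset are implementation- and
  parameter-dependent; the package documents rather than asserts them.
- The exact rank-sum branch enumerates up to $2\times10^5$ reassignments;
  beyond that the normal approximation is used even in the presence of
  heavy ties.
- Very large networks (≫10⁵ edges) will make the threshold scan's repeated
  rewiring the dominant cost; `grid_step` and `rewires` are the levers.
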