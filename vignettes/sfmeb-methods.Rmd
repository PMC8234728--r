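---
title: "Normalization-free DE detection with a kernel minimum enclosing ball"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization-free DE detection with a kernel minimum enclosing ball}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfmeb)
```

## The problem

Differential-expression (DE) analysis of RNA-seq counts almost always starts
by normalizing libraries: estimating one scaling factor per sample so that
counts become comparable. That estimate is fragile exactly where it matters
most — when a large fraction of genes is DE, when up-regulation is
concentrated in one condition (inflating that library), when the data mix
subpopulations with *different* effective scaling factors, or when the two
"conditions" are two species with no shared library scale at all. This
package takes the opposite route: skip normalization entirely and use the
one piece of prior knowledge such experiments usually have — a small set of
genes believed *not* to change (housekeeping genes within a species,
conserved orthologs across species).

## The model

Each gene $i$ is a feature vector $x_i \in \mathbb{R}^m$ of its raw counts
across all $m$ samples. The known non-DE genes are assumed similar enough
that an implicit feature map $\phi$ sends them into a compact region of a
kernel feature space; a hypersphere is fitted around them and anything
outside it is called DE. The soft-margin primal is

$$
\min_{c, R, \xi}\; R^2 + C \sum_{i=1}^{n} \xi_i
\quad \text{s.t.} \quad
\lVert \phi(x_i) - c \rVert^2 \le R^2 + \xi_i,\;\; \xi_i \ge 0 ,
$$

with slack variables $\xi_i$ allowing some training genes outside the ball
at linear cost $C$ per unit. Its dual is the convex quadratic program

$$
\min_\alpha\; \alpha^\top K \alpha - \sum_i \alpha_i K_{ii}
\quad \text{s.t.} \quad \textstyle\sum_i \alpha_i = 1,\; 0 \le \alpha_i \le C ,
$$

where $K_{ij} = \phi(x_i)^\top \phi(x_j)$ is the kernel, by default the RBF
kernel $K(x, y) = \exp(-\nu \lVert x - y \rVert^2)$. The center
$c = \sum_i \alpha_i \phi(x_i)$ is never materialized. From the KKT
conditions, the squared radius $R^2$ is the squared feature distance from
$c$ to any *boundary* support vector ($0 < \alpha_i < C$), and the decision
function for an arbitrary gene is

$$
f(x) = K(x,x) - 2\sum_j \alpha_j K(x, x_j)
     + \sum_{jk} \alpha_j \alpha_k K(x_j, x_k) - R^2 ,
$$

with $f(x) > 0 \Rightarrow$ DE and $f(x) \le 0 \Rightarrow$ non-DE (a gene
exactly on the boundary is non-DE). Because only differences $x - y$ of raw
count vectors enter the RBF kernel, no per-sample scale is ever estimated —
this is what "scaling-free" means — and the same machinery applies verbatim
to cross-species ortholog counts. The signed value $f(x)$ doubles as a
significance ranking (larger = farther outside the ball = more confidently
DE); it is *not* a p-value, and the package deliberately does not dress it
up as one.

## Parameters that matter

* **`C` (default 0.1)** — soft-margin penalty. Feasibility of the dual
  requires $nC \ge 1$, so the default demands at least 10 training genes
  (`meb_fit()` and `sfmeb()` enforce this with an explicit message). Values
  near 1 approach the hard-margin ball; 0.1 is fixed during tuning.
* **`nu`** — RBF scale, the only tuned parameter. It is selected by grid
  search (`meb_tune()`) so that the *training reject rate* — the fraction of
  known non-DE genes left outside the ball — is closest to a target;
  ties go to the smallest `nu`. The reject rate is the type-I-error knob:
  the default target is 10%, and the `"cross_species"` preset raises it
  to 20% because conserved-ortholog training sets are noisier.
* **`nu_grid`** — 30 logarithmically spaced points from $10^{-4}$ to
  $0.999$. The grid is confined to $(0, 1)$; log spacing is essential
  because squared distances between raw count vectors span several orders
  of magnitude, so the transition from "everything inside" to "everything
  outside" happens over orders of magnitude of `nu`, not over a linear
  range. The full per-`nu` diagnostic table is always computed and returned.
* **`target_reject`** — achieved rates are *reported*, never assumed: the
  tuning result and the detection report both carry the achieved value.

### Numerical choices

The dual is solved by pairwise coordinate descent (SMO): starting from the
uniform feasible point, weight moves between the most KKT-violating pair of
coordinates, each step solved in closed form, until the gradient gap is
below $10^{-10}$ (scaled by the kernel diagonal). The iteration is
deterministic and monotone, and for this convex program it reaches the
global optimum; the test suite checks it against an independent
projected-gradient oracle. A ridge of $10^{-10}$ on the Gram diagonal picks
the minimum-norm solution among equivalent optima (e.g. duplicated training
genes), keeping the output deterministic. Boundary support vectors are
identified with tolerance $10^{-7} C$ on the open interval $(0, C)$, and
$R^2$ is the *mean* of their squared center distances — the theory says any
single one suffices, but averaging is numerically safer and agrees to
solver tolerance. $R^2$ is clamped at 0 if it comes out within $-10^{-10}$.
Degenerate inputs are handled explicitly: an all-identical training set
fits a radius-0 ball with a warning; all-zero training genes are retained
with a warning (the method imposes no expression filter); a fit in which
every dual weight sits at a bound has no boundary support vector and errors
with advice to change `nu` or `C`.

## What the simulator emulates

`simulate_counts()` reproduces the structure of the standard two-condition
count simulations used to benchmark normalization-free detection:

* Baseline expected counts are i.i.d. log-normal (meanlog 4, sdlog 1.5,
  natural log) — a heavy-tailed law mimicking empirical read proportions.
  The classical benchmark resamples empirical proportions from real data;
  that data is not bundled, so the log-normal is this package's stand-in,
  with parameters exposed in `sim_config()`.
* Exactly `round(G * pi0)` genes are DE, a fraction `p_up2` of them
  up-regulated in condition 2; the log2 fold change `d` is split
  symmetrically ($\mu 2^{\pm d/2}$) so the ratio of condition means is
  exactly $2^d$. `fc_mode = "at_least"` adds an exponential excess
  (rate 1, truncated at 2) for "no less than `d`" designs.
* `u = (u1, u2)` uniquely expressed genes have expected count exactly 0 in
  the absent condition — these model genes expressed in only one tissue or
  species and are counted as DE in evaluations.
* Per-condition depth factors (default `(1, 1.5)`) multiply all expected
  counts, so library-size confounding is present unless disabled.
  Heterogeneous ("two scaling factor") data concatenates two independently
  generated blocks with different designs and depths
  (`combine_heterogeneous()`); the preset second block uses depths
  `(1.2, 0.8)` so the blocks genuinely disagree about scale.
* Counts are Poisson or negative binomial
  ($\mathrm{var} = \mu + \phi\mu^2$, default $\phi = 0.1$). The NB variant
  stands in for empirical-dispersion simulators that require external
  reference data.
* The two-species design (`simulate_two_species()`) additionally draws
  `s = (s1, s2)` unmapped genes present in one species only; they consume
  sequencing depth (reported per sample) but are excluded from the returned
  ortholog matrix, and a random subset of non-DE orthologs is returned as
  the conserved training surrogate.

What the generator does **not** emulate: gene-length effects, empirical
mean–dispersion relationships, correlated genes, batch structure, or
mapping artifacts. Passing the simulation-based tests therefore shows that
the detector behaves as designed under idealized count noise with known
truth — not that it dominates on any particular real dataset.

## Evaluation utilities

`roc_auc()` sweeps thresholds over the distinct score values; grouping tied
scores into one step makes the trapezoidal area equal the Mann–Whitney
statistic $P(S_{DE} > S_{nonDE}) + \tfrac12 P(=)$ exactly, which is how the
tests pin it down to $10^{-12}$. `library_size_test()` is the naive
baseline that uses only raw counts and library sizes: an exact conditional
binomial test of each gene's condition-1 total against the combined total,
with null probability the condition-1 share of the total library. (The
baseline is traditionally just *named* "Library Size"; the binomial form
here is this package's concrete definition, with replicate pooling by
within-condition sums, or rounded means via `pool = "mean"`.)
`false_discovery_count()` counts known non-DE genes among the top-$k$
detections — the false-discovery proxy usable on real data.
`run_study()` ties it together: simulate, draw a training set, tune, score,
AUC, replicated under derived seeds.

## Design choices where the design was open

* **Raw counts as features.** Nothing is logged or length-adjusted; an
  optional `log1p` flag exists but is off by default, since the raw-count
  geometry is the method's premise.
* **Tuning criterion.** Without labelled test data, "achieved training
  reject rate closest to target" is the operational rule; a validation-set
  mode (minimize held-out non-DE rejection among near-target grid values)
  is available when extra non-DE genes can be spared.
* **Problem sizes in tests and the acceptance script** are scaled-down
  versions of the full designs (thousands of genes rather than tens of
  thousands, 5 replicates rather than 20), chosen so the full suite runs in
  minutes while leaving the qualitative comparisons (SFMEB vs library-size
  baseline) clearly resolved.

## A worked run

```{r example}
cfg <- sim_config(G = 1000, pi0 = 0.6, d = 2, p_up2 = 0.9, u = c(60, 30),
                  seed = 42)
sim <- simulate_counts(cfg)
train <- select_training_genes(sim$truth, 100, seed = 42)
fit <- sfmeb(sim$counts, train)
fit
roc_auc(fit$report$score, sim$truth$label != "nonDE")
```

The fit object carries the per-`nu` tuning table (`fit$tuning$per_nu`), the
dual weights (`coef(fit)`), and the per-gene report (`fit$report`);
`plot(fit)` draws the two-sample discrimination plot with training genes
overlaid.

## Known limitations

* The score is a distance, not a p-value; no FDR is attached.
* Performance degrades when the DE fraction is small and replicates are
  absent — the ball then gains little over normalization-based methods.
* Tuning assumes the training list is genuinely non-DE; contamination
  inflates the ball and costs sensitivity, which is why the cross-species
  preset tolerates a higher reject rate.
* With `C = 0.1` a training set of exactly 10 genes is feasible but forces
  every dual weight to its bound, leaving no boundary support vector to set
  the radius; in practice use comfortably more than `ceiling(1/C)` genes.
```
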