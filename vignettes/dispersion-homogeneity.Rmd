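---
title: "Testing homogeneity of multivariate dispersions with DTH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing homogeneity of multivariate dispersions with DTH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DTH)
```

## The problem

Many high-dimensional analyses — microbiome profiling above all — reduce the
data to a matrix of pairwise dissimilarities $\Phi = (\phi_{ij})$, with
$\phi_{ij} = \phi(Y_{i\cdot}, Y_{j\cdot})$ a measure such as Euclidean
distance, Bray–Curtis, or Jaccard. Groups of samples can then differ in
*location* (where their centroids sit) or in *dispersion* (how spread out
each group is). Omnibus distance-based tests such as PERMANOVA confound the
two, so dedicated dispersion tests are needed both as tests of scientific
interest in their own right (dysbiosis often manifests as increased spread,
not a shifted centroid) and as companions that tell location signals apart
from dispersion signals.

The classical dispersion tests summarise each group's spread by a single
number: the mean distance to the group centroid after a principal-coordinates
embedding (PERMDISP / `betadisper`), or the mean squared within-group
dissimilarity (the Gijbels–Omelka *U*-statistic approach). Two groups can
have equal *mean* dispersion while the *distribution* of their within-group
distances differs — heavier tails, more outliers, a bimodal mixture. Such
differences are invisible to one-parameter tests.

## The DTH test

For group $g$ with $n_g$ samples, collect the multiset of within-group
dissimilarities

$$\Phi_g = \{\phi_{ij} : g_i = g_j = g,\ i < j\},$$

with $L_g = |\Phi_g| = n_g(n_g-1)/2$ elements, and its empirical CDF

$$\bar F_g(z) = \frac{2}{n_g(n_g-1)} \sum_{i<j,\ g_i=g_j=g} I(\phi_{ij} \le z),$$

the fraction of within-group pairs closer than $z$ — equivalently the
average over the group's samples of the fraction of groupmates within
distance $z$ (the package tests this equivalence explicitly). The null
hypothesis is that the *distribution* of within-group dissimilarities is the
same in every group: $\bar F_1 = \cdots = \bar F_G$ in expectation.

For each pair of groups the package computes two divergences between
$\bar F_g$ and $\bar F_{g'}$:

* the Kolmogorov–Smirnov distance $K = \sup_z |\bar F_g(z) - \bar F_{g'}(z)|$,
  powerful against location–scale differences of the distance distribution;
* the 1-Wasserstein distance $W = \int |\bar F_g(z) - \bar F_{g'}(z)|\,dz$,
  powerful against tail and outlier differences.

Both are computed exactly from the merged step functions (a single merge
pass in C++), so unequal cardinalities $L_g \ne L_{g'}$ are handled without
subsampling; for equal cardinalities $W$ reduces to the mean absolute
difference of sorted values.

Within-group distances share samples and are therefore dependent, so
asymptotic two-sample null distributions are invalid. Significance comes
from a permutation scheme that regenerates, $R$ times, a family of
within-group sets $\{\Phi_g^{(r)}\}$ with equal dispersion in every group.
Writing $T_0$ for an observed statistic and $T_r$ for its replicates, the
observed statistic gets the add-one permutation p-value
$p_0 = (1 + \#\{r: T_r > T_0\})/(R+1)$ and each replicate gets the
rank-based p-value $p_r = \mathrm{rank}(-T_r)/R$ (each replicate is compared
to the other $R-1$). The K and W evidence is combined by the omnibus
statistic $m = 1 - \min(p_K, p_W)$, computed for $r = 0, \dots, R$. With two
groups the final p-value is the permutation p-value of $m$. With $G > 2$
groups, every pair's omnibus statistic is reduced to a p-value the same way
and the $G(G-1)/2$ pairwise p-values are pooled with Fisher's combination
$f = -\sum \ln p$, whose own permutation p-value is reported. All pairs and
both statistics reuse one replicate stream, which preserves the dependence
among pairwise comparisons.

When $G = 2$ the Fisher path is equivalent to the direct path (the map
$p \mapsto -\ln p$ is strictly decreasing, so the exceedance counts agree up
to ties); `dth_test(..., force_fisher = TRUE)` exposes the general path and
the test suite asserts the equality on seeded data.

## Permutation schemes

Two replicate-generation schemes are provided (`make_replicates()`):

* **`labels`** (default): permute the group labels over samples and
  re-extract within-group sets from the fixed dissimilarity matrix. This
  preserves the full dependence structure of the distances and is *exact*
  whenever samples are exchangeable under the null — in particular in every
  simulation scenario shipped with the package, where group locations are
  identical.
* **`pooled`**: pool the observed within-group distances of all groups and
  repartition them at random into sets of the original cardinalities. This
  never touches between-group distances, making it a pragmatic,
  location-robust alternative for real data whose group centroids may
  differ (a between-group location shift inflates between-group distances,
  which the pooled scheme never mixes into the null sets).

The original literature describes a dedicated scheme that generates
equal-dispersion replicates while accounting for location differences; its
construction is specified only in its source publication, so this package
documents the two schemes above as its permutation engine rather than
claiming to reproduce that construction. Both schemes are deterministic
given a seed, and the C++ permutation kernel consumes R's own RNG stream, so
`set.seed()` semantics apply; the test suite verifies that the kernel's
replicate families are bit-identical to the R-level reference
implementation. Replicates are generated sequentially from the single RNG
stream, so results are reproducible by construction.

## Tunable parameters

* `R` (default 999): permutation replicates. The p-value resolution is
  $1/(R+1)$, so the default resolves $p = 0.001$; the Monte-Carlo studies in
  the tests use $R = 199$ (resolution 0.005) to keep thousands of test
  invocations affordable.
* `scheme` (default `"labels"`): see above.
* `metric`: Euclidean for continuous data, Bray–Curtis ($\sum_k |x_k - y_k| /
  \sum_k (x_k + y_k)$) for abundances, binary Jaccard ($1 -
  |\text{shared}|/|\text{union}|$, presence = value $> 0$) for
  presence/absence structure. The command-line `test` subcommand guesses
  Bray–Curtis for integer-valued tables and Euclidean otherwise, always
  overridable. Any user-supplied dissimilarity matrix is accepted in place
  of a feature table.
* `bins` (default 3) in `discretize_covariate()`: a continuous covariate is
  discretized into near-equal quantile groups before testing. Three bins
  balance resolution against the requirement that every group contribute at
  least two samples (hence at least one within-group distance); values tied
  at a boundary fall to the lower bin.

## Ties and degenerate inputs

* Replicate ranks use the *maximum* rank within tied blocks, the
  conservative choice; with continuous dissimilarities ties have probability
  zero, so this matters only for discrete or duplicated data.
* All exceedance counts use strict inequality ($T_r > T_0$), matching the
  add-one p-value convention, which guarantees $p \in [1/(R+1), 1]$ and
  hence that $-\ln p$ is always finite.
* If every pairwise dissimilarity is equal, all statistics are identically
  zero and the strict-inequality count would make the p-value's behaviour an
  artefact of ties; the test returns $p = 1$ with a warning instead.
* The ECDF uses weak inequality ($\phi_{ij} \le z$): jump points are counted
  at their own location.

## Comparator tests

Two classical one-parameter dispersion tests are reimplemented from first
principles so that all three tests can run on identical inputs and share
infrastructure:

* `betadisper_test()`: principal-coordinates embedding of the dissimilarity
  matrix (eigendecomposition of the double-centered $-\frac12 D^{(2)}$
  matrix; axes split by eigenvalue sign; eigenvalues below
  $10^{-10}\max|\lambda|$ dropped), squared distances to own-group centroids
  computed as (positive-axis part) − (negative-axis part) and clamped at
  zero before the square root — the standard heuristic correction for
  non-Euclidean dissimilarities — then a one-way ANOVA F on the distances,
  with a label-permutation p-value that recomputes centroids and F per
  permutation. This mirrors `vegan::betadisper` with centroid (not spatial
  median) centering and no bias adjustment; the tests cross-check observed
  distances and F against `vegan` to $10^{-8}$.
* `go_perm_test()`: each group summarised by $\hat V_g$, the mean of
  $\phi_{ij}^2/2$ over $\Phi_g$ (the *U*-statistic variance form: for
  univariate Euclidean data it is exactly the sample variance; the factor
  $1/2$ is cosmetic and cancels in the permutation p-value, which the tests
  assert), compared across groups by the size-weighted spread
  $\sum_g n_g (\hat V_g - \bar V)^2$. Only the permutation version exists
  here; the asymptotic variant of the original proposal depends on a
  limiting distribution derived in its source publication and is not
  provided.

## The simulators

The generators exist to characterise size and power in settings where the
truth is controlled exactly; all have identical group means, isolating pure
dispersion signals, and all collapse to exchangeable groups at $\theta = 0$
so that label permutation is exactly valid and empirical size is a
meaningful acceptance surface.

**Normal scale mixtures** (`simulate_normal`): sample $i$ in group $g$ draws
a dispersion $v_i$ from a group-specific mixing distribution, then
$Y_{i\cdot} \sim N_d(0, v_i I_d)$. Defaults $d = 500$, $n = 150$ split
evenly over $G \in \{2, 3, 5\}$ groups, $\theta \in [0, 2]$:

* **S0** — $v_i \sim \mathrm{Gamma}(\alpha_g, \kappa_g)$ with $\kappa_g =
  (\Gamma(2\alpha_g + \tfrac12)/\Gamma(2\alpha_g))^{-2}$ (`gamma_kappa()`),
  which makes $E\sqrt{v_i + v_j} = 1$ and hence the expected within-group
  distance constant across groups: one-parameter tests should have
  negligible power here while distribution-level tests retain it. The
  formula is fixed by the requirement $E\sqrt{v_i+v_j}=1$ (using
  $E\sqrt{X} = \sqrt{\kappa}\,\Gamma(a+\frac12)/\Gamma(a)$ for
  $X \sim \mathrm{Gamma}(a,\kappa)$) and is verified by a Monte-Carlo oracle
  in the tests. Shapes $(\alpha_g)$: $(1, 1+3\theta)$ for $G=2$,
  $(1, 1+6\theta, 1+3\theta)$ for $G=3$, $(1, 1, 1+6\theta, 1, 1+3\theta)$
  for $G=5$.
* **S1** — $v_i$ log-normal$(\mu_g, \sigma_g^2)$ with $\sigma_g^2 = 3 -
  2\mu_g$, so $\mu_g + \sigma_g^2/2 = 3/2$ and $E(v_i) = e^{3/2}$ in every
  group: constant mean dispersion, varying dispersion distribution.
  $(\mu_g)$: $(1, 1-\theta)$, $(1, 1-\theta/2, 1-\theta)$,
  $(1, 1, 1-\theta/2, 1, 1-\theta)$.
* **S2** — log-normal with common $\mu = 1$ and varying $(\sigma_g^2)$:
  $(1, 1+2\theta)$, $(1, 1+\theta, 1+2\theta)$,
  $(1, 1, 1+\theta, 1, 1+2\theta)$: mean dispersion varies, the classical
  setting favouring one-parameter tests.
* **S3** — deterministic $v_g$: $(1, e^{\theta/80})$,
  $(1, e^{\theta/40}, e^{\theta/80})$,
  $(1, 1, e^{\theta/40}, 1, e^{\theta/80})$: a pure scale shift.

In every scenario family the non-null groups occupy fixed slots of the group
vector (the 2nd for $G=2$; 2nd and 3rd for $G=3$; 3rd and 5th for $G=5$),
with the remaining groups at the null parameterisation.

**Negative-binomial counts** (`simulate_negbin`): sample $i$ draws a size
parameter $r_i$, then $d = 500$ independent counts with $E(Y_{ij}|r_i) =
\mu$ and $\mathrm{Var}(Y_{ij}|r_i) = \mu + \mu^2/r_i$ (success probability
$p = r/(\mu + r)$). Scenarios mirror S1–S3 above via $r_i \sim
\mathrm{InvGamma}(\alpha_g, \beta_g)$ — so $E(1/r_i) = \alpha_g/\beta_g$ and
$\mathrm{Var}(Y_{ij}) = \mu + \mu^2\alpha_g/\beta_g$ — with S1:
$\alpha_g = 5 \cdot (1, e^{-\theta})$-patterned and $\beta_g = \alpha_g$
(mean dispersion constant at 1, distribution varying), S2: $\alpha_g = 3$
with $\beta_g = 5 \cdot (1, e^{-\theta/10})$-patterned (graded as
$e^{-\theta/20}, e^{-\theta/10}$ across the non-null slots for $G > 2$), S3:
deterministic $r_g = (1, e^{\theta/30})$-patterned (graded
$e^{\theta/60}, e^{\theta/30}$); $\theta \in [0, 3]$. The mean parameter is
not part of the scenario definitions, which control dispersion only; the
package fixes $\mu = 10$ for all groups — a realistic per-taxon mean for
moderately abundant taxa, constant across groups so that only dispersion
varies — and exposes it as an argument. An S0 analogue (equal mean
within-group Bray–Curtis distance) is not constructible in closed form and
is not attempted.

**Continuous covariate** (`simulate_continuous`): $x_i \sim U(0,1)$,
$Y_{i\cdot} \sim N_d(0, e^{s x_i} I_d)$; $s = 0$ is the null. This is a
generic surrogate for covariate-linked dispersion, used with
`discretize_covariate()`.

What the simulators do *not* emulate: the sparsity, compositionality,
taxon–taxon correlation and zero-inflation of real microbiome data
(template-based simulators exist for that purpose and are out of scope
here). Passing size/power benchmarks on these generators therefore
demonstrates correctness of the testing machinery under controlled
dispersion signals, not performance on any particular real dataset.

## The study driver and problem sizes

`run_study()` executes the benchmark grid: for each (scenario, $G$,
$\theta$) cell it simulates `n_reps` datasets, computes the distance matrix
once per dataset, and applies all requested tests to the same matrix — DTH
and the GO-type test literally share one replicate stream per dataset. The
package's shipped configuration for size benchmarks uses 200 datasets per
cell with $R = 199$ permutations, which resolves empirical size to a
binomial standard error of about $\sqrt{0.05 \cdot 0.95/200} \approx 0.015$
per cell (about 0.004 when averaged over a 12-cell grid) and keeps the full
null grid in the minutes range on one core; larger replicate counts are a
configuration change (`n_reps`, `R`), not a code change.

## Known limitations

* The `pooled` scheme repartitions observed within-group distances; it is
  conservative in preserving the pooled multiset but, unlike the `labels`
  scheme, does not preserve the geometric dependence among distances sharing
  a sample. It is offered as a robustness option, not a default.
* For $G > 2$, Fisher's combination treats the pairwise p-values as if
  independent; the permutation of the combined statistic corrects the
  calibration, but power against alternatives concentrated in a single pair
  may differ from a max-type combination.
* `betadisper_test` implements centroid centering only (no spatial median)
  and no small-sample bias adjustment.
* Very small groups ($n_g = 2$, a single within-group distance) are
  accepted but carry almost no information; the ECDF then has a single
  jump.
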