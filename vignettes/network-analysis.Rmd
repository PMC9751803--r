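---
title: "Molecular ecological network analysis with MicEcoNet"
author: "MicEcoNet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular ecological network analysis with MicEcoNet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

MicEcoNet turns OTU count tables into signed microbial co-occurrence
networks and asks whether those networks are non-random, modular, held
together by keystone taxa, and robust to species loss. This vignette is
the package's account of the methods: the model behind each stage, the
parameters that matter, the numerical choices, and what the synthetic
benchmarks do and do not demonstrate.

## From counts to a similarity matrix

The unit of analysis is one sample group (an arm of a study at one
timepoint); `runPipeline()` builds one network per level of the metadata
`group` column.

1. **Prevalence filtering.** OTUs present in fewer than half of the
   group's samples are removed (`min_prevalence = 0.5`); an OTU present
   in exactly half is kept. Rare and sporadically detected taxa produce
   correlation estimates dominated by their zero pattern, so they are
   excluded before any inference. Filtering is per group by default
   (`prevalence_scope`), because the group is the unit of network
   construction; a global mode exists for cross-group comparability of
   the OTU universe.
2. **Log relative abundance.** Counts are divided by the *full* sample
   total (the denominator is taken before row filtering, so retained rows
   keep their compositional meaning) and log10-transformed. Zeros cannot
   pass through the log, and the default policy replaces them with 0.01
   times the smallest nonzero relative abundance in the matrix — a
   deterministic, scale-respecting pseudo-abundance. The alternative
   `zero_strategy = "na"` leaves zeros missing and lets the correlation
   step use pairwise-complete observations.
3. **Pearson correlation** between OTU log-abundance profiles gives a
   symmetric similarity matrix with unit diagonal. Zero-variance profiles
   (possible after aggressive filtering) are flagged and assigned zero
   correlation. Spearman is available by configuration.

## The RMT threshold

Hard-thresholding a correlation matrix requires a cutoff, and an
arbitrary cutoff is the main criticism of correlation networks. The
random-matrix-theory approach selects it from the spectrum itself. The
nearest-neighbour spacing distribution (NNSD) of a matrix's eigenvalues
is universal: a matrix dominated by noise follows the Gaussian
orthogonal ensemble (GOE) Wigner surmise,
$P(d) = (\pi d/2)\,e^{-\pi d^2/4}$, while a matrix of independent
modular blocks follows Poisson statistics, $P(d) = e^{-d}$. As the
threshold rises and noise entries are zeroed, the spectrum crosses from
GOE to Poisson; the crossing point is the smallest threshold at which
only system-specific (modular) structure remains.

Per candidate threshold (grid 0.30–0.99, step 0.01 — the conventional
grid, on which reported thresholds such as 0.86 lie):

* entries with $|r|$ below the candidate are zeroed (diagonal kept) and
  rows/columns with no surviving off-diagonal entry dropped;
* the eigenvalues are **unfolded**: duplicates within 1e-8 are collapsed
  (degenerate levels carry no spacing information), a cubic smoothing
  spline with 10 degrees of freedom is fitted to the empirical cumulative
  spectral function $\hat F$, and levels are mapped to
  $e_i = N\hat F(\lambda_i)$ so spacings $d_i = e_{i+1}-e_i$ have mean 1.
  The low spline df is essential: a fit that follows every step of the
  empirical staircase forces all spacings to 1 and erases exactly the
  fluctuations being tested. Scan points with fewer than 50 distinct
  eigenvalues or 30 spacings are flagged unusable rather than trusted.
* the spacing histogram (bins of width 0.1 up to $d = 3$, open tail,
  adjacent bins pooled until every expected count is at least 5) is
  tested by Pearson chi-square against both laws.

`selectThreshold()` returns the smallest threshold whose spacings are
consistent with Poisson (goodness-of-fit p > 0.05) *and* fit Poisson
better than GOE. If no point qualifies the best Poisson fit is returned
with a prominent warning. Three modes cover practice: `auto` (per-group
selection), `fixed` (a supplied value, reproducing published shared
thresholds), and `shared_auto` (per-group selection, then the smallest
selected value applied to every group). The shared mode exists because
cross-group comparisons are only meaningful under one threshold: a group
whose scan happens to select a slightly higher cutoff would otherwise
have edges removed for reasons unrelated to its biology. Group contrasts
in this package's benchmarks use `shared_auto`.

On 500-by-500 GOE samples the chi-square prefers the Wigner law, and on
block-diagonal composites of independent blocks it prefers Poisson, in
every benchmark seed — the machinery's positive and negative controls
(`generateGoeMatrix()`).

## The network and its topology

An edge joins every OTU pair with $|r|$ at or above the threshold,
weighted by the signed correlation; isolated nodes are dropped. Edge
signs are the co-occurrence/exclusion readout: the positive share of
edges is reported per group, and signs are otherwise set aside —
modularity, roles and robustness operate on the unweighted, unsigned
topology, matching standard molecular-ecological-network practice.

`globalProperties()` reports node and link counts, average degree
$2L/N$, average local clustering (nodes of degree < 2 contribute 0 and
are included), average path distance over *connected* pairs only (so
fragmented networks are not assigned infinite distances), modularity of
the greedy partition, and the $R^2$ of an ordinary least-squares fit of
log10 degree frequency on log10 degree — the conventional scale-free
summary (deliberately not a maximum-likelihood power-law test, which is
out of scope).

**Null model.** Significance of clustering and modularity is judged
against degree-preserving Maslov–Sneppen rewiring: double-edge swaps
(10L attempts) rejecting loops and multi-edges, 100 replicates by
default. Signs are reassigned by permuting the original sign multiset;
topology alone is randomised. The z-score
$(\mathrm{obs}-\bar x_{\mathrm{null}})/s_{\mathrm{null}}$ is reported
per property; average degree is invariant under the null by
construction, so its z is undefined and flagged. On planted-modular
benchmarks the empirical modularity and clustering exceed the null by
tens of standard deviations.

## Modules and keystones

Modules are detected by greedy agglomerative maximisation of Newman's
$Q = \sum_m (l_m/L - (d_m/2L)^2)$ (deterministic; leading-eigenvector
and walktrap are available alternatives). Node roles follow the
Guimerà–Amaral coordinates: within-module degree z-score $Z_i$
(population standard deviation; $Z_i = 0$ where the module's degree
spread is zero) and participation coefficient
$P_i = 1 - \sum_s (k_{is}/k_i)^2$. Default cutoffs are the conventional
$Z_i \ge 2.5$ (module hub) and $P_i \ge 0.62$ (connector); nodes above
both are network hubs, and all non-peripheral nodes are flagged as
potential keystones. Both cutoffs are configurable. Module taxonomic
composition is summarised for modules of at least 5 nodes.

## Robustness and group comparison

Stability is measured as attack tolerance. A removal scheme deletes
either a uniform random floor(fraction × N) of nodes or
ceiling(fraction × |keystones|) of the keystone set (so "half of one
keystone" removes it), then applies a secondary-extinction cascade —
any node left with no partners is removed, iteratively — and records the
surviving fraction of the original nodes. The cascade rule is
deliberately abundance-free and deterministic; abundance-weighted
cascades are an explicit non-goal. One hundred repetitions per scheme
give a robustness distribution per group; groups are compared by
one-way ANOVA with a Tukey HSD compact letter display for more than two
groups. Error bars and tests are over repetitions (not bootstrap over
samples), and the repetition count is reported alongside.

## The synthetic community generator

All benchmarks run on `generateCommunity()`, which plants known network
structure in realistic 16S-style count data:

* **Latent model.** Each planted module has one standard-normal factor;
  OTU $i$ in module $m$ has latent
  $z_i = \varepsilon_i(a_i F_m + \sqrt{1-a_i^2}\,\eta_i)$ with sign
  $\varepsilon_i \in \{\pm 1\}$, so within-module correlations are
  $\varepsilon_i\varepsilon_j a_i a_j$ and the planted matrix is
  positive semi-definite by construction. Member squared loadings are
  spread uniformly over (`rho_pos - loading_spread`, `rho_pos`), giving
  heterogeneous correlations and right-skewed degrees; each module's
  hubs get a boosted loading (`rho_pos + hub_boost`, capped at 0.97) and
  therefore carry their block's strongest correlations. The negative
  fraction `f_neg` is planted by flipping the sign of a fraction
  $q = (1-\sqrt{1-2f^-})/2$ of members, which yields exactly $f^-$
  negative within-module pairs; this PSD-safe construction caps
  representable `f_neg` at 0.5, consistent with the predominantly
  positive networks observed in gut communities.
* **Background.** OTUs beyond the `n_modules * module_size` structured
  ones (default 4 × 25 of 200) are unstructured. This is both realistic
  — only part of a community covaries tightly — and necessary: because
  relative abundances share a denominator, compositional closure adds a
  spurious positive component to every pairwise correlation proportional
  to the coherent fraction of total biomass. With no independent
  background, planted negative associations are visibly biased toward
  zero and module recovery degrades.
* **Counts.** Latents are exponentiated around per-OTU means
  (`mu_sd = 1.5` on the natural-log scale, a realistically heavy-tailed
  abundance distribution), closed to compositions, and drawn
  multinomially at `depth = 50000` reads — a typical modern 16S library.
  Dropout then zeroes a count $c$ with probability
  `zero_inflation * exp(-c / dropout_tau)` (defaults 0.05 and 25): like
  real sequencing dropout it concentrates on low-abundance entries. A
  count-independent dropout would, combined with the pseudo-abundance
  zero replacement, inject extreme log outliers into otherwise abundant
  profiles and destroy correlations that survive in real data of this
  depth.
* **Defaults** emulate one arm of a gut-microbiome study: 200 OTUs, 12
  samples, 4 modules of 25, peak within-module correlation 0.8, 20%
  negative associations, one hub per module. `generateTwoGroupScenario()`
  pairs a sparser group A (`rho_pos` 0.60) with a denser group B (0.85)
  sharing the same per-OTU abundance means, so group differences are
  confined to association structure and alpha diversity is matched.

**Benchmark problem sizes.** The packaged checks use 500-by-500 spectra
for the RMT controls (20 seeds), 200 OTUs × 50 samples for threshold and
sign recovery (20 and 5 seeds), 150 OTUs × 30 samples with 100-network
ensembles for the null-model check (10 seeds), and the default two-group
scenario at 12 samples per arm with 100 robustness repetitions (20
seeds). These sizes resolve each property clearly while keeping a full
run on a single CPU in the low minutes.

## What the benchmarks do and do not show

Passing recovery tests on this generator demonstrates that the chain —
filtering, log-ratio transform, correlation, RMT threshold, module
detection, role classification, robustness — correctly recovers the
structure the generator plants, through realistic compositional,
sampling and dropout noise. It does not demonstrate that real gut
communities satisfy the latent-factor model: real data carry
phylogenetic correlation among taxa, batch and temporal structure,
abundance-dependent dispersion beyond the multinomial, and ecological
interactions that no correlation network identifies causally. Printed
statistics from any particular sequenced cohort (a specific shared
threshold such as 0.86, specific positive-edge percentages) depend on
those data and are not reproduced here; what the package reproduces are
the method's *properties* — threshold selection in the planted range,
module and sign recovery, non-randomness versus degree-preserving
nulls, and the denser-is-more-robust stability ordering.

Known limitations, chosen deliberately:

* At a dozen samples per group, pairwise correlation estimates have
  standard error near 0.3; selected thresholds are correspondingly high
  (~0.75) and individual hub ranks fluctuate. The generator's hub
  invariant is therefore a set-level statement (at least half the
  planted hubs in the top degree decile), not a per-hub guarantee — no
  PSD-consistent construction can do better at that sample size.
* A node cannot be strongly correlated with many mutually uncorrelated
  partners (positive semi-definiteness forbids it), so planted hubs are
  loading-boosted within their module rather than given cross-module
  spokes.
* The NNSD is computed on the full thresholded matrix after dropping
  all-zero rows/columns (not on the largest component only), and
  unfolding uses one global spline; both follow the lineage of the
  molecular-ecological-network tooling.
* Greedy modularity is the deterministic default; it can merge small
  planted modules in sparse regimes, which is visible in the benchmarks
  as detected-module counts exceeding planted ones (background clusters)
  without harming adjusted agreement on structured nodes.

## A compact example

```r
library(MicEcoNet)

sc <- generateTwoGroupScenario(
    communitySpec(rho_pos = 0.60, group_label = "A", seed = 1))
res <- runPipeline(list(table = sc$table, seed = 1,
                        threshold_mode = "shared_auto",
                        out_dir = "mena_out"))
res$topology_table          # per-group N, L, avgK, avgCC, GD, Q, R2 + nulls
res$sign_table              # positive/negative edge percentages
res$robustness_anova        # group stability comparison
compareGroups(res)          # B - A deltas per property
```

The output directory holds, per group, the filtered table, similarity
matrix, threshold scan, GraphML network with node phyla and edge signs
(loadable in Gephi or Cytoscape), node-role and module-composition
tables, robustness draws, and a manifest recording the resolved
configuration and seeds; a rerun with the same configuration and seed is
byte-identical.
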