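---
title: "Comparative cortical anatomy with connectivity blueprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative cortical anatomy with connectivity blueprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Comparing cortical organization across primate species is hard because
homologous areas can move, grow, shrink, or change their borders between
brains. The connectivity-blueprint framework sidesteps surface registration
by describing every point of cortex in a species-independent coordinate
system: its pattern of connection to a fixed set of major white-matter
tracts whose bodies can be identified in all species under comparison
(canonically 39 tracts — 18 per hemisphere plus 3 cross-hemispheric
pathways).

A **connectivity blueprint** is a (vertices × tracts) matrix built in two
steps from probabilistic tractography:

1. a (cortex × brain) matrix counts, for every surface vertex, the
   streamlines reaching each brain voxel;
2. multiplying by a (brain × tracts) matrix of tract probability maps
   yields a (cortex × tracts) matrix.

After row normalization, row $i$ is that vertex's **connectivity
fingerprint**: a probability distribution $M_{ik}$ over the tract set.
`build_blueprint()` performs the product and normalization;
`normalize_rows()` and `average_blueprints()` cover the normalization and
cross-subject pooling.

Fingerprints in two brains (blueprints $M$ and $H$) are compared with the
symmetric Kullback–Leibler divergence, in bits:

$$
D_{ij} \;=\; \sum_k M_{ik}\,\log_2\!\frac{M_{ik}}{H_{jk}}
       \;+\; \sum_k H_{jk}\,\log_2\!\frac{H_{jk}}{M_{ik}} .
$$

`symmetric_kl()` implements the scalar case and `divergence_matrix()` the
all-pairs case; the same measure works within a species. Derived maps:

- `min_divergence_map()` — per-vertex minimum divergence to the other
  species: the *connectional dissimilarity map*, high where a fingerprint
  has no counterpart in the other brain;
- `fingerprint_search()` — divergence of every vertex to one query
  fingerprint, used to localize a candidate homolog;
- `top_fraction_fingerprint()` — the average fingerprint of the most
  similar fraction of vertices (e.g. the top 1%);
- `entropy_map()` — Shannon entropy $-\sum_k p_k \log_2 p_k$ of each
  fingerprint, separating *which* tracts reach a vertex from *how many*;
- `local_correlation_map()` — neighborhood-wise Pearson correlation
  between two surface maps.

A whole cortical map $h_i$ on one surface (e.g. a T1/T2-weighted myelin
proxy) is transformed onto the other surface by divergence-weighted
interpolation (`transform_map()`):

$$
m_j \;=\; \frac{\sum_i D_{ji}^{\gamma}\, h_i}{\sum_i D_{ji}^{\gamma}},
\qquad \gamma = -4 .
$$

Finally, a labeled atlas is collapsed to one fingerprint per region
(`region_fingerprints()`), two atlases are compared by pairwise region
divergence with mutual-argmin matching (`cross_atlas_divergence()`), and
the union of both species' regions is projected into a shared 2D space by
spectral embedding of the joint divergence structure (`spectral_embed()`,
`atlas_embedding()`).

## Assumptions

The framework assumes (i) the tract set is genuinely homologous — each
column refers to the same bundle in every brain compared; (ii) a
fingerprint, as a *proportional* distribution over tracts, carries the
relevant anatomical signature (absolute streamline counts are discarded by
the normalization, deliberately: they are dominated by seeding and
geometry); (iii) low fingerprint divergence is evidence of homology. The
last assumption is the scientific hypothesis the framework operationalizes,
not a mathematical fact; divergent results flag *connectional
reorganization*, which is related to but distinct from cortical expansion.

## Parameters that matter

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `epsilon` | `connectivity_blueprint()` | `1e-8` | floor added to every fingerprint entry before renormalization |
| `gamma` | `mapping_config()` | `-4` | divergence-weighting exponent of the map transform |
| `threshold` | `fingerprint_search()` | lowest 5% | localization mask for a fingerprint search |
| `sigma` | `spectral_embed()` | median off-diagonal divergence | Gaussian affinity bandwidth |
| `fraction` | `top_fraction_fingerprint()` | `0.01` | share of most-similar vertices averaged |
| `k` | `ring_neighborhoods()` | `3` | mesh ring order of the local-correlation window |

**Epsilon floor.** The KL divergence is undefined when one distribution
has support the other lacks, and tractography fingerprints contain exact
zeros routinely. We therefore add a small constant to every entry of a
normalized fingerprint and renormalize: $p \mapsto (p + \varepsilon)/(1 +
K\varepsilon)$. At the default $\varepsilon = 10^{-8}$ the perturbation of
any well-supported fingerprint is below $4\times10^{-7}$ in total
variation for $K = 39$, far below tractography noise, while every
divergence becomes finite. Disabling the floor (`epsilon = 0`) restores
the strict definition: `symmetric_kl()` then returns `Inf`, with a
warning, on support mismatch. Vertices whose *raw* fingerprint is all zero
are not floored into a uniform distribution but masked as degenerate — a
uniform fingerprint would silently match any high-entropy cortex.

**Gamma and the zero-divergence singularity.** With $\gamma < 0$ the
weight $D^{\gamma}$ diverges as $D \to 0$. The implementation resolves
this with the analytic limit: target vertices with one or more
zero-divergence sources (within `zero_tol = 1e-12`) copy the mean of
exactly those sources. For numerical safety all weights are computed as
$(D/\min D)^{\gamma}$, bounding them by 1, so steep exponents (the
nearest-neighbor limit $\gamma \to -\infty$) cannot overflow. The output
is always a convex combination of the source map.

**Search threshold.** Localizing an area from a divergence map needs a
cutoff. The default selects the lowest 5% of unmasked divergence values; a
percentile adapts to the overall divergence scale of the pair of brains
being compared. An absolute cutoff in bits is available, and the resolved
threshold is recorded in the search result and in CLI config output.

**Entropy and divergence base.** Both use $\log_2$, so all information
quantities are in bits and the uniform fingerprint over 39 tracts has
entropy $\log_2 39 \approx 5.285$ bits.

**Spectral embedding choices.** The divergence-to-affinity kernel, the
Laplacian normalization and the eigenvector choice are all conventions
rather than consequences of the model. We use the Gaussian kernel
$\exp(-D/\sigma)$ with the median heuristic for $\sigma$, the symmetric
normalized Laplacian $L = I - \mathrm{D}^{-1/2} A \mathrm{D}^{-1/2}$, and
the eigenvectors of the 2nd and 3rd smallest eigenvalues (the 1st is
constant up to degree weighting). All are configurable and recorded in the
output. Eigenvector sign is intrinsically arbitrary; we canonicalize it by
making each vector's largest-magnitude entry positive, which also makes
the embedding reproducible under permutations of the input order. A
disconnected affinity graph (possible only with infinite divergences) is a
hard error naming the components. The joint (both-species) divergence
matrix is embedded in one pass, rather than embedding each species
separately and aligning afterwards, so that between-species divergences
shape the common space directly.

**Ties.** Argmin and top-fraction selections break ties by the smaller
vertex index, making every localization deterministic.

## Cross-subject pooling

Group blueprints are the element-wise mean of row-normalized
subject blueprints, renormalized per row, with a vertex masked in the
group if masked in any subject. Averaging after normalization weights
every subject equally regardless of total streamline count; for rows that
already sum to one the renormalization is a no-op, so the operation is
idempotent and symmetric. Pooling before normalization would instead
weight subjects by streamline yield, which is dominated by technical
factors. No smoothing across the surface is applied at any stage.

## The synthetic generator

Real blueprints require diffusion MRI, tractography and surface models,
none of which belong in a unit test. `generate_pair()` emulates the
statistical structure the framework's analyses rely on:

- each of `n_regions` regions has a base fingerprint drawn from a flat
  Dirichlet over the tract set; homologous region pairs share the base
  across species;
- divergent regions shift a fraction (`divergent_shift`, default 0.5) of
  species A's base mass onto one designated tract — emulating a tract
  with a much stronger influence in one lineage;
- vertex fingerprints are `Dirichlet(concentration × base)` draws, so
  `concentration` (default 200) plays the role of combined
  individual-and-measurement noise; higher concentration means tighter
  fingerprints, and the median within-homolog divergence decreases
  monotonically in it;
- a scalar surface map is a fixed linear readout of the fingerprint
  (unit-normal weights shared across species) plus Gaussian noise
  (`scalar_noise_sd`, default 0.1) — a map predictable from connectivity,
  like a myelin proxy;
- `generate_tractography_inputs()` factorizes a planted blueprint into
  vertex-to-brain and brain-to-tract matrices whose normalized product
  reproduces it, exercising the construction path end to end.

Defaults are 2000 vertices per species, 39 tracts, and 10 regions, so one
region is a decile of the surface; the single default divergent region
therefore fills the top decile of the dissimilarity map when the planted
gap dominates the noise. The structural draw (bases, divergent tracts,
readout weights) depends only on `seed`; the `subject` argument re-draws
only the vertex noise, giving repeated "individuals" of the same two
species for variability analyses.

Because vertices within a region share one base fingerprint, they are
statistically exchangeable: the planted vertex-level correspondence is
membership in the homologous region, and recovery is scored as the argmin
partner falling inside that region. The generator does **not** emulate
cortical geometry, spatial autocorrelation along the surface, distance
biases of streamline propagation, gyral crowns versus sulcal walls, or
hemispheric asymmetries. Passing tests therefore show that the estimators
recover planted structure under Dirichlet noise — not that tractography
artifacts in real data are benign.

## Variability of between-species predictions

`prediction_variability()` repeats the map transform over subject pairs
and reports per-vertex mean, standard deviation and
$Z = (\text{mean} - \text{data})/\text{std}$, with zero-variance vertices
carrying the `NA` sentinel. Two properties are worth keeping in mind when
reading Z maps. First, a prediction at a target vertex averages over many
source vertices, so its between-pair standard deviation is much smaller
than the per-vertex noise of any *measured* map; Z compares the data
against the spread of predictions, not against measurement noise, and
honest measurement noise alone will produce large |Z|. Second, with $n$
pairs the statistic behaves like a Student $t$ with $n-1$ degrees of
freedom when the observed map is itself drawn from the predictive process,
so small ensembles have heavy tails by construction. The test suite checks
the exact identities (Z $\equiv$ 0 when the observed map equals the mean
prediction; sentinels where std = 0) and, with 20 subject pairs and a
held-out-pair observation, that Z is centered with most vertices inside
|Z| < 3.

## Degenerate inputs and numerical conventions

- $0\log 0 = 0$ throughout (entropy and both KL terms).
- All-zero rows: flagged by `normalize_rows()`, masked (with a warning) by
  the blueprint constructors.
- Divergence matrices are clipped at zero to absorb rounding noise of the
  vectorized decomposition
  $D_{ij} = \sum_k M\log_2 M + \sum_k H\log_2 H - \sum_k M\log_2 H -
  \sum_k H \log_2 M$, which agrees with the term-by-term sum to $10^{-10}$.
- Local correlations need at least 3 valid neighbors and nonzero variance
  in both maps; anything else is a sentinel.
- On-disk vertex indices are 0-based; in-memory indices are 1-based.

## Problem sizes

The shipped tests run the full pipeline at 2000 vertices per species with
39 tracts for the headline recovery checks and 80–500 vertices elsewhere;
a 2000 × 2000 divergence matrix computes in about a second through the
vectorized decomposition, and the whole suite in well under a minute.
These sizes were chosen to exercise every code path at the default study
conditions while keeping the suite quick to iterate on; the operations
scale to the ~10k-vertex meshes used in practice (a 10k × 10k divergence
matrix is ~800 MB dense, the reason the TSV writer guards at 5000×5000 —
compute such matrices block-wise).

## Known limitations

- No statistical significance testing of divergence values; the framework
  reports dissimilarities, not p-values.
- Comparability requires *identical* tract sets; there is no partial
  matching of overlapping tract repertoires.
- The divergence-weighted transform cannot extrapolate: predicted values
  are convex combinations of the source map.
- GIFTI/CIFTI surface formats are not read or written; surface scalars,
  labels and blueprints use plain-text formats (one value per line, TSV),
  and divergence matrices TSV only.
- Spectral coordinates are identified only up to rotation/reflection
  between runs of *different* inputs; only the canonicalized sign is
  stable.
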