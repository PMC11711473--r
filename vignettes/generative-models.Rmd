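---
title: "Economic generative models of spatially embedded brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Economic generative models of spatially embedded brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wiregrow)
```

## The model and its assumptions

wiregrow simulates the growth of a binary structural connectome as a
sequence of single-edge additions. Regions live at fixed 3D coordinates;
for every unconnected pair (i, j) the selection score is

$$ s_{ij} = d_{ij}^{\,\eta}\,(k_{ij} + \varepsilon)^{\,\gamma} $$

with $d_{ij}$ the Euclidean distance (the wiring cost; constant over
growth) and $k_{ij}$ a topological value term recomputed after every
addition. One pair is drawn per iteration with probability proportional
to its score until the target connection count is reached. The model's
assumptions are worth keeping in view:

* Edges are only added, never removed or weighted; the observed data must
  therefore be binarised, and sparsely (around 10% density) for the
  simulations to be meaningful.
* Cost is Euclidean distance, not fibre length; the two correlate
  strongly but Euclidean distance underestimates the cost of
  inter-hemispheric wiring.
* The model is fitted to distributions of topology, not to edge
  locations. A well-fitting model reproduces degree, clustering,
  betweenness and edge-length distributions — and usually much of the
  correlation structure among local measures — while placing many
  individual edges in the wrong locations.

Thirteen interchangeable value rules are registered (`gnm_rules()`):
`spatial` ($k \equiv 1$), the homophily pair — `neighbors` (count of
shared neighbours) and `matching` (shared neighbours over the union of
both neighbourhoods, excluding the pair itself) — and the
mean/min/max/absolute-difference/product reductions of the endpoint
clustering coefficients (`clu-*`) or degrees (`deg-*`). `matching` is
the normalised form of `neighbors`; one implementation serves both the
growth engine and the matching graph measure, so they cannot drift
apart.

## Fitting

`gnm_fit()` fits $(\eta, \gamma)$ by grid search: one simulation per
grid point (configurable via `nreps`), grown from a fixed seed network
to the observed edge count, scored with the energy

$$ E = \max(KS_k, KS_c, KS_b, KS_e), $$

the largest two-sample Kolmogorov–Smirnov statistic across the four
nodal distributions. "Edge length" here is the *nodal* total connection
length (the sum of a node's connection lengths), matching the local
measure set; a per-edge-length variant is available through
`ks_edge = "edgewise"` since both conventions exist in the literature.
Complementary fit diagnostics are the topological fingerprint
dissimilarity (Frobenius norm between the 6×6 correlation matrices of
the local measures) and spatial embedding (node-wise Pearson
correlations of each local measure between observed and simulated
networks).

Ties in the landscape minimum are broken toward smaller $|\eta|$, then
smaller $\gamma$. Zero-variance columns in a fingerprint (e.g. a regular
toy graph where degree is constant) are set to correlation 0 with a
warning so the dissimilarity stays defined.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| $\eta$ | fit over $[-3, 0]$ | distance exponent; negative favours short connections (dimensionless) |
| $\gamma$ | fit over $[0.1, 0.6]$ | value exponent (dimensionless) |
| $\varepsilon$ | $10^{-5}$ | offset added to $k$ so zero-value pairs stay reachable; without it homophily growth can freeze early, when no pair shares a neighbour |
| seed prevalence | 0.95 | edge kept in the seed when present in ≥95% of subjects |
| consensus mask | 0.60 | minimum subject fraction for an edge to survive masking (≥ comparison; a flag switches to >) |
| absolute threshold | 325 | streamline count for the variable-density analysis |
| density target | 0.10 | exact per-subject density for the controlled analysis |
| rich-club nulls | 1000 | degree-preserving rewirings; α = 0.05 per degree level, one-sided, uncorrected |

The default fitting grid bounds are the refined homophily region; rule
comparison (all 13 rules on one cohort) is run on this refined grid so
that every rule competes where the generating process actually lives — a
coarse lattice over a very wide range can miss the optimum of the true
rule entirely and invert the ordering.

## Numerical choices

* Scores are computed in log space (`wiring_probabilities()`) or with
  direct `pow` on cached terms (the C++ engine); both are exact for the
  exponent ranges used.
* Sampling is inverse-CDF over the deterministic pair ordering (i < j,
  column order), one uniform draw per iteration from R's RNG, so traces
  are exactly reproducible from `set.seed()` across platforms.
* The engine updates scores incrementally: after adding edge (u, v) the
  value term can change only for pairs touching u or v (and, for
  clustering rules, their common neighbours). The incremental update is
  proven equal to full recomputation by replay tests on random traces
  for every rule.
* Degree-preserving nulls use double-edge swaps; picks with no valid
  swap are skipped, so graphs admitting none (stars) return unchanged
  with a recorded swap count of zero.
* Modularity is Newman spectral bisection with deterministic
  Kernighan–Lin refinement, written here rather than delegated so the
  partition is reproducible bit-for-bit; its Q is re-evaluated from the
  definition, and tests cross-check against igraph's evaluation.
* Disconnected pairs contribute 0 to efficiency; characteristic path
  length averages finite paths only. Both conventions are stated because
  10%-density networks are frequently disconnected.
* Fractional target edge counts round half-to-even in
  `threshold_to_density()` (so a 90-node network at 10% keeps exactly
  400 of 4005 pairs); generator and consensus-bin targets round half
  away from zero.
* Density-cutoff ties break by higher weight, then lexicographic node
  pair.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` produces the study conditions end to end: a
bilateral mirrored geometry (90 nodes by default, hemisphere clusters
±25 mm from the midline, spreads 12/35/22 mm — a neonatal-scale brain);
per-subject covariates with preterm fraction 0.29, birth age < 37 weeks
defining preterm, and postnatal exposure negatively correlated with
birth age; a binary scaffold grown by the package's own engine at
group-specific ground-truth parameters (term η = −1.74, γ = 0.32;
preterm η = −1.85, γ = 0.34, the representative best-fit values for the
two groups); analysis density 10% at term, increasing 0.004/week of
scan age, with raw (unthresholded) matrices 2.5× denser so that count
thresholding has room to work; and streamline counts on present edges
from a shifted negative binomial whose mean decays with distance
(scale 450 at zero distance, e-folding 60 mm, size 8). The dispersion
choice is deliberate: counts stay overdispersed relative to Poisson, yet
the shortest, most consistent connections survive thresholding in
nearly every subject, so a 95%-prevalence seed network exists — as it
does in real cohorts. A pure geometric count model (dispersion 1) makes
every edge too volatile and the seed degenerates to empty.

Because the ground truth is the same engine being fitted, parameter
recovery tests deliberately use a different RNG stream for fitting than
for generation, so recovery reflects the estimator rather than shared
noise.

What the generator does **not** emulate is real hub geography. Under a
distance-penalised growth truth, high-degree nodes emerge where nodes
are spatially dense — near the centre of each hemisphere cluster — so
rich-club members of the synthetic consensus network sit closer together
than average (about 37 mm versus 62 mm over all pairs at the defaults).
In real neonatal data the rich club consists of spatially dispersed
association hubs, and rich connections are the longest class. Tests that
pass on synthetic cohorts therefore validate the machinery (thresholds,
measures, energy, recovery, group contrasts in wiring length), not the
claim that rich connections are longest — that direction depends on real
hub placement, and the corresponding check is expected to fail on
synthetic data. This is the binary GNM's well-documented weakness at
spatial embedding, inherited by any cohort the GNM itself generates.

## Group experiment conventions

`run_group()` grows many models per group at fixed parameters, recording
every added edge, and classifies edges against a rich-node set frozen
from the consensus network before any simulation (not recomputed per
run). Counts include the seed edges as an iteration-0 baseline, so
rich + feeder + local equals the running edge total at every iteration.
Lengths are cumulative means over added edges; the per-iteration added
lengths are also emitted. `compare_groups()` reports raw difference
curves, permutation p-values over runs for the final state, and
standardized effects (mean difference across generative time divided by
the pooled SD over runs × iterations). The standardized scale matters
for per-class counts: at matched iterations the three class counts sum
to the same total in both groups, so raw differences are constrained to
cancel, and only standardized magnitudes are comparable across classes.
Group-contrast uncertainty is by run-level permutation rather than
spline regression; smooth-model effect sizes from real-data studies are
tied to real atlas geometry and are not reproduction targets here.

## Problem sizes used in validation

The test-suite experiments are sized for a single CPU: oracle
equivalence enumerates all 64 graphs on 4 nodes plus random graphs up to
8 nodes; the sampler check uses $10^5$ one-step draws on 5 nodes;
parameter recovery fits 10 synthetic subjects (90 nodes, ~400 edges) on
a 20×20 grid; rule comparison fits the same 10 subjects under all 13
rules on a 10×10 grid; the group experiment runs 200 growths per group
(scaled down from the 1000 a full analysis would use — the directions
under test are stable far below that). The full-scale settings remain
the defaults in the user-facing functions.

## Known limitations

* Binary, growth-only models: no pruning, no weights, no
  connection-strength dynamics.
* One static geometry per cohort, while a real perinatal brain grows;
  distances are fixed at their atlas values.
* The energy compares distributions, not edge placements; identical
  energies can correspond to quite different wirings.
* Rich-club detection on small or very sparse networks is fragile: few
  degree levels have enough nodes for a defined coefficient, and the
  selected club can be large when low degree levels reach significance.
* `summarize_cohort()` is descriptive by design; inferential modelling
  (splines, mixed models) belongs in external statistics packages, fed
  by the tidy tables the pipeline writes.
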