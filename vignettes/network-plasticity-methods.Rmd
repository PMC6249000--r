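---
title: "Modelling post-lesion network plasticity with plastnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling post-lesion network plasticity with plastnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastnet)
```

## The analysis in one paragraph

A focal lesion perturbs the whole functional network, not just its site.
`plastnet` quantifies that perturbation longitudinally: regional
timecourses become signed, unthresholded Pearson connectomes; the pre-lesion
connectome is partitioned into modules by consensus Louvain clustering;
per-region metrics (strength, participation coefficient, within-module
connectivity, PCA hubness) are tracked across pre-lesion, 3-month and
12-month scans; stage changes are modelled by p-value-driven stepwise
regression on four predictors — neuron density, non-neuronal cell density,
hubness, and the pre-lesion connectivity of the lesioned (seed) region —
with two bespoke resampling procedures guarding the inferences.

## Connectomes

`compute_fc_matrix()` correlates region-by-time matrices (Pearson), errors
on constant timecourses, and enforces symmetry. Matrices stay continuous and
signed throughout: thresholding is deliberately avoided, so every downstream
operation defines its own negative-weight policy (below).
`average_fc_matrices()` averages across subjects elementwise by default —
plain averaging of correlations is what the emulated study reports — with a
Fisher-z option (`atanh` → mean → `tanh`) for users who prefer the
variance-stabilised pooling. Whether to Fisher-transform before averaging is
genuinely open; raw is the default because it reproduces the reference
behaviour, and the option documents the cleaner alternative.

The seed profile (`seed_connectivity_profile()`) is the mean of the left-
and right-hemisphere seed rows of a *full* matrix (one still containing the
excluded regions), restricted to the 78 network regions. The bundled atlas
encodes the 41 Regional Map areas per hemisphere; hippocampus and amygdala
are flagged out of the network bilaterally. The published source of the
parcellation does not fix a region order, so the bundled table orders
alphabetically within hemisphere, left first — a package convention, stated
as such, and preserved through every table and matrix.

## Modules, modularity and consensus

`louvain_partition()` implements the greedy two-phase Louvain algorithm with
Newman–Girvan modularity at resolution $\gamma$:

$$Q = \frac{1}{2m}\sum_{ij}\left[W_{ij} - \gamma\frac{k_i k_j}{2m}\right]
\delta(c_i, c_j).$$

Conventions that matter, all tested against closed forms and a brute-force
double-sum oracle:

- Community detection and participation run on the **positive part** of the
  matrix with the diagonal zeroed. Positive-part analysis is the most common
  choice for weighted signed connectomes and keeps $P_i \in [0,1]$. A signed
  asymmetric variant $Q^+ - \frac{m^-}{m^+ + m^-}Q^-$ is available in
  `modularity_score(weights = "signed")`.
- Self-weights are excluded but the diagonal null-model term is kept, so one
  module at $\gamma = 1$ scores exactly $Q = 0$ and two equal disconnected
  cliques score $1 - \gamma/2$.
- Node sweeps visit regions in seeded random order; among equal-gain moves
  the lowest-index community wins; a move requires a strict gain. This makes
  every run deterministic given its seed.
- Restarts alternate the classical all-singleton start with a random initial
  partition, and every run ends with a flat single-node refinement pass on
  the original graph. The random restarts matter: pure singleton-start
  Louvain stalls in local optima on small dense graphs, while the mixed
  strategy attains the exhaustively enumerated maximum on all 100 random
  8-node test graphs (4140 partitions each).

"Most consistent modules" over many stochastic runs is not a uniquely
defined procedure; `consensus_partition()` implements agreement-matrix
consensus (Lancichinetti–Fortunato): run Louvain `n_reps` times, form the
co-assignment frequency matrix, zero entries below $\tau = 0.5$, re-cluster
the thresholded agreement matrix, and iterate until every run agrees
(equivalently, the agreement matrix is block-binary). The alternative — the
modal partition — is brittle when no single labelling recurs; co-assignment
consensus degrades gracefully and is the standard in the connectomics
toolboxes. The default resolution is $\gamma = 1$, with a robustness grid of
0.8–1.4 in steps of 0.1 mirroring the regime from two modules down to
singleton modules.

## Node metrics

Strength is the signed row sum by default (`weights = "positive"`
available); participation is computed on positive weights, with $P_i = 0$
for zero-strength regions; within-module connectivity is the *signed* mean
weight to same-module regions, `NA` for singleton modules (an empty mean, not
zero). Hubness is the first principal component of the z-scored
(regions × 2) strength/participation matrix via the 2 × 2 correlation
eigendecomposition, signed to correlate positively with strength; the
variance explained is reported because a low value would mean the two hub
criteria disagree and the composite is uninterpretable.

## Stage changes and regression

Stage changes are plain later-minus-earlier differences. Because acute
(3 months − pre) and chronic (12 − 3 months) changes share the middle scan,
chronic changes are residualised on acute changes by OLS before modelling
(`residualize_chronic()`), and the acute–chronic relationship itself is
tested against the shared-timepoint null rather than zero:
`shared_timepoint_null()` draws three independent standard-normal
pseudo-scans per simulation, forms both difference maps, and records the
slope t statistic of chronic on acute. For iid equal-variance scans
corr(B − A, C − B) is −0.5 analytically, and the simulated mean matches to
within Monte-Carlo error — the null is centred near $t \approx -5$ at
$n = 78$, which is why comparing against zero would be badly miscalibrated.
The scan-value distribution is taken as standard normal; the recorded t
statistic is location- and scale-invariant, so only the shape assumption is
substantive. Empirical p-values use the +1-corrected rank rule
$p = 2\min(\#\{T \le t\}, \#\{T \ge t\} + 1)/(n_{sims}+1)$, capped at 1, so
finite simulation never reports $p = 0$.

`stepwise_regression()` is forward–backward selection from the
intercept-only model, driven by partial-F (equivalently coefficient-t)
p-values with `p_enter = 0.05` and `p_remove = 0.10` — the canonical
defaults of the environment the emulated analysis ran in, both
configurable. Predictors are z-scored before selection so betas are
comparable across predictors; the response keeps its own units. Ties are
broken by candidate order (documented; selection is order-invariant in the
absence of ties, which holds almost surely for continuous data). For
candidates left out of the final model the reported t and p are
add-one-candidate partial statistics relative to the final model, matching
the convention of reporting test statistics for non-selected predictors.
Whether the original analysis was forward-only is unstated; forward–backward
is the stricter default and reduces to forward selection whenever nothing
ever crosses `p_remove`. Type-I calibration was checked by simulation: under
a global null at $n = 78$ each candidate enters the final model in ≈5% of
1000 datasets.

`beta_difference_test()` implements the full-versus-subset comparison: per
permutation each region's dependent value is drawn independently from the
full or subset dataset with probability ½ (the exchange scheme is unstated
in the emulated design; independent Bernoulli mixing is the natural
exchangeable choice), the stepwise regression is rerun *in full* (selection
is part of the procedure under test, so it is never frozen at the reference
model), and beta differences from the full-data reference are accumulated,
with unselected predictors contributing exact zeros. Significance is the
observed difference falling outside the middle 95% of the permutation
distribution.

## Lesion volumetry

`lesion_percent()` handles both table conventions: remaining-volume records
(percent lesioned = $100(1 - v/v_{ref})$) and directly measured lesion
volumes ($100\,v/v_{ref}$). Reporting rounds half away from zero at two
decimals; full precision is kept internally. The mean row of
`lesion_table_summary()` averages the rounded per-subject percents — the
convention that reproduces the printed mean row exactly; with a shared
reference volume the alternative (percent of the mean volume) differs only
in the third decimal. A remaining volume exceeding its reference warns and
clamps to 0% with a flag rather than reporting a negative lesion.

## The synthetic-data generator

`generate_study()` builds studies whose statistical structure matches what
the analysis assumes, with complete ground truth:

- **Modules:** four planted blocks (20/20/19/19 by default) with within/
  between mean weights 0.6/0.1 and symmetric weight noise sd 0.05 — a
  signal-to-noise regime at which consensus clustering should recover the
  planted partition exactly, which the tests assert via adjusted Rand index.
- **Hubs:** the top 15% of regions on the hubness gradient get their
  between-module weights boosted (×1.5), raising both strength and
  participation. Boosting between-module rather than within-module edges
  keeps hub weights inside correlation range and makes hubs *connector*
  hubs, the intended sense.
- **Predictors:** four per-region gradients drawn with a target correlation
  structure (neuron–hubness +0.4, non-neuronal–hubness −0.3,
  neuron–non-neuronal +0.2 by default), moving-average smoothed along the
  region index (window 5, reflecting edges) to mimic smooth cortical
  gradients, re-standardized, then mapped to natural scales (strictly
  positive densities around 60,000 and 40,000 cells per unit volume; seed
  connectivity around 0.15 correlation units).
- **Planted changes:** each stage change equals
  `effects × z-scored predictors + N(0, noise_sd)` in standardized units,
  converted to metric units by `change_scale` (0.05 correlation units per
  standardized unit by default; 0.02 for log-Jacobian). The injection is
  *exact* for within-module connectivity — a closed-form additive edge
  perturbation per module (solvable for module size ≥ 3) makes each
  region's measured within-module change equal its planted value to machine
  precision — and exact for log-Jacobian volumes (a direct vector series).
  For the participation coefficient, which is nonlinear in edge weights, the
  between-module edge perturbation is directional: planted and measured
  changes correlate strongly but magnitudes are approximate. End-to-end
  parameter-recovery claims therefore use the within-module metric.
- **Subjects and scans:** per-subject matrices add symmetric noise (sd 0.02)
  to the group structure; `mode = "timecourse"` instead samples 988 Gaussian
  timecourses from the (nearest-PSD) planted correlation structure and
  correlates them, adding realistic sampling noise. Default timecourse
  length matches one resting-state run of the emulated acquisition.
- **Range handling:** the generator errors if the *systematic* structure
  (block means plus noise-free planted effects) leaves [−0.99, 0.99];
  stochastic tails are saturated at ±0.999. This separates configuration
  errors (always reported) from rare noise excursions (absorbed, since a
  hard error on a 4.5-sd tail event would make large simulation sweeps
  unusable).

What the generator does **not** emulate: spatial autocorrelation on a
cortical surface, hemodynamics and scanner noise spectra, motion artifacts,
inter-subject registration error, or lesion-induced signal dropout. Passing
tests therefore demonstrate the correctness and calibration of the
*statistical machinery* under the stated generative assumptions, not
robustness to the full messiness of real imaging data.

## Validation scales and numerical choices

The test suite validates at these problem sizes, chosen to exercise the
study scale ($n = 78$) while keeping the suite quick to run: exhaustive
modularity enumeration on 8-node graphs (4140 partitions, 100 graphs, 100
restarts each); 1000 simulations for null calibrations; 1000 null datasets
for stepwise type-I; 500 synthetic studies for end-to-end recovery
(selection rate ≥ 80% and mean beta bias ≤ 10% are the asserted bars;
observed: ~100% and <1%); 100 replicates at 2000 permutations for
beta-difference power. The standalone `scripts/acceptance.R` uses 200
recovery replicates and 50 power replicates — tighter but still
Monte-Carlo-stable sizes for a quick single-command reproduction. The
end-to-end recovery study uses `change_scale = 0.04` so that every seed's
systematic structure stays inside correlation range; the standardized
conditions (effect 0.5, noise 0.5) and the reported rates are invariant to
this unit choice.

Other numerics: symmetry tolerance 1e-8 on matrix read (averaging W with
its transpose below that); write precision 17 significant digits
(round-trips bit-close at 1e-12); strict-gain move rule with 1e-12 slack in
Louvain tie comparisons; consensus iteration cap 50 with an informative
error reporting mean agreement; Cholesky-based OLS with a rank check that
names perfectly collinear candidate sets.

## Known limitations

- Participation-change injection is directional, not exact (above).
- The consensus procedure assumes the co-assignment matrix eventually
  becomes block-binary; adversarial matrices with genuinely ambiguous
  structure hit the iteration cap and error rather than returning an
  arbitrary labelling.
- Stepwise regression inherits the known inferential caveats of data-driven
  selection: reported p-values for selected predictors are conditional on
  selection. The package reproduces this modelling choice faithfully rather
  than replacing it; the permutation and simulation nulls are the
  compensating safeguards.
- `n_modules` and metric values at extreme resolutions (γ ≥ 1.4, singleton
  modules) are returned but within-module connectivity is then all-`NA` by
  the empty-mean convention.
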