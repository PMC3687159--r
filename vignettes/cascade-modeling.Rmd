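---
title: "Modeling three-layer transcriptional cascades with masked neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling three-layer transcriptional cascades with masked neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascann)
```

## The model and its assumptions

A transcriptional cascade here is a three-layer directed graph: upper-layer
transcription factors (TFs) regulate the genes encoding a module's direct
regulators (the middle layer), which regulate a target gene. `cascann`
fits, per target gene, a feed-forward network whose topology equals that
graph: one input per upper TF, one logistic-sigmoid hidden node per middle
TF, a linear output node, and input-to-hidden weights pinned to exactly
zero wherever the cascade has no edge. The hidden nonlinearity stands in
for the saturating, combinatorial way middle-layer TF activity responds to
its own regulators; the linear output reflects that log-ratio expression
of a target is modeled as an additive combination of its regulators'
activities.

The implicit assumptions are worth stating:

* *Expression is a usable proxy for activity.* The model sees only mRNA
  log2 ratios; post-translational activation is unobserved. The time-shift
  search (below) relaxes this in one specific way — a constant
  per-regulator lag — and the heterodimer extension in another
  (constitutively transcribed partners with condition-specific activity).
* *The wiring is given, not learned.* Modules and edges come from binding
  data and curated edge lists; the network never adds or removes an edge.
  What is learned is only the quantitative sign/strength along fixed
  edges.
* *Experiments are exchangeable sampling units.* The evaluation protocol
  splits individual experiment columns (after replicate averaging) at
  random, mirroring the source protocol's wording and counts. Adjacent
  time points of one condition can land on both sides of a split, so a
  correlated-samples optimism is inherent to the protocol; the
  output-shuffle null, which inherits the same structure, is the guard. A
  split-by-condition-block option was considered and deliberately left
  out of the default to keep the protocol and its published interpretation
  aligned.

## Data handling

Expression values are taken as-is ("no further normalization"): the reader
performs no rescaling, and missing values (empty cells or `NA`, never a
sentinel number) stay distinguishable from zero because the module
finder's missingness rule needs them. Replicate experiments are averaged
(mean of non-missing values) *before* any modeling, so replicates of one
measurement can never straddle a train/test split. Experiments are then
partitioned into stress categories, dropping excluded conditions (e.g.
over-expression and knockout series); every downstream step is
per-category.

## Module discovery

The module finder is a faithful re-implementation of the published
heuristic's outline, with its stated defaults:

| parameter | default | meaning |
|---|---|---|
| `stringent_p` | 0.001 | binding cutoff forming core sets |
| `relaxed_p` | 0.01 | per-regulator relaxed cutoff for extension |
| `missing_frac_max` | 0.20 | rejection threshold ("more than 20 %" missing; the boundary is kept) |
| `min_core_size` | 3 | minimal initial core |
| `coherence_radius` | `0.8 * sqrt(m)` | expression-distance threshold over `m` experiments |

Two pieces the outline leaves open were fixed as follows and are fully
configurable:

* *Coherence metric.* Genes are row-normalized (z-scored per gene across
  the category, matching the row-wise pre-processing option the original
  pipeline enabled) and compared by Euclidean distance to the core's mean
  profile, with pairwise deletion of missing entries rescaled to the full
  profile length. The default radius `0.8·sqrt(m)` admits profiles whose
  average per-experiment deviation from the mean profile is 0.8 z-units —
  loose enough to tolerate measurement noise, tight enough that
  uncorrelated profiles (expected distance `sqrt(2m)`) are excluded.
* *Combined p-value.* The extension step multiplies the candidate's
  p-values across the module's regulators and requires the product to be
  strictly below `relaxed_p^|R|` ("less than" the relaxed cutoff — the
  strict inequality matters: a regulator with p = 1 must always block
  extension). Missing binding p-values fail every cutoff.

Core sets are the deduplicated per-gene stringent regulator sets; modules
are not exclusive (a gene may belong to several), matching the heuristic's
silence on exclusivity.

## Cascade assembly

An edge (TF → gene) is believed only if a binding site lies within the
promoter window: offsets 1 to `window_bp` (default 1000) base pairs
upstream of the transcription start, boundary inclusive — the source
states only "1000 bp upstream", and the inclusive reading keeps the
filter's semantics monotone and unsurprising. Modules with at least two
regulators are extended upward: the upper layer is the union of the middle
TFs' upstream regulators. A module is dropped when that union is empty
(unknown regulators), exceeds `max_upper = 15` ("plentiful"), when a
middle TF would receive no input edge (its hidden node would be
disconnected), or when a TF would sit in both layers (the mask must stay
acyclic; the source is silent, exclusion is the conservative choice). One
cascade is emitted per member gene — same graph, different output.

## Training and evaluation

Levenberg–Marquardt minimizes the mean squared error over the free
parameters only; masked weights are not in the parameter vector, so they
are zero before, during and after training by construction. The Jacobian
is analytic (logsig chain rule); finite differences exist solely as a test
oracle. Defaults follow the common Matlab-toolbox-style settings, since
the source names only the algorithm: initial damping `1e-3`, up/down
factors 10 and 0.1, damping overflow at `1e10`, at most 100 epochs, 10
step retries per epoch, and validation patience 6. The returned weights
are those with the best validation MSE seen (early stopping), not the last
epoch's.

The protocol: `n_reps` (default 100) random 50/25/25 splits; per split a
fresh uniform[-0.5, 0.5] initialization; the score is the Pearson
correlation on the test partition, averaged over repetitions; success is
`mean r > 0.7` (strict). Numerical edge cases: a degenerate constant
prediction scores r = 0 with a `degenerate` flag rather than erroring, so
aggregation never aborts; samples with a missing input or target are
dropped listwise; fewer than 8 complete samples is an error (every
partition must be non-empty).

One protocol parameter is this package's own addition: `n_starts`
(default 3). Each repetition trains from `n_starts` seeded initializations
and keeps the one with the best *validation* MSE. With training sets of
only a handful of samples, a single LM run occasionally converges to a
catastrophic local minimum (test r near −1); restarts selected on
validation data remove that failure mode without ever touching the test
partition. Setting `n_starts = 1` recovers the plain protocol.

## Time-shifted (asynchronous) regulation

Each upper TF's profile may be shifted `k_i` steps backwards within each
condition's own time grid; a sample pairs the target at time index `j`
with TF `i` at `j - k_i` and exists only when every `j - k_i >= 1` — a TF
can never appear to act after its target responds. Two inconsistencies in
the source description were resolved as follows (and flagged, not silently
chosen):

* The stated bound `0 < k < n-1` contradicts the accompanying worked
  examples, which show `k = 0` and `k = n-1`; the inclusive range
  `0 <= k <= n-1` is implemented, with `n` the smallest multi-time-point
  condition in the category (single-time-point conditions are excluded
  from the bound and contribute samples only to the unshifted design).
* The stated count "n·N combinations" is inconsistent with independent
  per-TF shifts; the full cross product `(n)^N` is enumerated, with a cap
  (default 1e5) that aborts with guidance rather than running forever.

The search evaluates every assignment with **common random numbers**: all
assignments share the split and initialization streams, so assignments
with equal sample counts are compared on identical partitions. (An earlier
design with independent per-assignment streams suffered winner's-curse
ranking errors across the dozens of candidates; the shared-stream design
also makes the all-zero assignment reproduce the synchronous evaluation
exactly.) Ties are broken toward smaller total shift, then enumeration
order. Assignments leaving fewer than 8 samples are recorded as `NA` and
never best. More than one assignment typically clears the success
threshold; all are reported.

## Heterodimers

For single-regulator modules, interaction partners of the regulator are
screened: a partner is usable iff binding data exist for it and its
expression in the category is constitutive — at least 95 % of non-missing
points within twofold, interpreted on log2 data as `|value| <= 1` with
both boundaries inclusive ("at least", "not more than"). A usable partner
becomes a second hidden node; its upstream regulators merge into the upper
layer (union semantics; the source does not say whether shared upper TFs
were merged or duplicated, and a set-valued upper layer forces the union).
The partner's own expression never enters the model — inputs remain the
upper layer only, which is exactly the point: a constitutive partner is
invisible in expression but visible through its regulators.

The control replaces the partner with randomly chosen TFs having the same
upstream-regulator count, so every control network has the identical free
parameter count; an improvement specific to the true partner therefore
cannot be a flexibility artifact.

## The synthetic world

`generate_bundle()` emulates all five inputs from a planted truth:

* Upper-layer TF profiles are per-condition random walks (step SD 0.5 log2
  units) — *not* white noise, because a delay is unidentifiable in
  principle from memoryless profiles. Walks are simulated `max(shift)`
  steps before the first observed time point, so the planted lag structure
  holds exactly at every observed sample (clamping lags at the boundary
  would leak synchronous signal into early time points).
* Middle-TF activity is the logistic readout of the planted, shifted
  weights, rescaled affinely to roughly [−2, 2] log2 units so both layers
  live on realistic microarray scales; module genes share the target's
  generating function plus independent Gaussian noise (default SD 0.05);
  background genes are independent walks; constitutive TFs are near-zero
  profiles clipped within twofold.
* Binding p-values are 1e-4 on true regulator–module pairs and
  Uniform(0.3, 1) elsewhere; true edges carry a binding site at 500 bp,
  decoy edges only at 1500 bp; interaction pairs cover the planted dimer
  plus screening decoys.

What this does **not** emulate: replicate-level microarray noise models,
missing-data patterns of real arrays, biophysical transcription kinetics,
overlapping/correlated modules, and condition-dependent dimer affinity. A
green test on these worlds therefore establishes that the machinery
recovers what it is designed to recover under its own assumptions — not
that those assumptions hold in any particular organism.

Fixture design notes (each chosen once, from identifiability reasoning):

* `planted_delays` uses a *single* hidden node and explicit planted
  weights (1.5, 1.2, −1.3). With randomly drawn weights a TF can receive a
  near-zero coefficient, making its delay unidentifiable by construction;
  with two hidden nodes the free-parameter count (11) exceeds the shifted
  designs' training-set size (6), so every assignment interpolates and
  ranking becomes noise.
* `planted_dimer` uses 12 conditions × 4 time points (≈ 48 experiments,
  the scale of a real per-category stress compendium) and interaction
  strength 3 against a single-TF readout weight of 0.5, so the planted
  multiplicative effect dominates the additive one.
* `pure_noise` replaces the module genes with standard normal noise on a
  15 × 8 grid — the null world for calibration tests.

## Reproducibility

Every random stream is derived from one integer seed through a
deterministic string-keyed hash (global → stage → cascade → repetition →
restart), so stages can re-run independently yet byte-identically, and two
pipeline runs with the same configuration produce identical report files.
Thread count is accepted by the CLI but never affects results.

## Known limitations

* Training sets under the 50/25/25 protocol can be very small for deep
  shift assignments; mean correlations at those depths carry wide
  sampling error even with restarts (the reason `search_shifts` reports
  every assignment, not just the winner).
* No multiple-testing correction across cascades is applied, matching the
  source protocol.
* The per-column split ignores temporal autocorrelation within conditions;
  interpret synchronous success rates as optimistic upper bounds and lean
  on the shuffle null for significance.
* Module discovery is a faithful outline-level re-implementation, not a
  bit-exact clone of the original tool; externally produced module tables
  in the same TSV schema can be substituted at the `cascades` stage.
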