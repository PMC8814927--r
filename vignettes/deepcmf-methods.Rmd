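---
title: "Methods: collective factorization, knowledge-graph similarity, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collective factorization, knowledge-graph similarity, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: the models it
fits, the parameters that matter, the synthetic data the tests run on, and
the numerical and design choices made where more than one reasonable
option existed. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## 1. The collective model

### Input transformation

A *collection* is a set of numeric views `X_m`, each relating a row
entity `r_m` and a column entity `c_m`; entity dimensions are inferred
from the view shapes and cross-checked (`matrix_collection()`). For every
entity `e` the *concatenated matrix* `C^(e)` assembles all views touching
`e`: views with `e` on the rows enter as-is, views with `e` on the
columns enter transposed, and a square self-view (e.g. a
disease-by-disease similarity matrix) enters exactly once, as-is. Blocks
are ordered by ascending view id. No order is canonical for learning —
any fixed order gives an equivalent model — but a deterministic order is
what makes seeded fits reproducible and lets `extract_view_block()`
recover every original view bit-exactly, which the tests rely on.

### Network and objective

Each entity gets one autoencoder: an affine encoder into a bottleneck of
width `k` (`latent_dim`) and an affine decoder back to the input width,
with tanh activations by default and a linear decoder output. Extra
hidden layers can be configured (`hidden_sizes`) but the default
architecture has the bottleneck as its only hidden layer. The joint
objective sums three groups of terms:

* entity reconstruction `ℓ_E`: mean squared error between `C^(e)` and its
  decoding;
* view reconstruction `ℓ_R`: mean squared error between `X_m` and
  `U_{r_m} U_{c_m}'`, where `U_e` is the bottleneck activation of `C^(e)`
  (for a self-view the term is `U_e U_e'`);
* optionally a task loss `ℓ_T` on an affine head over one entity's
  bottleneck.

Every term is normalised by its element count. The losses are named
abstractly in the collective-factorization tradition; squared error is
the Frobenius-norm choice that makes the unsupervised model a nonlinear
generalisation of classical collective matrix factorization. Per-element
normalisation keeps a 500 × 40 view from drowning a 40 × 40 one; the
weights `w_E, w_R, w_T` (`loss_weights`, default 1, 1, 1) remain exposed
because no principled universal ratio exists.

Training is full batch: a single optimizer step updates every network
from the joint gradient, which is what couples the factors across views.
Full batch avoids sub-sampling bias in `ℓ_R` (mini-batching over rows of
one view implicitly re-weights the coupled entity on its other side) and
is cheap at desk scale. The optimizer is Adam (learning rate `1e-5`,
weight decay `1e-6` by default, matching the reference experimental
settings for this architecture; every synthetic experiment in this
package sets a larger rate explicitly because desk-scale matrices
converge in seconds at `5e-3`–`2e-2`). Parameters initialise from a
fan-in-scaled uniform distribution drawn from the seeded generator in a
fixed order — encoders and decoders in entity order, the task head last —
so equal seeds give bit-identical fits, and attaching a head never
perturbs the autoencoder initialisation. A non-finite loss aborts with a
diagnostic naming the epoch and worst term rather than silently
continuing.

### Supervised mode

`dcmf_task()` attaches labels for one entity; a single affine layer maps
that entity's bottleneck to the outputs (sigmoid + cross-entropy for
binary, softmax + cross-entropy for multiclass, linear + MSE for
regression). Primary-diagnosis-style category labels are mutually
exclusive, so the multiclass head is single-label softmax; an
independent-sigmoid multilabel mode (`kind = "multilabel"`) is provided
for genuinely multilabel targets. With `w_T = 0` the head receives no
gradient and the encoder trajectory is bit-identical to the unsupervised
fit — a tested invariant. Prediction encodes new rows supplied in the
same concatenated coordinates and applies the head; there is no
transductive refitting at prediction time. Dropout and denoising
corruption are deliberately absent from the collective model (they
belong to the SDAE baseline, where the reference settings specify them).

## 2. GRA similarity and the knowledge graph

The global resource allocation similarity of two nodes sums, over all
paths of length `l ≤ L` between them, `β^l` times the reciprocal product
of the intermediate nodes' degrees. Defaults are `β = 0.5` and `L = 3`:
the decay constant is the convention of the framework this measure
generalises (any `β ∈ (0,1)` satisfies the requirement that shorter
paths weigh more), and a horizon of 3 is where path enumeration stays
exact yet affordable on dense clinical graphs — both are exposed.

Two modes exist. `simple_path` (default) enumerates simple paths by
depth-first search and is exact; the independent oracle
`gra_bruteforce()` recomputes the same sum from `igraph`'s path
enumeration and agrees to `1e-12` on randomized graphs in the tests.
`walk` evaluates the truncated series `Σ_l β^l A (D⁻¹A)^(l-1)`, which
admits revisiting walks — an upper bound on the simple-path score, and an
approximation of the path formulation — but runs on graphs where
enumeration is hopeless. Degrees always count all edges of the full
heterogeneous graph, and paths may pass through nodes of any type, so a
medication can mediate similarity between two diseases.

`S(i, i)` is set to 0 by default (similarity is defined for distinct
nodes); `diagonal = "rowmax"` is available because a zero diagonal is a
statement (`‖u_i‖² ≈ 0`) when the matrix is later factorized. In the
experiment harness the issue is neutralised differently — by
standardizing views (below), which removes the diagonal's mean along
with everything else's.

Triplet filtering mirrors the standard cleaning of literature-derived
predication extracts: a configurable excluded-predicate list (defaults
`PART_OF`, `LOCATION_OF`, `PROCESS_OF` — ontological relations that do
not connect clinical concepts in the intended sense), removal of
NEG-prefixed (negated) predicates, and restriction of both endpoints to
the concept vocabulary; predicates are upper-cased before matching. The
graph keeps only the existence of a relation: multiple predicates
between a pair collapse to one undirected edge and self-relations are
dropped. Concepts present in a patient view but absent from the graph
receive zero similarity rows, so square views stay aligned with the
patient-view columns.

## 3. Concept matrices and TF-IDF

`concept_matrix()` turns per-episode mention records into views: disease
matrices are binary (presence of the concept in the episode), medication,
procedure and lab matrices are counts. `tfidf()` weighs concept `j` in
episode `i` as `tf(i,j) · idf(j)` with smooth
`idf(j) = ln((1+N)/(1+df_j)) + 1` by default — finite even for an unseen
concept, and the dominant convention in standard text-vectorization
tooling — with plain idf and log-tf variants selectable and recorded in
the output's metadata. Zero cells stay zero. The synthetic pipeline
applies TF-IDF to all three notes views, including the binary disease
view (the transform is described for the matrices collectively, and the
binary case is well defined); it is a switch, not a commitment. No row
normalisation is applied. Structured prescription/lab views are ingested
as counts and not TF-IDF transformed.

## 4. The synthetic study design

The generator plants ground truth and builds everything from it, so every
test has an oracle. Per entity a factor matrix `U*_e` (standard normal,
rank `k*`) is drawn; each view is `U*_r U*_c' + ε` with Gaussian noise,
then linked to its value kind: counts by `round(exp(0.5 · x))` (skewed,
dispersed, non-negative — chosen so TF-IDF has something realistic to
do), binaries by thresholding at the median (density ½). The knowledge
graph draws an edge between concepts `u, v` with probability
`plogis(-2 + 6 cos(u*, v*))`, so graph proximity reflects latent
similarity *by construction* — the property the knowledge-graph views'
value relies on — plus small fractions of negated and excluded-predicate
noise triplets so the filter has work to do. Labels are Bernoulli draws
from `plogis(scale · U*_p b + c)` with `b` standard normal and the
intercept tuned to a target prevalence; the returned Bayes accuracy
(Monte-Carlo, fresh draws) bounds any classifier.

Default conditions, chosen once: 500 patient episodes; 40 diseases, 30
medications, 20 procedures, 15 labs; `k* = 3`; noise sd 0.5; coefficient
scale 1. Two defaults deserve their rationale spelled out:

* **Prevalence defaults to 0.5.** A mortality-style 12% base rate is
  available as a knob, but with scale-1 logistic labels it leaves the
  Bayes accuracy only ~0.6 points above the majority rate: accuracy then
  cannot distinguish any two reasonable methods, and directional
  comparisons between arms degenerate into ties. Balanced labels keep
  the generative mechanism identical and make accuracy an informative
  metric.
* **Coefficients are unnormalised** (`b ~ N(0,1)`, so the linear score
  has standard deviation ≈ `scale·√k*`). Normalising by `√k` would
  shrink the signal as the rank grows and make the task mostly label
  noise at `scale = 1`.

Components use independent seeded streams: changing the graph seed
leaves views and labels bit-identical.

What the generator does *not* emulate: clinical text (concept counts are
synthetic, not extracted), temporal structure, missing data, the extreme
sparsity and vocabulary size (thousands of concepts) of real note-derived
matrices, or incompleteness and noise of a real literature graph. Passing
tests therefore show that the machinery recovers planted structure and
that the directional relationships between arms hold under these
conditions — not that they transfer to any particular clinical corpus.

## 5. The evaluation harness

The protocol is 90/10 train/test splits, three seeded repeats, metrics
averaged (accuracy, macro F1, weighted F1; AUC for binary tasks by the
Mann–Whitney rank statistic, reported as `NA` on a degenerate single-class
split rather than failing the repeat). Unsupervised arms (SDAE, ALS-based
collective factorization, unsupervised DCMF) learn representations once
from *all* instances — the transductive reading of
learn-representations-then-classify — and hand train-split rows to a
downstream classifier (logistic regression or random forest with library
defaults and fixed seeds). The supervised arm refits on each training
split and predicts held-out rows through its head; its held-out inputs
are never seen with labels. The SDAE accepts one matrix and is therefore
valid only where no square knowledge-graph views are present (view 1);
the harness rejects other combinations with an error listing the valid
arms. The ALS baseline is a self-contained reimplementation of classical
collective factorization (ridge-regularised alternating least squares on
the concatenated systems), not a wrapper around any existing package.

Two harness choices matter enough to flag:

* **Standardization.** `run_experiment()` centers each view's columns
  and scales by the view's overall standard deviation before any model
  sees it. Raw TF-IDF, count and adjacency-like similarity matrices are
  non-negative with a large mean/density component; left in place, that
  component occupies the leading latent dimension of every factor and
  factor recovery collapses. Centering is the matrix-factorization
  analogue of centering before PCA. Centering statistics come from all
  instances' inputs, consistent with the transductive protocol; labels
  play no part.
* **A compressive bottleneck.** The harness default is `latent_dim = 2`
  against the generator's default rank 3. When the representation cannot
  keep everything, unsupervised compression keeps what reconstructs
  views best, while supervised training keeps what predicts — which is
  precisely the mechanism by which end-to-end supervision earns its
  advantage over the two-stage pipeline. With `latent_dim ≥ k*` both
  arms saturate and the comparison collapses to noise. Task weight
  defaults to 2 in the harness because the task term is a per-instance
  mean while the reconstruction terms are sums over views.

The knowledge-graph (view 2 vs view 1) comparison deserves honesty about
its effect size: on the default conditions the mean supervised gain from
adding similarity views is positive but small — of the same order as
seed-to-seed variation (held-out sets are 50 episodes) — so while the
direction is reproducible at the tested seeds, individual seeds can go
either way. The supervised-vs-two-stage gap is larger and stable in
direction across the configurations examined.

## 6. Numerical notes and problem sizes

Exact-recovery tests use linear activations, where the model is a
collective linear factorization and a noiseless planted-rank collection
is recoverable to numerical accuracy; the tests run 40/30/20-dimensional
entities with rank 2 and a 10000-epoch Adam budget at rate 0.02 annealed
by a per-epoch factor of 0.9995 (a constant rate leaves Adam oscillating
near the optimum on some instances; the annealed budget recovers every
instance examined to three decimal places or better), about fifteen
seconds per seed. Directional comparisons run the default 500-episode bundle over
five seeds with three splits each; the whole acceptance computation
completes in a few minutes on one CPU. These sizes are the package's
chosen desk-scale study conditions: large enough for the properties to be
meaningful, small enough to be re-run routinely.

Ties in argmax predictions resolve to the first class
(`max.col(ties.method = "first")`); cross-entropy clamps probabilities at
`1e-12`; the brute-force GRA oracle refuses graphs above 12 nodes;
degenerate collections (an entity in no view, conflicting dimensions,
disconnected view groups) are caught by `validate_collection()` — errors
for invariant violations, warnings for connectivity and constant
columns.

## 7. Known limitations

Dense full-batch training bounds practical problem sizes (roughly 10⁴
rows per entity on one CPU); there is no missing-data mask, no tensor or
time-indexed views, no GPU path, and no automated hyperparameter
scheduler (a seeded random-search helper, `dcmf_random_search()`, stands
in for one deliberately). Simple-path GRA is exponential in the horizon;
walk mode is the scalable stand-in and is flagged as an approximation.
The SDAE baseline implements a single hidden layer — sufficient for its
role as the single-source reference arm, not a general deep-SDAE.
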