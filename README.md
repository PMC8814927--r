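# deepcmf

Patient representation learning from heterogeneous relational data by
**deep collective matrix factorization (DCMF)**, with **knowledge-graph
similarity views**.

Clinical data rarely arrives as one matrix. A cohort of patient episodes
comes with disease, medication and procedure concept matrices extracted
from notes, structured prescription and laboratory tables, and — from the
biomedical literature — knowledge graphs relating the same clinical
concepts to each other. `deepcmf` learns one low-dimensional
representation per *entity* (patient episodes, diseases, medications,
procedures, labs) from an arbitrary collection of such matrices, and lets
graph-derived similarity matrices join the collection as additional square
views, so literature knowledge is infused directly into the patient
representations.

## The model

Given `M` matrices (views) `X_m` over `E` entities, where view `m` relates
the entities `r_m` (rows) and `c_m` (columns), DCMF learns a factor matrix
`U_e` (of rank `k`) per entity such that every view is approximated by the
product of its two entity factors:

```
X_m  ≈  U_{r_m} U_{c_m}'          for every view m
U_e  =  f_θ(C^(e))                for every entity e
```

where `C^(e)` is the *concatenated matrix* of entity `e` — all views
containing `e` side by side, transposed where `e` indexes the columns —
and `f_θ` is an entity-specific autoencoder whose bottleneck of width `k`
is read out as `U_e`. All `E` autoencoders are trained *collectively* on
the joint objective

```
L = w_E Σ_e ℓ_E(C^(e), C^(e)')  +  w_R Σ_m ℓ_R(X_m, U_{r_m} U_{c_m}')  [ +  w_T ℓ_T(y, y') ]
```

with mean-squared reconstruction losses and, optionally, a task loss
`ℓ_T` on a single affine head attached to one entity's bottleneck
(sigmoid/cross-entropy for classification, linear/MSE for regression).
With the head the model is an end-to-end *supervised* predictor; without
it, factors feed any downstream classifier (the two-stage pipeline).

Knowledge-graph structure enters through the **global resource allocation
(GRA)** similarity: for nodes `i, j` of an undirected graph, every path of
length `l ≤ L` between them contributes the reciprocal of the product of
its intermediate nodes' degrees, discounted by `β^l`:

```
S(i, j) = Σ_{paths p: i→j, |p| ≤ L}  β^|p| / Π_{v interior of p} k(v)
```

Short paths through low-degree (specific) nodes dominate; hub nodes are
damped. Per-type similarity matrices computed from a filtered
subject–predicate–object triplet graph become square views (`disease ×
disease`, ...) in the collection.

## Worked example

Simulate a synthetic cohort with known latent structure, then compare the
two-stage pipeline (unsupervised DCMF + logistic regression) against the
end-to-end supervised model with knowledge-graph views:

```r
library(deepcmf)

spec   <- synth_spec(n_patients = 200, seed = 42)
bundle <- simulate_bundle(spec)
bundle
#> <dcmf_bundle> 200 patients, rank 3, seed 42
#>   view1: 3 views, 4 entities
#>   view2: 6 views, 4 entities
#>   view3: 8 views, 5 entities
#>   labels: prevalence 0.530, Bayes accuracy 0.698

run_experiment(bundle, view = 1, model = "dcmf", classifier = "lr",
               split_seed = 42, model_seed = 42)
#> <metrics_report> dcmf, view 1, classifier lr (3 repeats)
#>   accuracy 0.4833 | macro F1 0.4568 | weighted F1 0.4898 | AUC 0.4177

run_experiment(bundle, view = 2, model = "dcmf_supervised",
               classifier = "none", split_seed = 42, model_seed = 42)
#> <metrics_report> dcmf_supervised, view 2, classifier none (3 repeats)
#>   accuracy 0.7500 | macro F1 0.7083 | weighted F1 0.7483 | AUC 0.7375
```

`view1` holds TF-IDF concept matrices from simulated notes; `view2` adds
one GRA similarity view per concept type from a simulated knowledge graph;
`view3` adds structured prescription and lab count views. The labels are
Bernoulli draws from a logistic model on the true patient factors, so the
printed Bayes accuracy (0.698) bounds what any classifier can achieve in
expectation; per-split accuracies on 20 held-out episodes fluctuate around
it. At this small cohort size the end-to-end supervised model clearly
outperforms the two-stage pipeline.

The model itself follows the usual R idiom — `dcmf()` returns a fitted
object with `print`, `summary`, `coef` (the latent factors), `predict`
(through the task head), `fitted`/`residuals` (view reconstructions) and
`plot` (loss history) methods:

```r
fit <- dcmf(bundle$view1,
            dcmf_config(latent_dim = 2, epochs = 400, learning_rate = 5e-3),
            task = dcmf_task(bundle$labels$y, "patient"))
summary(fit)
head(predict(fit, type = "score"))
```

A thin command-line front end over the same functions is installed at
`inst/cli/deepcmf-cli.R` (subcommands `simulate`, `fit`, `gra`,
`kg-similarity`, `experiment`).

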