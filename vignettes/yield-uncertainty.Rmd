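---
title: "Uncertainty-aware reaction yield prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware reaction yield prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-throughput experimentation produces tables of chemical reactions — a
handful of component molecules combined combinatorially — each annotated with
a measured yield between 0% and 100%. A model that predicts yields for unseen
combinations saves costly syntheses, but raw point predictions are risky:
some reaction subfamilies are intrinsically noisy, and a model trained on a
few thousand examples is genuinely uncertain in sparsely covered regions of
reaction space. `yieldnet` therefore predicts a *distribution* for the yield
of a reaction, separates the two sources of uncertainty, and supports
abstaining from the least trustworthy predictions.

## Data representation

A reaction is a set of $m \ge 1$ reactant molecules and one product, each
converted from SMILES into an undirected graph over heavy atoms. Hydrogens
are implicit: they enter as a per-atom count, never as nodes. Atom features
are the element (one-hot over a vocabulary frozen at configuration time,
with a fallback slot for anything unseen), formal charge, degree,
hybridization, implicit hydrogen count, valence, chirality slot,
hydrogen-bond donor/acceptor flags, aromaticity, ring membership and
ring-size flags (sizes 3–8 plus a "larger" flag). Bond features are the bond
type (single/double/triple/aromatic), a stereochemistry slot, ring
membership and conjugation. The feature lengths $p$ (atoms) and $q$ (bonds)
are fixed by the `feature_config()` and identical for every graph it
produces, so a trained parameter set is self-describing.

Structure perception is delegated to OpenBabel (via ChemmineR/ChemmineOB);
a few features the toolkit does not expose directly are derived by
documented rules:

* *implicit hydrogens*: standard valence + formal charge − sum of incident
  bond orders;
* *hybridization*: a triple bond or two double bonds → sp; a double bond or
  aromaticity → sp2; otherwise sp3;
* *donor/acceptor*: N or O bearing a hydrogen donates; any N or O with
  non-positive formal charge accepts (a Lipinski-style rule);
* *conjugation*: aromatic bonds, or bonds whose two endpoints are both
  sp/sp2;
* *ring membership*: an atom or bond is in a ring exactly when it lies on a
  non-bridge edge of the molecular graph.

The cis/trans stereo slot is encoded in the feature layout but the 2D
perception path does not populate it, and chirality parities are likewise
left at "none"; both are known limitations rather than silent omissions.

## The model

Each graph is encoded by a message passing neural network. Nodes are
embedded linearly into $d$-dimensional states. For each of 3 message passing
steps (weights shared across steps), node $v$ receives

$$ \mathbf{m}_v = \sum_{w \in N(v)} A(\mathbf{e}_{vw})\, \mathbf{h}_w, $$

where the *edge network* $A(\cdot)$ — a two-layer perceptron — maps the bond
feature vector to a $d \times d$ matrix, and the state is updated by a GRU
cell, $\mathbf{h}_v \leftarrow \mathrm{GRU}(\mathbf{h}_v, \mathbf{m}_v)$. A
set2set readout (3 processing steps) pools the node states into an
order-invariant vector: an LSTM cell produces a query, attention weights are
the softmax of query–state dot products, and the attended read vector is fed
back concatenated with the query. A fully-connected ReLU layer "sparsifies"
the pooled vector into the graph representation $\mathbf{r}$.

The reaction representation concatenates the *sum* of the reactant
representations with the product's,
$\mathbf{h} = [\sum_l \mathbf{r}^{R,l},\, \mathbf{r}^P]$, which makes the
model invariant to reactant order (and summation, unlike averaging, keeps
stoichiometric multiplicity informative — duplicating a reactant changes the
representation). A feed-forward head with two hidden ReLU layers and dropout
maps $\mathbf{h}$ to two outputs: the predictive mean $\mu$ and the log
predictive variance $\log \sigma^2$, both in standardized yield units.

The reference configuration uses $d = 64$, graph representations of length
1024 (larger because they are summed over reactants), 512-unit head layers,
and dropout 0.1 on the two head layers only — there is no dropout inside the
graph encoder, so a molecule's representation is deterministic given the
parameters. One graph encoder is shared between reactants and products: the
concatenation already separates the roles, and sharing halves the parameter
count. The width of the edge-network hidden layer is set to $2d$.

## Training

Yields are standardized to mean 0 and variance 1 (population convention)
over the training set only. With $\lambda \in [0, 1]$ the objective blends
two likelihoods:

$$ \mathcal{J}(\theta) = (1-\lambda)\,\frac{1}{N}\sum_i (y_i - \mu_i)^2
 + \lambda\,\frac{1}{N}\sum_i \left[ \frac{(y_i-\mu_i)^2}{\sigma_i^2}
 + \log \sigma_i^2 \right]. $$

At $\lambda = 0$ this is exactly the mean squared error (homoscedastic
maximum likelihood); at $\lambda = 1$ the heteroscedastic Gaussian negative
log-likelihood (its constant $\tfrac12 \log 2\pi$ and global factor
$\tfrac12$ dropped, which changes no minimizer). The default $\lambda = 0.1$
keeps the mean stable while letting $\sigma^2$ absorb input-dependent noise.

Optimization uses Adam, batch size 128, 500 epochs in the reference
schedule: learning rate $10^{-3}$ for the first 80% of epochs, then
$10^{-4}$ and $10^{-5}$ over the final 10% + 10% (400/50/50 at 500 epochs;
the proportional rule lets shorter desk-scale runs keep the same shape). L2
regularization with factor $10^{-5}$ applies to weight matrices, not biases,
and is excluded from the reported loss history, which tracks the data terms
only. The last incomplete minibatch is kept, which matters for very small
training sets. There is no early stopping and no hyperparameter search.

Numerical choices: weights are Glorot-uniform at initialization (the
set2set forget-gate bias starts at 1), $\log \sigma^2$ is clamped to
$[-10, 10]$ before exponentiation — the heteroscedastic loss is notoriously
unstable early in training — with a zero gradient beyond the clamp; the
set2set query is initialized to zeros and attention logits are unscaled dot
products. The predictive mean is not clipped to $[0, 100]$: clipping would
bias the Gaussian likelihood near the bounds.

All gradients are hand-derived matrix backpropagation, verified in the test
suite against central finite differences for every parameter group, and the
message passing recurrence is additionally checked against an independent
brute-force per-node implementation.

## Inference and uncertainty decomposition

At prediction time dropout stays active (MC dropout): $T$ stochastic passes
(default $T = 30$) through the head produce samples
$\{(\hat\mu^{(t)}, \hat\sigma^{2(t)})\}$. The predicted yield is the sample
mean of $\hat\mu^{(t)}$; the predictive variance decomposes as

$$ \mathrm{Var}[y_*] \simeq
 \underbrace{\frac{1}{T}\sum_t \hat\sigma^{2(t)}}_{\text{aleatoric}}
 + \underbrace{\frac{1}{T}\sum_t (\hat\mu^{(t)} - \bar\mu)^2}_{\text{epistemic}}, $$

with the population (1/T) divisor in both terms. The aleatoric part is
irreducible measurement noise learned through the variance head; the
epistemic part is model disagreement induced by dropout, vanishing when
dropout is disabled or $T = 1$. The implementation computes the total as
`aleatoric + epistemic` in that order so the identity holds exactly in
floating point. Since only the head is stochastic, the graph encoder runs
once per molecule and all $T$ passes reuse its output. Each pass draws its
dropout masks on a deterministic child stream of the user seed, so
predictions are bit-reproducible.

Everything is reported on the percent scale: means via
$\mu \cdot s + \bar y$, variances via $\cdot\, s^2$. Because this map is
affine with positive scale it preserves uncertainty rankings, so rank-based
evaluation is unaffected by standardization.

## Evaluation and selective prediction

`regression_metrics()` reports MAE, RMSE and $R^2$;
`spearman_error_uncertainty()` the Spearman rank correlation (average ranks
on ties) between absolute error and an uncertainty score — the standard
proxy for uncertainty-quantification quality. `coverage_curve()` sweeps
selective prediction: at coverage $c$ the $\lceil c \cdot n \rceil$
lowest-uncertainty predictions are kept (a keep-count rule rather than a
score threshold, so exact coverage fractions are reproduced regardless of
ties; ties break by original row order) and MAE/RMSE are computed on the
kept subset. The default grid runs from 100% down to 30%. The uncertainty
score defaults to the total predictive variance, with the aleatoric-only and
epistemic-only components available for ablations.

## The synthetic generator

`synth_spec()`/`generate_reactions()` emulate the statistical structure of
combinatorial yield benchmarks at toy scale: three reactant roles (default 8
"core", 4 "ligand", 3 "base" molecules drawn from a fixed pool of small
valid organics) and one product per core. The base yield of a combination is
50 plus additive per-component effects plus one core×ligand interaction,
clipped to $[20, 80]$; measured yields add Gaussian noise whose standard
deviation depends on the ligand (first half of the ligands: low noise,
second half: high noise; default 2 and 12 percent points) and are clipped to
$[0, 100]$. Keeping base yields inside $[20, 80]$ makes boundary clipping —
and the mild non-normality it introduces — rare. Ground truth (base yield,
noise sd, noise group) travels in `true_*` columns that the CSV writer
never places in training files.

What this emulates: discrete combinatorial structure, a learnable additive
signal with an interaction, group-wise heteroscedastic noise, bounded
yields. What it does not: real reaction chemistry, mechanism, or any
relation between molecular structure and yield beyond component identity —
so passing tests demonstrate that the method recovers designed statistical
structure, not that it understands chemistry. Results on real benchmark
data must be established separately with the CSV loader.

## Desk-scale study sizes

The package's end-to-end experiments (test suite and `scripts/acceptance.R`)
use 2000 synthetic reactions with a 70/30 split, widths reduced about
four-fold from the reference configuration (node 16, graph 256, head 128,
edge hidden 32), 60 epochs, batch 128, $\lambda = 0.1$, $T = 30$, across
five seeds. These sizes were chosen once as the smallest study at which the
designed noise groups separate cleanly; at that scale a fitted model
recovers the two aleatoric noise levels to within a few tenths of a percent
point, the error–uncertainty Spearman correlation is strongly positive, and
halving the coverage roughly halves the MAE.

## Known limitations

* No reaction SMILES (`A.B>>C`) parsing, atom mapping, 3D conformers,
  multi-product reactions, ensembling or post-hoc calibration.
* Stereochemistry slots exist in the feature layout but are not populated
  by the 2D perception path.
* Conjugation and donor/acceptor flags are rule-based approximations.
* The predictive mean is unbounded; downstream users may wish to clip
  reported yields to $[0, 100]$ for display.
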