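---
title: "ddinet: model, design choices and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ddinet: model, design choices and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The prediction problem

A drug–drug interaction (DDI) tuple is a triple $(d_x, d_y, r)$: two
drugs and an interaction type drawn from a finite set. Given drugs as
SMILES strings, the model outputs the probability that the typed
interaction occurs. The working hypothesis — well supported by
pharmacology — is that interactions are driven by a small number of
*substructures* (functional groups, ring systems) rather than by whole
molecules, so the architecture is built to (a) represent substructures
of every radius, and (b) expose which substructure pair drove each
prediction.

## Molecular graphs and featurization

`parse_smiles()` converts a SMILES string into an attributed graph:
atoms are nodes, each chemical bond contributes two *directed* bonds.
OpenBabel (through ChemmineOB) does the chemistry — parsing, kekulized
bond orders, formal charges, aromatic ring perception. Atom features
(42 dimensions): a 16-slot element one-hot (B, C, N, O, F, Si, P, S,
Cl, As, Se, Br, Te, I, At, plus a *meta* slot for anything else), an
11-slot heavy-atom degree one-hot (0–10), a 5-slot hybridization
one-hot (sp, sp2, sp3, sp3d, sp3d2), a 7-slot implicit-valence one-hot
(0–6), and integer radical-electron count, integer formal charge and a
binary aromaticity flag. Bond features (6 dimensions): bond-type
one-hot (single, double, triple, aromatic), a conjugation flag and a
ring flag.

Derived properties follow RDKit's conventions, against which the test
suite freezes reference values for an 18-molecule panel: hypervalent
atoms (e.g. sulfone sulfur) are sp3 and break conjugation; allene is
conjugated; amide nitrogens and carboxyl oxygens are sp2 through
lone-pair conjugation; aromaticity additionally requires ring
membership (OpenBabel's MOL2 writer marks acyclic carboxylate
resonance as "ar", which we reject). Degrees count heavy atoms only;
hydrogens are implicit. Degree > 10 or implicit valence > 6 clamp into
the last slot with a warning; hybridization states outside the five
listed leave the block all-zero with a warning. Multi-fragment SMILES
(salts) are reduced to the largest connected fragment. Known
divergences from RDKit are limited to exotic lone-pair cases (e.g.
aniline-type nitrogen may differ in hybridization); none occur in the
fragment chemistry the synthetic generator emits.

## The substructure-attentive directed message passing encoder

Bond-level hidden states are initialized from both endpoints and the
bond itself,

$$h^{(0)}_{ij} = W_i x_i + W_j x_j + W_{ij} x_{ij},$$

and updated for $T$ steps with the directed-MPNN rule that excludes
the reverse bond,

$$h^{(t)}_{ij} = \mathrm{ReLU}\!\left(h^{(0)}_{ij} + W_m \sum_{k \in
N(i) \setminus \{j\}} h^{(t-1)}_{ki}\right).$$

The update rule is a design choice: the cited directed-MPNN family
defines exactly this form, and reverse-bond exclusion prevents
messages from echoing straight back. Bond importances $\beta$ come
from a self-attention graph-pooling scorer — one graph convolution
(symmetrically normalized adjacency with self-loops) over the *bond
line graph* (two directed bonds are adjacent iff they share an atom) —
and are softmax-normalized **over the incoming bonds of each target
atom**, so each node message

$$m^{(t)}_i = \sum_{j \in N(i)} \beta_{ji} h^{(t)}_{ji}$$

is a convex combination. The normalization scope is a choice (a raw
SAGPool score has no canonical softmax axis); the convex-combination
reading is what makes $\beta$ interpretable as per-bond importance. By
default $\beta$ is recomputed at every step from the freshest states;
`beta_mode = "once"` computes it at step 1 and reuses it, and
`"uniform"` freezes it for ablations.

Each step pools a graph summary $g^{(t)} = \sum_i m^{(t)}_i$, scored by
a per-step attention $e^{(t)} = \langle w^{(t)},
\tanh(W g^{(t)} + b)\rangle$ with softmax weights $\alpha^{(t)}$ across
steps ($w^{(t)}$ is per-step; $W$, $b$ are shared). Because a state at
step $t$ aggregates information from a radius-$t$ neighborhood,
$\alpha$ is a distribution over substructure radii. Final bond features
are $\sum_t \alpha^{(t)} h^{(t)}_{ij}$, and node features pass through a
one-hidden-layer MLP,

$$h_i = f\!\left(W_0 x_i + \sum_{j \in N(i)} h_{ji}\right).$$

$W_0$ is an addition of ours: the raw formulation adds a
$d$-dimensional atom vector to $h$-dimensional bond sums, which only
type-checks when $d = h$; a learned input projection is the minimal
repair that preserves the equation's intent.

Pooling ($g^{(t)}$, and $\alpha$) is per molecule. If a single "drug"
contained two disconnected fragments they would share one attention
distribution; we instead strip to the largest fragment at parse time,
so the case does not arise in practice.

## Substructure stacks and co-attention

$L$ independent encoder blocks are stacked; block $l$ consumes block
$l-1$'s node features (raw 42-dim features for $l = 1$) while bond
features re-enter each block's initialization unchanged. Each layer is
pooled with node importances $\beta_i$ (softmax over the molecule's
atoms of an atom-graph convolution scorer; scores are used as weights
only — no top-$k$ truncation) into a substructure vector
$g^{(l)} = \sum_i \beta_i h^{(l)}_i$. The stack
$(g^{(1)}, \ldots, g^{(L)})$ spans receptive-field radii $1 \ldots L$.

Two drugs couple through the co-attention map

$$\gamma_{ij} = b^\top \tanh(W_x g_x^{(i)} + W_y g_y^{(j)}),$$

with independent $W_x \ne W_y$ so that similar substructures are not
automatically rated high. $\gamma$ is deliberately **not** normalized —
that is how the model is defined; an optional per-tuple softmax sits
behind `gamma_norm` for experimentation. $W_x$, $W_y$, $b$ are shared
across relation types (the co-attention has no type subscript).
Reweighting multiplies each of drug $x$'s layers by the corresponding
row sum of $\gamma$ (column sums for drug $y$), and the graph-level
representations are the sums over layers. The identity
$\hat g_x^{(i)} = (\sum_j \gamma_{ij})\, g_x^{(i)}$ is asserted in the
test suite to 1e-6 even though the implementation is vectorized.

## Scoring, loss and training

A tuple is scored by a per-relation bilinear form,
$P = \sigma(g_x^\top M_r\, g_y)$, trained with mean binary
cross-entropy; probabilities are clamped to $[10^{-7}, 1-10^{-7}]$
before logs (internally the loss is computed in a numerically stable
logit form). $M_r$ is unconstrained, so $P(x,y,r) \ne P(y,x,r)$ in
general; `symmetrize_relations` folds $M_r$ to its symmetric part when
order invariance is wanted. Eq.-level bookkeeping gives a useful check:
the $L \times L$ matrix of pairwise substructure scores
$\hat g_x^{(i)\top} M_r\, \hat g_y^{(j)}$ sums exactly to the logit.

Initialization is Glorot-uniform with zero biases, all derived from a
single integer seed — with one deliberate exception: $M_r$ is scaled
down by $1/h$. A bilinear form multiplies two $h$-dimensional
activations, so its variance is quadratic where an ordinary linear
layer's is linear; at Glorot scale the initial logits exceed ±30,
saturate the sigmoid, and gradient descent first collapses all
representations toward the $p = 0.5$ saddle before anything is
learned. The $1/h$ factor keeps initial logits $O(1)$.

Optimization is Adam (weight decay coupled into the gradient) with an
exponential learning-rate schedule $\mathrm{lr}_e = \mathrm{lr} \cdot
0.96^{\,e}$, epochs counted from 0. Reference defaults mirror the
model's published setting — $T = L = 3$, $h = 64$, lr $10^{-4}$, batch
256, 50 epochs, weight decay $5\times10^{-4}$, a 60/20/20
train/validation/test split — and every one is overridable. Checkpoint
selection uses the lowest validation loss (the procedure is otherwise
unspecified; validation loss is the conventional criterion).
Divergence (non-finite loss) aborts with diagnostics rather than
continuing silently.

There is no deep-learning framework in this stack: the package carries
its own reverse-mode autodiff tape over dense/sparse matrix primitives
(`R/tape.R`). All graph aggregations are constant sparse operators
built once per mini-batch, and molecules of a batch form one
block-diagonal graph, so a forward/backward pass is a fixed sequence of
a few hundred matrix products regardless of batch composition. Every
primitive is validated against central finite differences, and the full
encoder against an independent dense brute-force implementation written
as explicit loops.

## Negative sampling — two protocols, chosen deliberately

Cross-entropy needs label-0 tuples, which DDI databases do not record.
Two protocols coexist here and the distinction materially affects every
reported metric:

* **Corruption sampling** (`negative_sampling()`): for each positive
  $(x, y, r)$, replace $x$ or $y$ (fair coin) with a uniformly drawn
  drug such that the corrupted tuple is not among the positives. This
  is the standard knowledge-graph protocol and what a practitioner
  would use on real data. Its blind spot: a corrupted tuple whose
  replacement drug happens to carry the same pharmacophore is
  *indistinguishable in principle* from a true positive, so if a
  fraction $c$ of drugs carry the relevant motif, even a perfect
  motif detector's held-out AUC is capped near $1 - c/2$ (minus label
  noise). On DrugBank-scale data $c$ is small; on a 60-drug synthetic
  pool, motif prevalence must be ~0.3 for enough positive pairs to
  exist, capping AUC near 0.83.

* **Rule-violating negatives** (`generate_ddi_dataset(neg_ratio = 1)`):
  the synthetic generator emits label-0 tuples drawn from pairs that
  violate the planted rule. This makes "did the model learn the
  planted chemistry?" a well-posed question with a ceiling near 0.98
  (limited only by the 5% label noise), and is the protocol of the
  learnability and explanation-recovery experiments below.

## The synthetic data generator

`generate_drugs()` assembles molecules by concatenating 1–3 fragment
SMILES from a ~30-fragment library (alkyl chains, benzene and
heteroaromatics, amide, carboxyl/ester, amine, ether, thioether,
halides), rejecting assemblies that fail parsing or standard-valence
sanity, and deduplicating by canonical SMILES. Pharmacophore-bearing
fragments are sampled with weight 3 so that the default motifs reach
~20–35% prevalence in pools of 20–60 drugs — small enough to leave
negatives abundant, large enough that a 60-drug pool supports 400
distinct positive pairs. Interactions are planted by `motif_rule()`s —
by default, amide-bearing drugs interact with benzene-bearing drugs
(type 0) and carboxyl/ester drugs with chlorinated drugs (type 1);
single functional groups, so a 2–3 layer receptive field can cover
them. Motifs are matched by labeled subgraph isomorphism (igraph VF2;
atoms labeled by element and aromaticity, bonds by order class), and
the matched atom indices are recorded per tuple as ground truth for
explanation recovery. Label noise flips positives to 0 with probability
`noise_rate` (structures are never perturbed).

What this emulates: the sparse, substructure-driven dependency
structure of curated DDI data. What it does not: realistic
medicinal-chemistry distributions, molecule sizes (assemblies are
5–25 atoms), multi-motif pharmacology, 86-way type inventories, or
dataset scale. Tests passing here demonstrate mechanism recovery and
implementation correctness, not clinical performance.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` run, end to end:

* **Oracle equivalence** — every encoder intermediate on 2–4-atom
  molecules equals the brute-force implementation to 1e-6.
* **Normalization invariants** — $\sum_t \alpha^{(t)} = 1$, per-atom
  $\sum \beta_{ji} = 1$, per-molecule $\sum_i \beta_i = 1$, and the
  row-sum reweighting identity, on 100 random seeded instances.
* **Permutation invariance** — tuple probabilities, $\gamma$ and the
  key layer pair are unchanged under atom relabelings.
* **Memorization** — 10 drugs, 50 positives + 50 corrupted negatives,
  $T = L = 2$, $h = 32$: training loss < 0.05 well within 300 epochs.
  As an overfitting-capacity experiment it uses overfit-appropriate
  optimizer settings (lr $10^{-2}$, batch 16, no weight decay).
* **Planted-motif learnability** — 60 drugs, 2 rules, 400 positives +
  400 rule-violating negatives, noise 0.05, 60/20/20 split; a compact
  configuration ($T = L = 2$, $h = 32$, lr $3\times10^{-3}$, batch 32,
  30 epochs, 3 seeds) reaches held-out AUC ≳ 0.97 on every seed.
* **Explanation recovery** — on the learnability run's positives, the
  top-3 node-importance atoms of the selected key layer are intersected
  with the planted motif and compared against a size-matched
  random-center baseline (one-sided binomial test). This check is
  *seed-dependent by nature* — see the limitations below — and the
  suite reports it as measured rather than conditioning on a favorable
  seed.

These sizes were chosen so the full suite runs in minutes on one CPU
while every claim stays statistically meaningful; all randomness
derives from explicit seeds.

## Known limitations

**Importance-score direction is not identified by the loss.** The
node importances $\beta_i$ enter the model only as softmax-normalized
convex weights in $g^{(l)} = \sum_i \beta_i h^{(l)}_i$. Nothing in the
cross-entropy objective distinguishes a solution whose scorer ranks
motif atoms *high* from one that ranks them *low* while the node
features compensate — flipping the scorer's sign and adjusting
downstream weights realizes essentially the same predictive function.
Empirically, models trained on the planted-motif benchmark all exceed
held-out AUC 0.94, yet their attention centers recover motif atoms
clearly above the random baseline for some training seeds and below it
for others, and stacking more layers does not resolve the ambiguity.
Explanations from a single trained model should therefore be read as
hypotheses to verify (as the original case-study methodology does,
against external chemistry), not as guaranteed attributions; checking
stability across training seeds is the minimal safeguard.

* Hybridization/conjugation are rule-based reconstructions calibrated
  to RDKit on common organic chemistry; exotic species (metal
  complexes, unusual lone-pair systems) may be featurized differently.
* Stereochemistry, isotopes, tautomers and 3D geometry are ignored by
  design — none appear in the feature table the model defines.
* The co-attention map is unnormalized, so $\gamma$ magnitudes (and
  hence $\hat g$ scales) are only comparable within a tuple.
* Bilinear scoring is order-sensitive unless `symmetrize_relations`
  is set; datasets whose tuples are unordered pairs should either
  symmetrize or augment with swapped tuples.
* The per-relation matrices grow as $|I| h^2$; very large type
  inventories would want a factorized parameterization.
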