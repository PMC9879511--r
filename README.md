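# ddinet

Dual graph neural networks for typed drug–drug interaction (DDI)
prediction, with substructure-level explanations — implemented in pure
R (including its own reverse-mode autodiff engine) on top of the
OpenBabel/ChemmineOB cheminformatics stack.

## Who this is for

Computational pharmacology and cheminformatics researchers who want a
*tested, inspectable* implementation of substructure-attentive DDI
prediction that runs anywhere R runs: no Python, no GPU, no external
model downloads. Everything — from SMILES featurization to training —
is exercised end to end on bundled synthetic data with planted,
verifiable structure.

## The model

Each drug's SMILES string becomes an attributed molecular graph
(42-dim atom features: element/degree/hybridization/implicit-valence
one-hots plus radical, charge and aromaticity; 6-dim bond features:
type one-hot plus conjugation and ring flags). A
**substructure-attentive directed message passing network (SA-DMPNN)**
encodes directed-bond states over *T* steps,

    h_ij^(0) = W_i x_i + W_j x_j + W_ij x_ij
    h_ij^(t) = ReLU(h_ij^(0) + W_m Σ_{k∈N(i)\{j}} h_ki^(t-1))

with per-bond importances β (self-attention graph pooling on the bond
line graph, softmax over each atom's incoming bonds) and a softmax
attention α over steps — i.e. over substructure radii. *L* stacked
blocks yield a substructure stack g^(1..L) per drug; two drugs couple
through a co-attention map

    γ_ij = bᵀ tanh(W_x g_x^(i) + W_y g_y^(j))

whose row/column sums reweight the stacks into graph-level vectors,
and a per-relation bilinear form scores the tuple:

    P(d_x, d_y, r) = σ(g_xᵀ M_r g_y)

trained with binary cross-entropy against corruption-sampled
negatives. The arg-max entry (h, t) of the pairwise score matrix
ĝ_x^(i)ᵀ M_r ĝ_y^(j) names the two encoder layers — receptive-field
radii — that drove the prediction, and the top-3 atoms by node
importance of those layers, expanded to graph distance h (resp. t),
delimit the responsible substructures. See
`vignettes/ddinet-methods.Rmd` for the full account.

## Worked example

```r
library(ddinet)

ds <- generate_synthetic_dataset(n_drugs = 30, n_tuples = 120, seed = 42)
sp <- split_dataset(ds$tuples, seed = 42)
cfg <- train_config(T = 2, L = 2, hidden = 32, lr = 3e-3,
                    batch_size = 32, epochs = 15, seed = 42)
ck <- train_ddi(ds$graphs, sp$train, sp$valid, cfg)
round(evaluate_ddi(ck, ds$graphs, sp$test), 4)
#>      ACC    AUC     F1 Prec Rec   AUPR  n
#> 1 0.8333 0.9286 0.8182 0.75 0.9 0.8956 48
```

The dataset plants two interaction rules (type 0: amide × benzene;
type 1: carboxyl × halide) plus label-0 tuples violating them; after
15 epochs the held-out AUC is already 0.93 (the acceptance script's
larger 60-drug benchmark reaches 0.94–0.98 across training seeds). Explaining one held-out positive:

```r
tp <- sp$test[sp$test$label == 1, ][1, ]   # D027 x D013, type 0
ex <- explain_ddi(ck$model, ds$graphs[[tp$drug_x]],
                  ds$graphs[[tp$drug_y]], tp$type)
ex$probability            # 0.869
ex$key_indices            # h = 1, t = 1: radius-1 substructures
ex$annotation_x$center_atoms   # top-3 importance atoms of layer h
```

`predict_ddi()` scores whole tuple tables (optionally with (h, t) per
row), `atom_similarity()` gives the Pearson atom-similarity matrices
used to visualize how node features organize into substructures, and
`motif_recovery()` quantifies how often attention centers land on the
planted motif atoms.

## Command line

A thin wrapper over the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/ddinet.R", package = "ddinet"))')
Rscript $CLI generate --n-drugs 20 --n-tuples 30 --seed 7 --out-dir data/
Rscript $CLI train --drugs data/drugs.csv --ddis data/ddis.csv \
        --out-dir run/ --T 2 --L 2 --hidden 32 --epochs 20 --seed 7
Rscript $CLI evaluate --checkpoint run/checkpoint.rds \
        --drugs data/drugs.csv --ddis data/ddis.csv --out metrics.json
Rscript $CLI explain --checkpoint run/checkpoint.rds \
        --drugs data/drugs.csv --x D001 --y D002 --type 0 --out exp.json
```

Exit codes: 0 success, 2 usage error, 3 data error.

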