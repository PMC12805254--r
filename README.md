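# gpcrmoa

Hierarchical graph modeling of ligand-induced GPCR activity: given a
receptor structure and a small molecule, predict **nonbinder**,
**agonist**, or **antagonist**.

## The science

G-protein-coupled receptor activation is a geometric event. Relative to
the conserved R3.50 switch on TM3, agonist binding swings the
intracellular half of TM6 outward (the Cα distance from R3.50 to the
TM6 anchor centroid at positions 6.30/6.34/6.48 opens by several Å) and
pulls TM7 inward (R3.50 to 7.49/7.50/7.53 closes). Classifying a
ligand's mode of action therefore means predicting the conformational
outcome of a local binding event — an allosteric problem.

The model is a two-stage equivariant graph network:

1. **Interaction module.** The receptor is reduced to a functional
   subgraph: the consensus binding site (cBS; residues within 4.0 Å of
   any bound ligand across holo structures) united with the consensus
   allosteric site (cAS; top 100 residues by mean apo→holo Cα
   displacement). Nodes sit on Cα plus one key functional sidechain
   atom per residue (37 descriptors per node: 34 learned features + 3
   coordinates on the equivariant channel); edges are k = 64 nearest
   neighbours. E(n)-equivariant GNN encoders process the cBS subgraph
   and the ligand graph (heavy atoms, 19 features, one seeded ETKDG
   conformer); bidirectional cross-attention couples them; a binding
   head emits `P_bind`.
2. **Allosteric propagation module.** The cross-attention-updated
   binding-site features — the *interaction signal* — are scaled by
   `P_bind` (gating) and injected into the full protein graph, then
   propagated by coordinate-updating EGNN layers and global
   self-attention into a conformational-state representation that the
   activity head classifies agonist vs antagonist.

Training is hierarchical multitask: `L_total = L_bind + λ·L_act`, with
the activity loss masked to ground-truth binders and binding false
negatives up-weighted by `w_FN = 1.5` (AdamW, learning rate 1e-4,
weight decay 1e-5 by default). Inference applies `τ_bind = 0.5` with a
confidence-based rescue: a compound with `P_bind ∈ [0.4, 0.5)` whose
activity confidence exceeds `τ_conf = 0.95` keeps its functional call.

Everything is testable offline: a synthetic generator builds seven-helix
receptors with a planted TM6/TM7 two-state shift, a ligand pocket, and
a grammar of ligands whose labels follow a deterministic
pharmacophore + size rule. See the vignette
(`vignettes/activity-modeling.Rmd`) for the full model description and
design rationale.

## Worked example

```r
library(gpcrmoa)

# a synthetic receptor with the planted activation signature
rec <- make_receptor(synthetic_spec())
m_inactive <- activation_metrics(rec$holo_inactive, rec$bwmap)
m_active   <- activation_metrics(rec$holo_active, rec$bwmap)
m_active$dist_tm6 - m_inactive$dist_tm6   # 4  (planted TM6 shift, Å)
m_active$dist_tm7 - m_inactive$dist_tm7   # -3 (planted TM7 shift, Å)

# dataset with planted labels, scaffold-aware split
ds <- make_dataset(synthetic_spec(), n_ligands = 150, seed = 5)
table(ds$manifest$label)
#    agonist antagonist  nonbinder
#         40         40         70
sp <- scaffold_split(ds$manifest$smiles, ds$manifest$label, seed = 11)
attr(sp, "summary")$fractions
#  test train   val
#  0.20  0.64  0.16

# train the two-stage model and score held-out scaffolds
fit <- gpcrmoa_fit(ds$samples[sp$partition == "train"],
                   val_samples = ds$samples[sp$partition == "val"],
                   cfg = model_config(hidden_dim = 32,
                                      egnn_layers_encoder = 1,
                                      egnn_layers_propagation = 2,
                                      self_attention_layers = 1,
                                      seed = 3),
                   epochs = 4, batch_size = 8, lr = 3e-3, seed = 3)
pred <- predict(fit, ds$samples[sp$partition == "test"])
head(pred, 3)
```

`predict()` returns one row per ligand with `p_bind`, `p_agonist`,
`p_antagonist`, the three-class `decision`, and whether the
confidence-based `rescued` path fired. The numbers above are what the
code prints at these seeds: the geometry deltas recover the planted
shifts exactly (noise-free generation), and the split quarantines whole
scaffold clusters in the test partition.

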