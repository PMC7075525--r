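# discoqa

Per-residue and global quality estimation for single 3D protein
structure models.

Homology modelling can produce a structural model for nearly any
protein sequence, but a model's usefulness depends entirely on its
(unknown) accuracy. `discoqa` predicts that accuracy in the absence of
an experimental reference: for every residue it predicts the lDDT score
(local Distance Difference Test, a superposition-free measure in
[0, 1]) the model would obtain against the native structure, and from
those values a global score with a length-dependent expected error.

The predictor is a composite, quasi-single-model score. Classical
single-model descriptors — six statistical potentials of mean force
(all-atom, Cβ, reduced, packing, Cβ packing, torsion; inverse-Boltzmann
pseudo-energies `e(b|t) = −log[(f_obs + σ f_ref) / ((1+σ) f_ref)]`),
agreement of the model with sequence-based secondary-structure and
solvent-accessibility predictions, a SCWRL3-style clash score and the
local residue count — are combined with **DisCo**, a distance-constraint
score built from experimentally determined structures homologous to the
target. Each template contributes Gaussian constraints
`g_ijk(d) = exp[−½ (d − μ_ijk)²]` for its Cα pairs below 15 Å;
templates are clustered by sequence similarity, cluster scoring
functions `h_ijc` are averaged constraint Gaussians, and the pairwise
score `s_ij(d) = Σ_c w_c h_ijc(d)` weighs clusters by
`w_c ∝ exp(γ SS_c)` (γ = 70). Per residue, DisCo averages `s_ij` over
all partners within 15 Å.

All terms are fused by an ensemble of 16 small feed-forward networks
(topology [n, 20, 20, 20, 1], ReLU, RMSprop, mse, 100 epochs, batch
400) — one per subset of the four optional feature blocks (torsion,
secondary-structure agreement, accessibility agreement, DisCo) — so
residues with missing inputs are dispatched to the matching network
instead of being dropped. The full input vector has 47 dimensions.

The package also contains a complete synthetic-data generator
(idealized natives, noise-perturbed models, templates with consistent
A3M alignments, mock predictor files), so the entire pipeline can be
trained, scored and evaluated without any external data.

## Worked example

Train every component from synthetic data and score a perturbed model
end to end:

```r
library(discoqa)

cp <- train_checkpoints(seed = 7)      # potentials, SS table, NNScorer
                                       # (a few minutes, fully seeded)

native <- make_native(36, seed = 991, id = "demo")
tpl <- make_templates_and_alignments(native, tempfile(), seed = 992)
pred <- make_predictor_files(native, tempfile(), error_rate = 0.1,
                             seed = 993)
model <- make_models(native, 1.0, seed = 994)[[1]]   # 1 A noise

res <- qe_score(model, cp, a3m = tpl$a3m,
                template_dir = tpl$template_dir,
                sspred = pred$ss2, accpred = pred$acc,
                reference = native)
res
#> quality_result 'demo_m01' (disco mode): global 0.730 (normalized 0.730,
#> coverage 1.00), expected error 0.039
round(head(res$per_residue), 3)
#> [1] 0.734 0.712 0.769 0.791 0.699 0.631
round(head(res$reference_lddt), 3)   # true lDDT, since a reference given
#> [1] 0.723 0.668 0.710 0.738 0.651 0.622
```

The per-residue numbers are predicted lDDT values: ~0.75 says the local
environment of that residue is expected to be mostly correct (a 1 Å
perturbation degrades but does not destroy local geometry); the global
score is their mean, the coverage pre-factor would shrink it for
incomplete models, and the expected error is the RMS deviation observed
for validation models of similar length. Withhold `a3m`/`template_dir`
and the result degrades gracefully to `single-model` mode using the
feature group without DisCo.

Individual components are exported directly: `compute_lddt()`,
`train_potential()` / `score_potential()`, `assign_ss_and_acc()`,
`clash_score()`, `spherical_smooth()`, `load_alignments()`,
`cluster_templates()`, `build_ensemble()`, `disco_score()`,
`train_nnscorer()` / `predict_nnscorer()`, `cross_validate()`,
`evaluate_predictions()`. A thin command-line interface with
subcommands `score`, `lddt`, `train-potentials`, `train-nn`,
`evaluate` and `make-fixtures` lives at `inst/exec/discoqa`.

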