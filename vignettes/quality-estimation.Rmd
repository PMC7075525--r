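---
title: "Estimating protein model quality with distance constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating protein model quality with distance constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A homology-modelling pipeline can produce a 3D model for almost any
protein sequence, but without the experimental structure there is no
direct way to tell which parts of the model are trustworthy. Model
quality estimation predicts, per residue and for the whole model, how
close the model is to the unknown native structure. `discoqa` implements
a quasi-single-model approach: it scores one model at a time, but it
augments classical single-model descriptors with consensus information
that it generates itself from experimentally determined structures
homologous to the target.

The currency of all predictions is lDDT, the local Distance Difference
Test: a superposition-free score in [0, 1] that asks, for every
reference atom pair within an inclusion radius, whether the model
reproduces the reference distance. It is both the training target of the
neural scorer and the evaluation measure.

## Target value: lDDT

`compute_lddt()` considers all reference heavy-atom pairs from different
residues with a reference distance below 15 Å. Each pair is checked
against the four deviation thresholds 0.5, 1, 2 and 4 Å; a check is
conserved when both atoms exist in the model and the model distance
deviates by less than the threshold. The per-residue score is the
conserved fraction of the checks touching that residue's atoms; the
global score pools all checks rather than averaging the per-residue
values, so incomplete models are penalized coherently. Contacts are
defined on the reference only — extra compactness in the model is not
rewarded or punished — and atoms missing from the model fail their
checks. The 15 Å radius is a parameter (`lddt_params()`); the
thresholds follow the standard lDDT parametrization. Stereochemistry
plausibility checks of some lDDT variants are deliberately out of scope.
Residues classified by the strict rule lDDT > 0.6 count as correctly
modelled in all ROC analyses (`classify_correct()`).

## Single-model descriptors

Six statistical potentials of mean force are trained by inverse
Boltzmann statistics: with observed type-conditional bin frequencies
$f_{obs}(b\mid t)$ and the type-pooled reference $f_{ref}(b)$,

$$ e(b \mid t) = -\log\frac{f_{obs}(b\mid t) + \sigma f_{ref}(b)}
                           {(1+\sigma)\, f_{ref}(b)} $$

with pseudo-count weight $\sigma = 0.02$ handling sparse counts
(Sippl-style). Types never observed fall back to the reference (zero
energy). The six terms:

* **all-atom interaction** — pairs over the 167-type alphabet of
  chemically distinguishable heavy atoms, 0.5 Å bins on [0, 20) Å;
* **Cβ interaction** — pairs of Cβ positions (glycine gets an ideal
  tetrahedral Cβ constructed from N, Cα, C at 1.53 Å bond length);
* **reduced** — Cα distance (1 Å bins, [0, 15) Å) crossed with the angle
  (30° bins) between per-residue direction vectors built from the
  backbone frame;
* **packing** and **Cβ packing** — counts of surrounding
  other-residue atoms within 10 Å, clamped to 32, per atom type;
* **torsion** — the central φ/ψ of three consecutive residues in 30°×30°
  cells, keyed by a 5-group identity triplet (GLY | PRO | pre-PRO |
  hydrophobic | polar). The grouping is a swappable table; the shipped
  default is this 5-group scheme.

The three interaction terms apply a sequence-separation threshold
|i−j| ≥ 5, which removes helix i,i+4 contacts and focuses the statistics
on long-range interactions. All stored energies are sign-flipped on
output so every per-residue feature is oriented "higher is better", like
lDDT. Full-atomic terms average per-atom contributions within a residue.

Four further descriptors complement the potentials:

* **secondary-structure agreement** — a log-odds score
  $S(d,p,c)=\log[p(d,p,c)/(p(d)\,p(p,c))]$ between the model's 8-state
  assignment $d$ and a 3-state sequence-based prediction $p$ with
  confidence $c \in 0..9$, trained with a Laplace pseudo-count of 1.
  The 8-state assignment and the solvent-accessible surface are
  computed internally: a DSSP-equivalent hydrogen-bond rule set
  (Kabsch–Sander electrostatic energy, bond below −0.5 kcal/mol)
  and Shrake–Rupley areas with a 1.4 Å probe. This removes any binary
  dependency; DSSP here names the definition, not an implementation.
* **accessibility agreement** — binary match between the observed burial
  class and an ACCpro-style two-state prediction. A residue is buried
  when its relative accessibility (area over the Tien et al. theoretical
  maximum) is strictly below 25%, the two-state convention of such
  predictors. The cut is configurable since the choice is not uniquely
  determined.
* **clash score** — SCWRL3-style hard-sphere penalties (radii C 1.6,
  N 1.3, O 1.3, S 1.7 Å): zero at or beyond the radius sum $R_{ij}$,
  10 at or below $0.8254\,R_{ij}$, linear in between, summed per
  residue and sign-flipped. Only atom pairs of residues at least two
  sequence positions apart are considered: with ideal peptide geometry
  the O(i)–Cα(i+1) 1–4 pair always sits below the C+O radius sum, so
  including adjacent residues would flag every trans peptide bond;
  those contacts are fixed by covalent geometry, not packing.
* **N** — the number of other residues with Cα within 15 Å.

All per-residue terms except N undergo spherical smoothing
(`spherical_smooth()`, σ = 5 Å): a Gaussian-weighted average over valid
neighbours (weight 1 at the centre) normalized over the valid
contributors only, which preserves constant fields exactly and keeps
values inside the input range.

## DisCo: distance constraints from homologous structures

Given an alignment of the target sequence to homologous structures
(an HHblits-style A3M plus per-template coordinates), every template k
contributes a Gaussian constraint for each mapped Cα pair with distance
$\mu_{ijk} < 15$ Å:

$$ g_{ijk}(d) = \exp\left[-\tfrac12 (d-\mu_{ijk})^2\right] $$

Templates are clustered (average linkage on 1 − pairwise normalized
sequence similarity, cut at 0.2) to prevent over-represented families
from dominating. Within a cluster c covering the pair,

$$ h_{ijc}(d) = \frac{1}{n_{ijc}} \sum_{k \in c} g_{ijk}(d), $$

and clusters combine through softmax weights
$w_c \propto \exp(\gamma\,SS_c)$ normalized over the clusters that cover
the pair, where $SS_c$ is the cluster's mean normalized sequence
similarity to the target and $\gamma = 70$ by default. The Gaussian
width is fixed at 1 Å, implementing the constraint definition verbatim.
The per-residue DisCo score averages $s_{ij}(d_{ij}) = \sum_c w_c
h_{ijc}(d_{ij})$ over all partners j within 15 Å in the model that the
ensemble covers. Seven reliability features describe the template
support per residue: mean number of covering clusters, mean
max-over-clusters similarity and identity, mean variance of the pooled
constraint distances, the number of evaluated and of total pairwise
functions, and their ratio.

Normalized sequence similarity is not uniquely defined by the method
description, so the package fixes one: per aligned column the BLOSUM62
score rescaled affinely so that the matrix minimum maps to 0 and the
first residue's self-score to 1, averaged over aligned columns. It is
bounded in [0, 1], equals 1 for identity, and makes
$\exp(\gamma\,SS_c)$ behave sensibly at $\gamma = 70$ (two clusters
0.003 apart in similarity split their weight by the logistic
$1/(1+e^{-70 \cdot 0.003}) \approx 0.552$). Softmax weights are computed
with the max-shift trick so that extreme γ (the tests use $10^6$)
remains finite. Constraint ensembles are independent of any scored
model and can be reused across models of the same target. Pairs
adjacent in sequence are retained — the separation filter belongs to
the potential terms, not to the constraints. When a single constraint
exists for a pair the variance feature is 0.

## Score combination: 16 networks, one per feature group

Each residue is described by up to 47 features: 11 per-residue
single-model terms, the DisCo score plus its 7 reliability features,
8 full-model averages of the potential and agreement terms, and a
20-dimensional amino-acid one-hot. Four blocks can be invalid per
residue — torsion (chain termini), secondary-structure agreement and
accessibility agreement (missing predictor input), and DisCo (no
template coverage). The $2^4 = 16$ subsets of valid optional blocks
define the feature groups; an `nn_scorer` holds one feed-forward
network per group and dispatches every residue to the network matching
its validity mask, so missing data changes the network, never the
answer's existence.

All networks share the production configuration: topology
[n, 20, 20, 20, 1] with ReLU hidden units and a linear output clamped
to [0, 1] (the target is lDDT; clamping keeps the topology literal
instead of appending a sigmoid), mean-squared-error loss, RMSprop
(learning rate 10⁻³, decay 0.9), 100 epochs, batch size 400. The wider
hyperparameter grid (alternative losses, optimizers, epochs, batch
sizes and topologies) is representable through `nn_config()`, but only
this configuration is the default. Weights use seeded He-uniform
initialization and seeded shuffling, so training is bit-reproducible.

Group g's network is trained on all residues whose valid blocks cover
g, using g's feature subset, with per-group z-scoring. A group with
fewer rows than one batch is not trained; at prediction time it falls
back to the best-populated group with a subset of its blocks —
ultimately the always-trained mandatory-only network. (A richer group's
network could not serve here: it expects features such residues do not
have.) Cross-validation (`cross_validate()`) partitions modelling
targets, never residues or models, so no target leaks between training
and validation; `blend_datasets()` supports mixing corpora by sampling
data points.

## Global score and expected error

The global score is the mean of the valid per-residue predictions
(`global_from_local()`). Because the model is scored "as is", an
incomplete model is not penalized; for evaluation against
coverage-sensitive targets the fraction of target residues covered by
the model multiplies the global score (`coverage_normalize()`), with
coverage counted by order-preserving sequence matching. The expected
error of a global prediction is the root-mean-square of reference
absolute errors from models of length l ± 40, computed from the
package's own out-of-fold validation predictions; an empty window
widens to the 30 nearest reference points.

## Evaluation

`roc_auc()` is the exact Mann–Whitney rank statistic with midrank tie
correction — no binning, fully deterministic. `evaluate_predictions()`
reports the pooled overall AUC and the mean per-model AUC for the
lDDT > 0.6 classification; models where the AUC is undefined (all
residues labelled equally, or constant predictions) are excluded from
the per-model mean but stay in the pool. The naive baseline
(`naive_predictor()`) blindly assigns a model's global score to each of
its residues: its per-model AUCs are all excluded by construction,
while its pooled AUC exceeds 0.5 whenever quality varies between
models — a useful reminder that pooled AUC partly measures a global
effect, not per-residue discrimination.

## The synthetic data generator

All training and evaluation data can be generated in code
(`make_native()`, `make_models()`, `make_templates_and_alignments()`,
`make_predictor_files()`), deterministically per seed:

* **natives** — full backbone + Cβ chains built by ideal-geometry NeRF
  placement from φ/ψ segments (helix −57/−47, strand −139/135, coil
  from three Ramachandran basins, with small jitter), rejection-sampled
  until clash-free. The sampler resamples angles locally around
  clashing residues, which converges quickly because clashes arise
  almost exclusively at segment transitions. "Clash-free" means no
  heavy-atom pair of residues |i−j| ≥ 2 below the hard-sphere contact
  distance R_ij; a flat minimum distance cannot be used because the
  α-helical O(i)–N(i+4) hydrogen bond sits near 2.9 Å by construction.
* **models** — per-atom i.i.d. Gaussian displacement of a native with
  amplitude schedules (the study corpus spans 0–3 Å over 8 models),
  optionally with deleted segments to emulate partial coverage.
* **templates** — noise-perturbed, truncated, point-mutated copies of
  the native written as PDB files together with a consistent A3M whose
  master is the target sequence.
* **predictor files** — the native's own 8-state assignment collapsed
  to 3 states and its burial classes, corrupted at a configurable error
  rate with confidences anticorrelated with corruption (the study
  corpus uses 15%).

What this emulates: controllable quality structure, partial template
coverage, prediction noise, and every file format the pipeline reads.
What it does not: real decoy physics (side chains beyond Cβ, rotamers,
compact misfolded states), realistic β-sheet pairing across segments,
or the distribution of errors real predictors make. Green tests
therefore demonstrate the correctness and internal consistency of the
machinery and its discrimination on controlled perturbations — not
benchmark performance on real models, which depends on real corpora.

## Problem sizes and numerical choices

The shipped study conditions: potentials are trained on 200 generated
natives of 30–42 residues; the scorer corpus is 30 targets × 8 models
with noise 0–3 Å, 4 templates per target (noise 0.3–1.5 Å, coverage
0.6–1, identity 0.6–0.95), predictor error 15%, master seed 7. These
sizes keep a full from-scratch training run in minutes while leaving
every feature group populated and the discrimination properties
testable. Residue indexing is 1-based contiguous over the extracted
polymer (the natural R convention); author numbering is metadata only.
Distance cutoffs are strict `<` throughout. Serialization containers
store floating-point payloads as C99 hex-float literals, which
round-trips doubles bit-exactly through JSON.

## Known limitations

Single-chain assessment only; mmCIF is not read (PDB is the contract
format); the DSSP-equivalent assignment implements the hydrogen-bond
rule set but not every annotation subtlety of full DSSP (e.g. β-bulge
handling); template search itself (HHblits) and the sequence-based
predictors are upstream tools whose outputs are ingested, not executed;
and the trained networks shipped by `train_checkpoints()` reflect the
synthetic corpus, so scoring real models requires retraining on real
data.
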