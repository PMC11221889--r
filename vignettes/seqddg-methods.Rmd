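---
title: "Predicting antibody-antigen binding affinity changes from sequence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting antibody-antigen binding affinity changes from sequence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Affinity maturation of a therapeutic antibody asks, for a candidate set of
residue mutations, how the binding free energy of the antigen-antibody
complex changes: ΔΔG = ΔG(mutant) − ΔG(wild type), in kcal/mol, with
positive values meaning weakened binding under the convention used here.
Structure-based estimators need a crystal structure of the complex and
falter exactly where antibody engineering operates — the conformationally
flexible CDR loops. `seqddg` implements a sequence-only alternative: a
regression network that reads the full chain sequences of the wild-type
and mutant complex and predicts ΔΔG directly.

## Featurization

Every protein (the antibody and the antigen of each complex variant) is
encoded as an `(n, 40)` matrix: columns 1–20 are a one-hot indicator of
residue identity over the fixed alphabet `ACDEFGHIKLMNPQRSTVWY`, and
columns 21–40 are a position-specific scoring matrix (PSSM) row per
residue. PSSMs from `psiblast -out_ascii_pssm` are parsed by
`parse_pssm()`, which re-orders PSI-BLAST's native column order to the
model alphabet so both blocks share one residue ordering. PSSM values are
used as raw log-odds; `featurize(..., zscale = TRUE)` optionally z-scales
the block for experimentation. The unknown residue `X` is accepted in
sequences and encodes as an all-zero row in both blocks, but is not a
legal mutation target.

When no PSI-BLAST profile is available — synthetic data, or fully offline
runs — `pseudo_pssm()` substitutes each residue's BLOSUM62 log-odds row.
This is a deterministic, alignment-free profile: it carries the
substitution-propensity structure of a real profile but no
position-specific conservation signal, and it is what all synthetic-data
experiments in this package use. Running PSI-BLAST itself (3 iterations
against UniProtKB/Swiss-Prot is the usual recipe) is deliberately outside
the package; profiles are assumed to be computed per concatenated
protein, matching the per-protein `(n, 20)` shape.

Multi-chain proteins (heavy + light antibody chains, multi-chain
antigens) are concatenated in table order into one sequence per role
before featurization; mutation positions are 1-based indices into the
named chain, and tables that use author/PDB numbering must carry a
per-chain offset column (see `?load_dataset`) — absent that, the
wild-type residue check fails loudly rather than silently misindexing.

## The network

Three blocks, with one parameter set shared across all four input
sequences (wild/mutant × antibody/antigen):

1. **Gated convolutional embedding.** Three 1-D convolutions with odd
   kernel widths (default 3/5/7) each emit `2·hidden_size` channels;
   half the channels gate the other half through a logistic sigmoid
   (a gated linear unit). The three branch outputs are concatenated to
   `d = 3·hidden_size` channels and layer-normalized per position.
2. **Attention.** Multi-head self-attention per protein,
   `A = softmax(QKᵀ/√d_k)`, output `Dropout(A·V·W_o) + H` (residual;
   dropout active only in training). Then multi-head mutual attention
   between the two proteins of the same complex variant: queries from
   one protein, keys/values from its partner, **no residual and no
   dropout** — the update is exactly the attended value projection
   (`model_config(mutual_residual = TRUE)` offers the residual variant
   for experimentation). Heads are realized by splitting `d` into
   `n_heads` sub-spaces, concatenating the head outputs and mixing with
   a linear map — the standard multi-head construction. Mutual attention
   runs in both directions so each protein's representation is
   partner-aware; the head-averaged antigen→antibody map, shape
   `(len_ag, len_ab)`, is the one exported for interpretability.
3. **Prediction head.** Each protein's per-residue representation is
   pooled over its true length (mask-aware mean by default; max pooling
   behind `model_config(pooling = "max")`). The four pooled vectors are
   concatenated `[ab_wt, ag_wt, ab_mt, ag_mt]` and passed through three
   fully connected layers (widths `fc_sizes`, rectifier between them)
   and a final affine map to the scalar ΔΔG. We read the architecture's
   "three fully connected layers" as the three hidden layers, with the
   regression output as a final affine map; no nonlinearity follows the
   scalar.

The ablation variant (`use_attention = FALSE`) skips block 2 entirely
and pools the embeddings directly; because self-attention is residual
and mutual attention preserves width `d`, the head input width is
unchanged, so the hidden-layer parameter count is identical — the
comparison isolates the attention block, not capacity.

Padding: batched inputs may be right-padded; all exported entry points
take an `n_valid` marker and computation is performed on the true
length, so padding invariance is exact rather than approximate.

No deep-learning framework is used. Forward passes cache their
intermediates and hand-written backward passes consume them; all heavy
steps are BLAS matrix products. Backpropagation correctness is pinned by
a finite-difference gradient test (relative error ≤ 1e-3 on sampled
parameters) and the attention operators are checked against explicit
loop-based oracles.

## Training

`train_model()` minimizes the mean squared error between predicted and
experimental ΔΔG with Adam (the standard adaptive-moment choice for this
architecture family) on shuffled mini-batches. The loss is averaged per
batch, then per epoch. Two seeds make runs bit-reproducible: the model
seed drives parameter initialization, the training seed drives shuffling
and dropout. Labels are used in kcal/mol without normalization — their
range is modest. When a validation set is supplied, the checkpoint with
the best validation loss is returned and `early_stop_patience` can end
training early; training aborts with diagnostics if the loss goes
non-finite.

The full-scale defaults (`hidden_size = 64`, learning rate 1e-4) suit
benchmark-scale datasets on capable hardware. All in-package experiments
use a compact configuration chosen for minutes-scale CPU runs: hidden
size 8 (d = 24), 2 heads, head widths 32/16/8.

## Evaluation protocols

Two splits mirror the two evaluation settings the method is meant for:

- `kfold_split()`: records shuffled and dealt into K near-equal folds
  (sizes differ by ≤ 1). `cross_validate()` trains one model per fold
  and pools all out-of-fold predictions; pooled Pearson correlation and
  R² are primary (the per-point scatter aggregates all folds), per-fold
  values are also reported.
- `label_ascending_split()`: within each complex, records are sorted by
  ΔΔG and the top `test_fraction` (default 0.2; the ratio is a free
  parameter of the protocol) is held out — an extrapolation test toward
  stronger affinity changes. Ties break by stable input order; a
  single-record complex goes to training with a warning.

Metrics: `pearson()` (product-moment correlation), `r_squared()`
implemented as the standard coefficient of determination
`1 − SS_res/SS_tot` (the usual textbook definition; it may be negative),
and `rank_consistency()` — R² applied to average-tie rank vectors — used
to score candidate-ranking experiments such as antibody optimization
campaigns, where only the ordering of mutants matters.

## Interpretability

For a record, the wild-type and mutant antigen×antibody mutual-attention
maps are min-max normalized over the whole matrix (the normalization is
written on matrix entries, not rows, so global normalization is used),
differenced (mutant − wild type), and min-max normalized again:

norm(x) = (x − min)/(max − min);  W_dist = norm(W_mt) − norm(W_wt);
result = norm(W_dist).

The result lies in [0, 1] and highlights residue pairs whose attention
changed upon mutation. A constant matrix normalizes to all zeros by
policy, so degenerate maps still render. Because min-max normalization
absorbs positive affine transforms, the result is invariant to common
rescalings of both inputs. Head-averaged maps are used (per-head export
is available from `mutual_attention()`); `export_heatmap()` writes a TSV
and a PNG with the antigen along the x-axis and the antibody along the
y-axis, labels like `Y32` carrying residue letter and 1-based index. On
synthetic data with a trained model, the mutated antibody columns of the
delta map tend to carry above-average weight; the test suite reports
this ratio as a diagnostic, not a hard gate — attention weight is an
explanation aid, not a causal measurement.

## Synthetic data: what it emulates, and what it does not

`generate_dataset()` builds complexes with uniformly random chains
(antigen 60–120, antibody 80–150 residues by default — long enough for
the convolution kernels, short enough for minutes-scale CPU training), a
contiguous antibody "interface" window (default 8 residues, weight 1;
all other positions weight 0), and 1–5 point mutations per record, drawn
from the interface with probability 0.8. The label is
`Σ_sites weight(site)·(v(mt) − v(wt)) + N(0, noise_sd)` with a
per-residue propensity scale `v ~ N(0, 1)`: the effect table
`effect(a→b) = v(b) − v(a)` is antisymmetric with a zero diagonal, like
an idealized single-site substitution scale. Defaults (8 complexes × 60
records, noise 0.3 kcal/mol, seed 7) define the package's standard
benchmark. Mutations are placed on the antibody chain only, since the
interface window lives there.

This generator gives the mutual-attention block a real signal to find —
interface residues matter, others do not — and makes labels additively
decomposable, which real epistatic mutation data is not. A consequence
worth stating plainly: because the ground truth is additive in single
sites, the no-attention ablation can match or even exceed the full
model on this benchmark (pooled embeddings already expose the per-site
substitution signal). The ablation comparison on synthetic data
therefore checks the contract — same pipeline, same head width, finite
predictions, accuracy reported side by side — and is not evidence about
the attention block's value on real interaction data, where the signal
is not additive. It emulates
none of the sequence statistics of immunoglobulins (no CDR grammar, no
germline frameworks, no conservation structure in the pseudo-profiles).
Passing the synthetic benchmark therefore demonstrates that the
architecture, gradients, training loop and evaluation plumbing work
end-to-end and can extract a localized interaction signal; it says
nothing quantitative about accuracy on AB-Bind- or SKEMPI-derived
benchmarks, which require the external data and per-protein PSI-BLAST
profiles.

## Numerical and design choices

- Layer-norm epsilon 1e-5; masked softmax is computed on the truncated
  true-length matrices, which is exactly equivalent to additive −∞
  masking and cheaper.
- Attention projections carry no bias terms; biases elsewhere initialize
  to zero, weights Glorot-uniform.
- Whole-matrix min-max normalization in the interpretability transform;
  constant matrices map to zero.
- The standard benchmark trains the compact model for a fixed 60 epochs
  with Adam at 2e-3 (batch 16, dropout 0.1) and uses the final model.
  The learning rate matters here: at 5e-3 the optimizer can sit
  indefinitely on a plateau (predicting per-complex means) before
  finding the wild-vs-mutant difference signal, whose magnitude mean
  pooling scales by 1/length; at 2e-3 with small batches learning is
  slower per step but reliable across seeds. Validation-loss checkpoint
  selection (available via `val_fraction`) proved counterproductive on
  this benchmark: as training progresses the prediction variance grows,
  which can raise a small validation split's MSE even while the
  held-out correlation keeps improving, so the selected checkpoint is
  systematically too early.
- `cross_validate()` marks fold metrics undefined (NA) when a fold has
  fewer than 2 test records or a constant truth vector; pooled metrics
  are still computed.

## Known limitations

- Pure-R training: minutes per benchmark-scale run on one CPU; the
  full-scale configuration on real benchmark datasets wants hours.
- Mutant PSSMs reuse wild-type profiles with substituted BLOSUM62 rows
  at mutated positions; regenerating true mutant profiles is external.
- No antibody numbering schemes (Kabat/IMGT) and no structure parsing;
  tables must reference plain sequence positions (or carry offsets).
- Attention-difference maps are a visualization of what the model
  attends to, not a physical interaction energy decomposition.
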