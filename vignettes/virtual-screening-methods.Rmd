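---
title: "Ligand-based virtual screening with a seven-class activity classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-based virtual screening with a seven-class activity classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Ligand-based virtual screening (LBVS) ranks the compounds of a
screening library by how much they resemble compounds with known
activity against a target — here, G protein-coupled receptors such as
the chemokine receptors CCR2, CCR3 and CXCR3. `selectscreen`
implements LBVS as a *multi-class* classification problem rather than
the usual active/inactive binary one: compound potency on the pChEMBL
scale (the negative decadic logarithm of molar IC50/Ki, with 0 used
as a sentinel for compounds reported inactive) is binned into seven
activity categories,

| class | pChEMBL range |
|------:|:--------------|
| 1 | below 4 (includes the inactive sentinel 0) |
| 2 | [4, 5) |
| 3 | [5, 6) |
| 4 | [6, 7) |
| 5 | [7, 8) |
| 6 | [8, 9) |
| 7 | 9 and above |

and a sequential feed-forward network maps 2048-bit ECFP4 fingerprints
(extended-connectivity, bond diameter 4 / Morgan radius 2) to a softmax
distribution over those seven classes. A seven-class model can
discard not only inactives but also low- and medium-activity
compounds, which matters when libraries contain many weak binders.

The published activity ranges are written "4–5", "5–6", and so on,
which leaves boundary membership ambiguous; the package adopts
left-closed/right-open intervals, so 5.0 is class 3 and 9.0 is class
7. That convention makes the map total, deterministic and monotone,
which the test suite verifies against a brute-force interval-lookup
oracle.

## Featurization

Fingerprints are computed by OpenBabel's ECFP4 implementation, called
once per dataset in batch mode, and folded from the 4096-bit hash
space to the configured width (default 2048; bits at congruent
positions are OR-ed). Folding halves memory and model width at the
cost of rare bit collisions; the width is recorded with every
fingerprint matrix. Tanimoto (Jaccard) similarity of two fingerprints
is `|a & b| / |a | b|`, defined as 0 for two empty fingerprints to
avoid 0/0.

Dataset curation canonicalizes SMILES through OpenBabel and drops
records whose SMILES fail either a conservative syntactic screen
(unbalanced parentheses/brackets, unmatched ring closures, illegal
characters) or the parser itself. The syntactic screen exists because
lenient parsers silently "repair" some malformed strings — `"C(("`
would otherwise come back as methane — and a curation step must
reject such records, not mutate them. Duplicate compound ids keep the
first occurrence, an order-stable policy.

Cross-set similarity between two fingerprint collections is
summarized as the average and the mode of the Tanimoto coefficient
over all `|A| x |B|` cross pairs, the mode on a 0.01 grid (ties to
the lower bin) because dataset modes are conventionally reported at
two decimals. A per-compound-maximum reading (each query compound's
best match) is also implemented behind a flag, since "similarity
between two datasets" is used both ways in the literature; all-pairs
is the default because it is symmetric and assumption-free.

## The classifier

The network is deliberately plain: fingerprint bits in, two ReLU
hidden layers (defaults 512 and 128 — the published description fixes
the ingredients but not the layer widths, so these are package
defaults, fully configurable and logged), a 7-unit softmax output,
categorical cross-entropy loss, and minibatch Adam (learning rate
1e-3, batch 32). Defaults of 1000 training epochs for a single model
and 100 epochs for the repeated-run selectivity protocol follow the
published procedure, which notes that loss and accuracy stabilize
well before 1000 epochs. Only fingerprint bits are inputs; the
pChEMBL value and the class are labels. Training on them would be
target leakage.

Reported loss is the *mean* per-sample cross-entropy (the per-set sum
is the other possible convention; the mean is used because it is
comparable across validation sets of different size). Argmax ties
break toward the lower class — the conservative activity call.
Initialization is He-normal from a seeded generator; all training
randomness (initialization and epoch shuffling) flows through a
single 64-bit seed, so runs are bit-reproducible in single-threaded
mode. The training core is compiled (RcppArmadillo), as is usual for
the numerical kernels of R machine-learning packages.

## Selectivity cross-evaluation

Receptor-subtype selectivity is probed by training one model per
receptor dataset and evaluating every model on every receptor's
validation set (an 80/20 uniform random split per receptor, the
published fraction). Each cell of the resulting matrix carries loss,
accuracy, the accuracy change relative to the matched-subtype cell of
the same run ensemble (other minus matched, so the diagonal is
exactly 0), and the average/mode Tanimoto coefficient between the
training and validation fingerprint sets. Metrics can be averaged
over `n_runs` seeded repetitions (seeds `base_seed + run - 1`); the
matched reference comes from the same ensemble to avoid seed
asymmetry. The association between transfer accuracy and dataset
similarity is quantified by a Spearman rank correlation — rank rather
than linear, because accuracy is bounded and the relation need only
be monotone.

## The synthetic generator

Real training data for this problem are ChEMBL exports; the package
generates structurally analogous datasets so that every stage is
testable without downloads. The generator builds congeneric series by
text substitution at a single marked attachment point on vetted
scaffold templates — 24 aromatic/heteroaromatic and 24
saturated/aliphatic cores — with substituents from a fixed fragment
pool. Validity is guaranteed by construction and verified by
round-tripping every generated SMILES through canonicalization.
Candidate molecules are canonicalized during generation and colliding
structures resampled, so a dataset never contains the same molecule
twice under different labels.

Latent activity is `clip(base(scaffold) + delta(substituent) + noise)`:
a dominant per-scaffold base effect drawn uniformly over the activity
scale, a smaller additive substituent effect (s.d. 0.5 pChEMBL
units), and Gaussian assay noise. Because scaffold and substituent
fragments light up characteristic fingerprint bits, this latent model
is linear in the fingerprint representation — learnable, but
imperfect at positive noise. A configurable fraction of *scaffolds*
is inactive (all their compounds get pChEMBL exactly 0, the sentinel
convention). Making inactivity a scaffold property rather than a
per-compound coin flip reflects how non-binding chemotypes behave and
keeps the labels a function of structure; randomly flagged inactives
would impose an arbitrary accuracy ceiling no model could beat.

Defaults — 20 scaffolds x 100 substituents (2000 compounds), 25%
inactive scaffolds, noise s.d. 0.4 — were chosen once to resemble the
curated receptor datasets this pipeline targets (600–5000 compounds,
25–40% inactives) and produce moderate, realistic validation
accuracies. The label-recovery benchmark uses the *separable* setting
(`noise_sd = 0`), where labels are a deterministic function of
structure and residual error measures only the model's ability to
compose scaffold and substituent effects from fingerprint bits.

For subtype pairs, the two datasets share a configurable fraction of
scaffolds; unshared scaffolds come from the two chemically distinct
template families, so average cross-set Tanimoto similarity rises
monotonically with the overlap. Shared scaffolds keep the same base
activity in both datasets (the chemotype is what transfers between
paralogous receptors) while substituent effects and noise are drawn
independently per receptor — shared chemistry, different
structure-activity detail, which is precisely the selectivity signal
the cross-evaluation should detect: at overlap 0 a model transfers
poorly to the other receptor; at overlap 1 it transfers well but
still short of matched performance.

What the generator does *not* emulate: real pChEMBL noise is not
Gaussian homoscedastic, real datasets mix assay types and contain
activity cliffs, and real scaffold diversity is far larger. Passing
tests on synthetic data therefore demonstrate that the pipeline's
machinery is correct and that the protocol detects the patterns it
is designed to detect — not that any particular accuracy will be
reached on ChEMBL data.

## Screening, percent ranks and consensus

A screened compound is ranked by its expected class ordinal
(`sum(p_k * k)`, so a pure class-k prediction scores exactly k); ties
break by the probability of the top class, then by library order.
"In x% of top predictions" is the compound's rank divided by the
library size, times 100; the within-range variant ranks only among
compounds sharing the predicted class. The published screening
reports do not define their ranking statistic; the expected-class
ordinal is one defensible reading, chosen because it uses the whole
distribution and reduces to the class label on confident predictions.

Docking scores enter as AutoDock Vina `REMARK VINA RESULT` lines from
multi-model PDBQT files (or plain score tables); the best pose per
compound is the minimum affinity over its poses. The energy cutoff
(default -10.5 kcal/mol) is inclusive — a pose exactly at the cutoff
passes. Consensus selection intersects the classifier's top-range
compounds with the docking survivors, ordered by ranking score then
affinity; a top-N alternative to the cutoff is provided because
published workflows use both forms of selection.

## Numerical choices and degenerate inputs

* Tanimoto of two empty fingerprints is 0; cross-set summaries refuse
  empty collections.
* `split_dataset` requires at least two records and a fraction
  strictly inside (0, 1); the training size is `round(fraction * N)`.
* Training refuses empty sets, labels outside 1..7, and zero epochs.
* Probability rows from the softmax sum to 1 within 1e-6; evaluation
  clamps predicted probabilities at 1e-12 before taking logs.
* Every random operation takes an explicit integer seed; derived
  seeds are documented arithmetic on the caller's seed.
* Bit-reproducibility is promised only in single-threaded mode;
  multi-threaded BLAS may reorder floating-point reductions.

## Problem sizes used by the packaged checks

The test suite exercises the label-recovery benchmark at its full
size (2000 compounds, 2048-bit fingerprints, 100 epochs) and the
selectivity protocol on 10-scaffold x 20-substituent subtype pairs
over the overlap grid {0, 0.25, 0.5, 0.75, 1} with one run per cell —
sizes chosen so the full protocol demonstrates its qualitative
pattern (matched-over-mismatched accuracy gap at zero overlap,
positive accuracy-similarity correlation) at desk scale. Unit tests
use still smaller networks and libraries, since they test contracts,
not model quality.

## Known limitations

* OpenBabel's ECFP4 bit assignment differs from RDKit's Morgan
  hashing; absolute bit identities are not interchangeable between
  toolkits, though Tanimoto similarities and model results are
  comparable in practice.
* The classifier is a fixed-topology dense network; no hyperparameter
  search, graph architectures or transfer learning are in scope.
* Percent-rank conventions differ across published screening reports;
  the within-range statistic here always uses the compound's own
  predicted class as the reference population.
* The pipeline consumes docking *scores*; it never runs a docking
  engine.
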