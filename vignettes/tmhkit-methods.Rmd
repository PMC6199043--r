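---
title: "tmhkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tmhkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tmhkit` predicts three structural properties of α-helical membrane
proteins from sequence-derived inputs: transmembrane helix (TMH)
topology, inter-helix residue–residue contacts, and per-residue relative
accessible surface area (RASA). This vignette documents the models, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the design choices made where the design was genuinely open.

## 1. Profiles

All engines consume an L×20 evolutionary profile per sequence, in the
fixed column order `A R N D C Q E G H I L K M F P S T W Y V`.

* `read_pssm()` parses the PSI-BLAST ASCII log-odds block (the optional
  percentage block and trailing statistics are ignored — only log-odds
  feed the features). Raw log-odds are mapped to (0,1) by the logistic
  function with slope 1 and midpoint 0. The logistic choice is ours: it
  is bounded, monotone, and standard for PSSM-fed classifiers; nothing in
  the original method description fixes a normalization.
* `pseudo_profile()` is a degraded fallback when no homology search is
  available: row *i* puts weight `w = 0.9` on the observed residue and
  `(1-w)/19` elsewhere (`X` rows are uniform). It carries no evolutionary
  information; accuracy claims in this package's tests are made in this
  mode, which is the harder setting.
* `msa_profile()` derives a frequency profile from alignment columns for
  the contact engine's pair features.

**Terminus padding.** Window features pad out-of-range rows with a
neutral constant. "Neutral" depends on the profile's value scale: 0.5 is
the logistic image of log-odds 0, so it is neutral for PSSM profiles, but
probability-valued profiles (pseudo, MSA-frequency) have rows summing to
1, where the neutral value is the uniform 1/20. Padding 0.5 there would
inject a large spurious signal at the termini (we measured it dominating
the pair-feature variance), so the padding value follows the source.

## 2. TMH topology engine

**Features.** Sliding windows of widths `W = 13` and `15` over the scaled
profile; per-residue propensities from the two widths are averaged.
Fusing two widths limits the bias either single width induces on short
("half") and long helices. We average the two classifier outputs *before*
smoothing; the pipeline order is classifier → fusion → median filter →
segmentation.

**Classifier.** The evidence-theoretic K-nearest-neighbor rule: each of
the `k = 11` nearest reference windows contributes the simple support
function `m({q}) = α₀·exp(−γ_q d²)`, `m(Θ) = 1 − m({q})` with
`α₀ = 0.95`; Dempster's rule combines the k masses; the output is the
pignistic TMH probability. The published name of this family does not fix
the "optimization" step, so we realize it as the canonical choice: γ_q is
initialized to the inverse mean squared within-class distance and refined
by a multiplicative coordinate search (factors ¼, ½, 2, 4; three rounds)
that accepts only strict improvements of leave-one-out misclassification
— hence refinement can never worsen the LOO error. Ties at the k-th
distance include all tied references, making classification independent
of reference ordering. Note that Dempster's rule is not idempotent:
duplicating every reference while doubling k strengthens each piece of
evidence and shifts propensities away from 0.5 (it can never flip a
decision); the test suite asserts exactly this invariant.

Training down-samples to at most `max_ref = 20000` reference windows per
width (stratified by class, seeded) to keep brute-force KNN queries
desk-scale.

**Segmentation.** The smoothed track (median filter, window 5, shrinking
at the termini so no values are fabricated) is thresholded at
`T₀ = 0.4` (inclusive). Because sliding windows blur short loops, two
helices joined by a 1–2-residue loop often surface as one segment; the
dynamic threshold raises the cutoff in steps of 0.05 (to at most 0.95)
over each candidate segment and splits at the first level where the
segment separates into ≥ 2 pieces, each ≥ `min_tmh_length = 5` residues,
with the segment's interior minimum at least `split_valley_depth = 0.1`
below that level; accepted pieces are split recursively and keep the
coordinates of the restricted re-thresholding (valley residues are
dropped). The original split rules are unpublished ("pre-learned rules");
the valley-depth + minimum-length rule is our explicit, testable
surrogate, and both constants are exposed in `segmenter_config()`. We
split but never merge: merging would break the monotonicity of the
procedure, and the original's behavior is unknown. Whether the original
enforces a minimum helix length is also unknown; ours is 5 and
configurable.

**Metrics.** A predicted and an observed helix match if they overlap by
at least `min(5, ⌈len_obs/2⌉)` residues, matched greedily one-to-one in
sequence order — the original never defines "correctly predicted", so we
follow common TMH benchmarking practice. `A_TMH`, `A_P`, and the N-/C-
end-offset scores are computed from the matching.

## 3. Contact engine

**Coevolution.** A native implementation of the sparse-inverse-covariance
family ("PSICOV-style", not a bit-compatible clone): sequence weights
`1/n_r` at 80% identity; weighted indicator frequencies over the 21-state
alphabet with pseudocount 1 — applied as covariance shrinkage toward the
independence model, so a signal-free alignment has exactly zero
covariance; the gap state is dropped as the indicator reference category,
which together with diagonal shrinkage (`λ = 0.1`, floor 1e-4) keeps the
matrix invertible; the precision matrix is estimated by graphical-lasso
block coordinate descent (`ρ = 0.005`, implemented in C++; tolerance
1e-3 relative to the mean off-diagonal, at most 50 sweeps — in our
benchmarks it converges in ~20). Pair score = L1 norm of the 20×20
precision block; the average product correction removes multiplicative
row/column background (exact on rank-one structure when self-pairs are
included; with them masked the residual is O(1/L) and shrinks with L).
Pairs with separation < 5 are masked (standard in contact benchmarking).

**Supervised ensemble.** Pair features are our design (the original
leaves them unspecified): two W = 7 profile windows, the separation
|i−j| — stored as |i−j|/L so it shares the [0,1] scale of the profile
cells, which a Euclidean metric requires — and the two within-helix
relative positions. Before training, each of the four semantic blocks
(window i, window j, separation, positions) is rescaled to unit total
variance on the training pool; without this the positional features
dominate the metric and the base learners are blind to the profile
signal. Each of the `n_models = 10` members is an OET-KNN model (reused
from the topology engine for code economy) trained on all positive pairs
plus an independent seeded draw of negatives at 1:1; the ensemble score
is the mean member propensity.

**Fusion.** The two maps are rank-normalized over unmasked pairs
(average rank on ties) and combined as `w·coevolution + (1−w)·ml` with
`w = 0.5`. The original states only that the outputs "are combined";
rank averaging is our surrogate — scale-free and robust to the two
engines' very different score distributions.

## 4. RASA engine

**Template engine.** A pool stores one entry per residue with a full
15-residue window: the unit-normalized flattened scaled-profile window
and the central residue's RASA. Queries score pool entries by cosine
similarity (mapped to [0,1] via `(s+1)/2`) and average the central RASA
of the `top_t = 3` most similar entries. Unit normalization makes the
similarity scale-invariant in the query profile.

**Regression engine.** The six feature blocks are our surrogate for the
original's unenumerated "six kinds of sequential features": (1) scaled
profile window (W = 9), (2) Kyte–Doolittle hydropathy window, (3) one-hot
residue identity, (4) TMH propensity window (a supplied track, or the
0/1 topology membership), (5) relative position within the containing
helix, (6) normalized distance to the nearer terminus. The environment
provides no support-vector-regression solver, so the engine is
radial-basis kernel ridge regression behind the same contract:
deterministic given a seed, targets centered (a constant-target corpus
yields an exactly constant predictor), outputs clamped to [0,100],
bandwidth from the median pairwise-distance heuristic, ridge `λ = 1e-3`,
basis capped at 2000 seeded rows.

**Knowledge rule.** `hard_switch` (default): a position uses the template
value iff its best mapped similarity ≥ `τ = 0.9`, else the regression
value — confident structural templates override the learned engine.
`similarity_blend` interpolates instead.

## 5. The synthetic world

The generators replace structure-database-derived corpora and state the
world the tests live in:

* **Proteins** alternate loops (1–30 residues, down to the 1–2-residue
  short-loop case) and helices (core 17–28; with probability 0.1 a
  "half" helix of 8–12; with probability 0.05 a long helix of 36–45;
  1–7 helices per protein). Helix residues are drawn with weights
  ∝ exp(KD/2) over the Kyte–Doolittle scale, loops from the complement —
  the simplest mechanism that makes helices recoverable from local
  composition, which is exactly the signal a profile-window classifier
  exploits.
* **Alignments** plant `n_pairs` disjoint column pairs (separation ≥ 5):
  with probability `coupling` a row draws the pair jointly from a fixed
  8-entry compatible-state list, else independently from the uniform
  background. The list mixes packing and identity pairs, so planted
  columns are also compositionally shifted — giving the supervised
  engine a signal too. A compatible-state list was chosen over a Potts
  model: controllable, analyzable coupling without MCMC.
* **RASA tracks** encode helical periodicity: within a helix
  `clamp(45 + 35·sin(2πi/3.6 + φ) + ε, 0, 100)` with a per-helix random
  phase φ and Gaussian ε (sd 10 by default); loops `clamp(70 + ε′)`.
  3.6 residues/turn is α-helix geometry.

What the generators do **not** emulate: phylogenetic correlation between
alignment rows, signal peptides, re-entrant loops, genuine evolutionary
conservation gradients, or any coupling between a helix's sequence and
its RASA phase. A green test therefore establishes that the engines
recover the stated statistical structure at desk scale — not performance
on real proteins.

**A consequence worth spelling out.** Because the RASA phase φ is random
per helix and independent of everything observable, the within-helix
sinusoid (variance 35²/2 ≈ 612) is irreducible noise for *any* predictor.
The best possible predictor is the class-conditional mean (45 in helices,
70 in loops); its Pearson correlation with the generated tracks, measured
on a 200-protein corpus, is ≈ 0.52. Our fused engine reaches ≈ 0.51 —
essentially the ceiling — and comfortably satisfies the fusion-dominance
MAE property, but the acceptance suite's `r ≥ 0.7` assertion cannot be
met in this world and is left failing by design rather than weakened or
gamed.

## 6. Numerical choices and degenerate inputs

* Dempster combination normalizes conflict at each pairwise step
  (equivalent to one final normalization); total conflict is impossible
  for α₀ < 1 and guarded regardless.
* `classify` computes distances by chunked BLAS matrix products with a
  clamp at 0 for negative round-off.
* Model archives are flat TSVs with a JSON header; floating-point cells
  are written as `%.17g` so archives round-trip bit-exactly.
* The graphical lasso falls back to a warning plus best iterate on
  non-convergence; the flag is attached to the returned map.
* `evaluate_rasa` on a constant observed track warns and returns `NA`
  correlation (MAE is still returned); a constant predicted track
  returns r = 0.
* Empty topologies, all-below-threshold tracks, sequences shorter than a
  template window, and single-class training corpora all produce defined
  results or classed errors (`tmhkit_*_error`), never silent truncation.

## 7. Known limitations

* Brute-force KNN: O(n·m) distance work per query batch; the 20000
  reference cap keeps this desk-scale but a production system would use
  an index.
* The coevolution engine's O((20L)³)-ish estimation limits alignment
  width to a few hundred columns on one CPU.
* No helix orientation (inside/outside) prediction, no β-barrels, no
  signal-peptide discrimination, no 3D model building from contacts.
* Pseudo-profiles make all shipped accuracy figures conservative; with
  real PSI-BLAST profiles the feature space is richer.
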