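---
title: "Sequence-only stability modelling: methods and design notes"
author: "protstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-only stability modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(protstab)
```

## The problem

High-throughput protease-resistance assays measure, for tens of thousands
of designed mini-proteins (25--65 residues) displayed on yeast, the
protease concentration at which half the displayed protein is cleaved
(EC50, on a log scale) under trypsin and chymotrypsin. Raw resistance
conflates two things: protection conferred by a folded structure, and the
intrinsic resistance of the unfolded chain, which depends on how many
cleavage-prone residues the sequence offers each protease. The package
implements a fully sequence-based modelling stack around this assay:

* an **unfolded-state model (USM)** that predicts the unfolded-chain EC50
  from sequence alone, trained on scrambled sequences that are very
  unlikely to fold;
* the **stability score**: observed EC50 minus USM-predicted EC50, per
  protease, with the combined score the minimum of the two (one unit is
  roughly ten-fold resistance);
* a multi-task convolutional **evaluator** predicting both stability
  scores and the secondary-structure string from the primary sequence;
* a **generator** translating secondary-structure strings to primary
  sequences (and its reverse), with beam decoding;
* constrained **beam-search refinement** of sequences under the
  evaluator's guidance;
* **cross-chip calibration** by orthogonal and piecewise-linear
  orthogonal regression;
* a **synthetic corpus** so every stage can be trained, scored and tested
  end to end without external data.

## Input encoding

Sequences are one-hot encoded into a fixed 23 x 175 window: the 20 amino
acids plus padding (`X`), start (`J`) and stop (`O`) rows. A sequence of
length $n \le 145$ occupies columns `offset .. offset+n-1` (0-based) with
`J`/`O` immediately flanking it; the legal range is
$15 \le \text{offset} \le 160 - n$, i.e. the middle 145 columns, splitting
the 30 spare columns symmetrically. The placement is "random but
consistent": a documented polynomial byte hash of (sequence, seed) picked
modulo the legal range, never the language's randomized string hash, so
placements look uniform across a corpus but are bit-stable across
sessions and platforms. Consistent placement prevents the evaluator from
binding absolute input positions to residue identities while keeping
training targets stable.

The unfolded-state model uses a fixed offset and restricts its max-pooling
to convolution windows that lie entirely inside the residue span, so its
predictions depend only on the residues; randomized placement is a
property of evaluator training only.

## The unfolded-state model

One fully separate model per protease (an open choice; the source
describes "one for each of the two proteases", which we read as
independent weights). Each model has 100 kernels of shape 23 x *w*
(*w* = 5 by default; the width is not stated in the reference and is
configurable), takes each kernel's **maximum** activation over the valid
convolution positions, and combines the 100 maxima through a learned
linear head. Training minimises mean squared EC50 error on scrambles with
Adam (learning rate 3e-3, minibatch 64), a held-out fraction (10%) for
early stopping, and restores the best-validation weights. The reference
leaves the optimiser unspecified; these defaults are recorded in the
training log.

Max-pooling makes the model placement-sensitive (a motif counts wherever
it occurs) but not composition-blind: a bank of kernels with graded
weights recovers smooth composition-driven rules well (the test suite
demonstrates $r^2 \ge 0.8$ against a known generative rule at $n = 2000$).

## The evaluator and its losses

Architecture (defaults = the reference sizes): three valid-convolution
layers — 400 kernels of 23 x 5 (output 171 x 400), 200 of 1 x 9, 100 of
1 x 17 — all ReLU with 20% dropout; a stability path of dense 80 and 40
ReLU units into a 2-unit linear layer (chymotrypsin, trypsin) with an
appended third unit computed architecturally as the minimum of the two;
and a secondary path, a dense 6 x 175 softmax layer over the full window.
Training uses minibatches of 64 triplets — a designed protein with
stability and secondary targets, an unlabeled natural sequence, and a
scramble of that natural — optimised with Adadelta, stopping when
validation loss fails to improve for five epochs and restoring the best
snapshot. That stopping rule is the default; see the note on desk-scale
training below.

The loss is $L = 0.2 L_s + 0.1 L_c + 2 L_d$ with:

* $L_s = \overline{(X-\hat X)^2} - 5 R^2(x_m, \hat x_m) -
  R^2(x_{c,t}, \hat x_{c,t})$, the mean squared error over the three
  outputs minus weighted coefficients of determination computed with
  minibatch means (the per-protease $R^2$ pools both columns). A perfect
  fit on a non-constant batch gives exactly $-6$. Two notational wrinkles
  in the source are resolved as follows: the first term is implemented as
  mean *squared* error (matching the printed formula; the prose says
  RMSE — the $-6$ anchor holds either way), and zero-variance minibatches
  set the affected $R^2$ term to 0 rather than dividing by zero.
* $L_c = \overline{2.5\,\sigma(\tilde y_m - \hat y_m)} +
  0.001\,\overline{(\hat y_c - \hat y_t)^2}$ for natural/scramble pairs.
  The printed equation has the opposite sign in the exponent, which would
  *reward* stable-looking scrambles, contradicting the stated intent; we
  implement the intent (naturals should out-score their scrambles, the
  bounded sigmoid capping the penalty at 2.5) and keep the printed sign
  available behind the `lcAsPrinted` switch.
* $L_d$ = categorical cross-entropy of the secondary softmax against the
  one-hot target plus four grammar-invalidity estimates:
  $0.8\,\overline{L^*(\hat Z_{01})} + 0.4 \max L^*(\hat Z_{01}) +
  0.1\,\overline{L^*(\hat Z)} + 0.05 \max L^*(\hat Z)$, where $L^*$ is
  the grammar-kernel convolution described next, and $\hat Z_{01}$ the
  per-column argmax binarization (ties broken toward the lowest row, L
  first, for determinism).

**Grammar kernels.** Six 6 x 2 kernels, one per secondary symbol, with a
$+1$ marking the focal symbol in the first column and $-1$ at each
permitted successor in the second: L→{L,E,H,O}, E→{L,E}, H→{L,H},
X→{X,J}, J→{L}, O→{X}. The convolution of a kernel with a one-hot
secondary matrix is exactly 1 at positions where the focal symbol is
followed by a forbidden one; values are clamped to [0, 1] and maximised
over kernels. For the softmax output the same expression is a
differentiable surrogate. As printed, only L may follow J — a chain can
never open directly into a strand or helix; we implement the table as
printed and expose `permissiveStart` to relax it, without guessing intent.
During training, gradient flows through the cross-entropy and the two
soft $L^*$ terms; the argmax-binarized terms are treated as
piecewise-constant (zero gradient), which matches their role as counters.

**Validation split.** The reference holds out 10,000 samples; corpora in
this package are usually far smaller, so below 50,000 designs the split
is 10% (floor 2), recorded in the config.

## The generator

A sequence-to-sequence translator from secondary strings over {L,E,H} to
primary sequences over a 19-letter vocabulary — cysteine is excluded
because disulfides confound the assay — plus a stop token used only in
training targets (generation is length-constrained by the input, so
emitted sequences never contain stop or padding symbols). The encoder and
attention operate on convolutional features; the decoder is a single-layer
LSTM. The reference model has ~128M parameters with unpublished layer
sizes; the default configuration here is deliberately desk-scale
(convolutional encoder 24+24 kernels, attention dimension 16, LSTM hidden
32; the parameter count is printed by `show()`), and all sizes are
configurable. Because source and target are aligned position-for-position,
attention scores combine a learned dot product between conv-derived keys
and a query from the previous decoder state with a Gaussian
monotonic-alignment prior ($\sigma$ = 2 positions) — a package design
choice that speeds convergence at small scale without removing the learned
attention pathway.

Training minimises cross-entropy with plain SGD (gradient-norm clipping at
5) for a configurable number of epochs (default 65, the reference's
stopping point; "iterations" is read as epochs). Stability-weighted
subsets resample the corpus with replacement, with expected multiplicity
proportional to the combined score clamped below at 0.05 (the reference
does not say how non-positive scores were handled; the clamp keeps the
weighting defined), and the number of unique designs drawn is reported.

**Metrics.** Perplexity is the antilog of the mean per-residue
cross-entropy (1 = perfect; 19 = chance on this vocabulary), computed
teacher-forced and excluding the stop position; reference tokens with
probability below 1e-12 are floored and reported. The character error
rate divides Levenshtein distance by reference length. Beam decoding
keeps the `width` best extensions by summed log probability at each step;
no length normalisation is applied since all hypotheses share the input's
length.

## Refinement

Beam-search over single-site substitutions (k = 50, 5 rounds in the
reference protocol; both are arguments). Each round enumerates all
19-per-site substitutions of each base, applies the constraint regime —
forbidden target residues (none / {W} / {A,F,I,L,M,V,W,Y}) and optionally
the rule that neither protease's USM prediction may decrease relative to
a reference — pools, deduplicates, ranks with the pluggable scorer
(the evaluator's combined score by default), records the top-1 as the
round's product and carries the top-k as new bases. The previous round's
product is kept in the candidate pool, which guarantees non-decreasing
product scores by construction. Two open points resolved as package
choices: the USM-nondecrease reference defaults to the immediate parent
(an `original` mode compares to the round-0 sequence), and the beam
resets to exactly the top-k pooled children each round. Ties are broken
by the lexicographic profile of mutated positions, then alphabetically —
determinism matters more than which equal-scoring variant wins.
Substitutions may revert earlier changes; products report net Hamming
distance. The control arm applies one uniformly random constrained
substitution per round. The substitution-effect matrix aggregates
(from, to) score changes by condition with Welch two-sample two-tailed
t-tests, uncorrected as in the reference figure, with an optional
Benjamini-Hochberg column.

## Calibration

Ladder designs shared between chips are fit by orthogonal (total least
squares) regression — both axes carry comparable assay error; the error
variance ratio defaults to 1 and is configurable — and the fitted line
maps the new chip onto the reference scale, per protease. Between
expression vectors, a piecewise-linear orthogonal regression constrains
data up to a best-fit inflection $c$ to lie along $y = x$ with a free
slope $s$ above (continuous at $c$): the saturating vector compresses
high responses. The fit minimises summed squared orthogonal distances to
the two-segment curve over a coarse (c, s) grid followed by a Nelder-Mead
polish — the profile over $s$ has flat plateaus (all points falling back
to the identity segment), so a line search alone is unreliable. Noiseless
data are recovered to 1e-6. When the fitted $s$ is within 0.05 of 1 the
data show no detectable curvature: $c$ is reported as $\max(x)$ with a
flat-fit flag. The map is inverted exactly before the ladder regression
when supplied to `reconcileChip`.

## The synthetic corpus

The generator emulates the *structure* of the assay data, not its
biophysics: topology-templated secondary strings (loops of 2--4 residues
around helix/strand elements), primaries drawn position-by-position from
class-dependent preferred residue sets (hydrophobics at helix heptad-like
phases {0,3} and alternating strand phases; hydrophilics elsewhere in
elements; turn-formers G,P,D,N,S,T in loops) with a per-design bias
drawn from U(0.55, 0.95). The hydrophobic class {A,F,I,L,M,V,W,Y} is the
same set used by the refinement constraints — one definition reused
across modules.

Per protease, the unfolded baseline is linear in cleavage-prone residue
fraction (K/R for trypsin; F/Y/W/L for chymotrypsin); folded protection
is a logistic function of the pattern-match fraction, scaled to
[0, 2.5] so synthetic stability scores occupy roughly -1 to 3. The
logistic midpoint (0.70) and width (0.055) place chance-level match —
what a scramble achieves against its parent's pattern, empirically about
0.5 — near zero protection, which is the construction the scramble
controls require. Observed EC50 = ceiling-compressed (c = 4.5, s = 0.5
by default) baseline + protection + Gaussian noise (sd 0.1);
credible-interval widths are log-normal (meanlog log 0.8, sdlog 0.75),
placing ~10% of widths above the CI-filter threshold of 2 so the filter
has something to remove. Chip pairs share ladder designs spanning >= 90%
of the EC50 range, with a linear distortion (slope 1.2, intercept -0.4)
plus noise injected into the second chip.

Everything is reproducible bit-for-bit from (config, seed): all
randomness goes through locally seeded RNG with the caller's stream
restored afterwards.

**What passing tests on this corpus do and do not show.** The corpus has
a clean, local, additive generative rule; real assay data have epistasis,
topology-specific biases, measurement artefacts and heavier noise.
Synthetic results demonstrate that the machinery is implemented correctly
and can recover a known signal end to end — not that the models reach any
particular accuracy on real designs.

## Problem sizes and numerical choices

Test and acceptance runs use desk-scale sizes chosen to exercise every
code path with comfortable statistical margins: 2,000-design corpora for
end-to-end training checks, 100 designs for the guided-vs-random
refinement comparison (3 rounds, greedy beam), generator checks at
n = 1,000 pairs, calibration recovery at n = 500. The evaluator's
reduced configurations keep the reference kernel widths (5/9/17) with
far fewer kernels (16–24 / 12–16 / 4–8) and 48/24 dense units.

**Desk-scale evaluator training.** Two reference-protocol choices do not
transfer to a small multi-task network on 2,000 designs, and the
end-to-end runs deviate from them deliberately (both remain defaults for
the full-scale configuration). First, early stopping on the composite
validation loss: at this scale the composite is dominated by the
secondary-structure term and reaches its minimum around epoch 15–20,
while the stability head's held-out accuracy keeps improving through
epoch 40+; restoring the "best" snapshot therefore returns an
undertrained stability head. The end-to-end runs instead train a fixed
50-epoch budget and keep the final weights (`restoreBest = FALSE`).
Second, dropout strength: with a 4-channel final conv layer, 20%
dropout induces a substantial mismatch between training-time and
inference-time activation statistics, which shows up as a compressed
output scale (predictions ~1.6–2× too narrow). Easing dropout to 0.15
restores calibration without measurable overfitting at this corpus
size. Other numerical choices:
probability floors at 1e-12 inside logs; clamping means clamp to [0, 1];
gradient-norm clipping at 5; Glorot-uniform initialisation with
deterministic seeds; argmax ties broken toward the first index
everywhere.

## Known limitations

* Sequences longer than 145 residues cannot be encoded; the stack is a
  mini-protein tool by construction.
* The evaluator's secondary head is a dense layer over the whole window,
  so its parameter count dominates the model; at full reference scale
  this is ~15M weights in one matrix.
* The generator's full-scale configuration is not reproduced; training
  at 128M parameters is out of desk scope by design.
* No uncertainty quantification on any prediction; scores are point
  estimates.
* The comparator stream assumes naturals and their scrambles are
  length-matched (they are, being permutations).
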