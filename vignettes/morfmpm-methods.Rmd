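---
title: "Predicting MoRFs with a minimax probability machine: models and methods"
author: "morfmpm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting MoRFs with a minimax probability machine: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Molecular Recognition Features (MoRFs) are short segments — typically 5 to 25
residues — embedded in longer intrinsically disordered regions (IDRs) that
fold when they bind a partner protein. A MoRF predictor assigns every residue
of a protein a score for being part of such a segment. `morfmpm` implements a
deliberately simple design: sequence-derived features only (no PSSMs, no
outputs of other predictors), a multi-window averaging scheme that encodes
local versus contextual composition, and a linear classifier with a
distribution-free performance guarantee.

## Per-residue features

Sixteen features are evaluated on every window:

* **13 AAindex scale averages.** Physicochemical property scales
  (accessions `CIDH920101`, `EISD860103`, `NISK860101`, `QIAN880105`,
  `ROBB760101/08/12/13`, `CORJ870103/06/07/08`, `MIYS990104`), each a map
  from the 20 amino acids to a real value. The window feature is the mean
  scale value over the window.
* **Topological entropy.** A normalized count of distinct sub-words: for a
  window of `len` residues the sub-word length `n` is the largest integer with
  `20^n + n - 1 <= len` (so `n = 1` for any window under 20 residues — all
  defaults, since windows of 10/45/90 sit far below the `20^2` bound), `p`
  counts distinct `n`-sub-words of the first `min(len, 20^n + n - 1)`
  positions, and the value is `log(p) / (n log(min(20^n, len - n + 1)))`,
  clamped to `[0, 1]`. Homopolymers score 0; maximally diverse short windows
  score 1. Shannon entropy (in bits, over the observed residue frequencies)
  is also provided as a feature kind, though it is not in the default set.
* **Two disorder propensities** (Remark 465-style and Deleage/Roux-style
  coil-vs-structure), used exactly like AAindex scales. The shipped tables
  (`inst/extdata/globplot_synthetic.aaindex1`) are **synthetic stand-ins**:
  they encode the standard disorder-promoting (P, E, S, Q, K, G, D, A) versus
  order-promoting (W, C, F, I, Y, V, L, M, H) residue ranking rather than any
  published table, and nothing in the package's behaviour or tests depends on
  their particular values.

Unknown residues (`X`, and any letter outside the 20-residue alphabet, which
the FASTA reader maps to `X` with a warning) take the mean of a scale's 20
values in averages and are excluded from entropy alphabets: mean imputation
leaves window averages unbiased, while a placeholder letter has no meaning as
an entropy symbol.

## The three-window averaging scheme

For a window size `N`, the sequence is padded with `N0 = floor((N-1)/2)`
virtual zero positions at each end and a window of length `N` slides with
step 1, giving `L + 2*N0 - N + 1` windows. Pads contribute zero to a scale
average's numerator but are counted in its denominator (the window feature is
"diluted" near the ends), and are dropped before entropies. Every window's
feature vector is then assigned to each residue it covers, and each residue
averages what it received — equivalently, row `j` is the mean of the window
vectors with indices in `[j + N0 - N + 1, j + N0]`, clamped to the valid
range, divided by the count actually present.

Two implementation notes. First, a symmetric three-branch closed form for
this average (left edge / interior / right edge, with the interior dividing
by `N`) is exact only for odd `N`; for even `N` the interior branch's upper
window index can exceed the last window, so the coverage-count form above is
used uniformly — it is the assign-accumulate-divide definition itself, and
the test suite checks bit-for-bit equality against a brute-force oracle over
window sizes 1–90 and lengths 5–120. Relatedly, slice means are computed as
`colSums()/count` rather than `colMeans()` so the final division rounds in
double precision exactly as the oracle's `sum()/count` does. Second,
sequences shorter than a window are handled by clamping the effective `N` to
`L` for that sequence (real proteins are frequently shorter than 90
residues); the clamping is silent unless `options(morfmpm.verbose = TRUE)`.

The default window sizes are 10 (MoRF-local composition), 90 (the disordered
context in which MoRFs sit), and 45 — half the long window — to damp the
noise the long window introduces; this three-window scheme replaces explicit
fixed-length flank modelling. Per-residue vectors are the horizontal
concatenation over windows in ascending size order, 48 columns for the
defaults, which fixes a deterministic model-file layout.

## Feature selection by simulated annealing

Subsets of a scale pool are scored with `J_d = tr(S_w + S_b)`, where `S_b` is
the prior-weighted between-class scatter of the class means and `S_w` the
prior-weighted within-class scatter (each class's sum of squared deviations
divided by its size). Two properties of this criterion are worth knowing:

* **It is label-independent.** `tr(S_w) + tr(S_b)` telescopes to the trace of
  the prior-weighted total scatter about the grand mean, so the criterion
  reduces to (essentially) total per-column variance. It is implemented
  exactly as defined — the identity is verified numerically in the tests and
  flagged here rather than silently "fixed" — and a label-aware alternative
  (`criterion = "between"`, i.e. `tr(S_b)` alone) is available off by
  default.
* **It is additive over columns.** The annealer therefore precomputes each
  column's contribution once and evaluates a subset as a sum, making moves
  O(1).

The annealer runs one move per temperature level — replace one selected
feature with one random unselected feature; accept improvements always and
deteriorations with probability `exp(-|ΔJ_d| / T)` — cooling geometrically
with `T_max = 1`, `T_min = 1e-4`, `r = 0.9995` (≈ 18 420 levels). The **best
state visited** is returned rather than the final state: it is never worse,
and the standard choice when the criterion is cheap to track. Runs are
reproducible from the schedule's seed; `candidate_sweep()` derives per-size
seeds from a master seed so a 10..20 sweep (11 candidate subsets) is one
deterministic call. Selection-time preprocessing conventionally uses the
short window (10) alone.

## The minimax probability machine

Given class moments `(μ₁, R₁)` for MoRF residues and `(μ₂, R₂)` for the rest,
the MPM finds the hyperplane `W'x = b` minimizing the *worst-case*
misclassification probability over all distributions with those moments. The
program reduces to

```
min_W  sqrt(W'R₁W) + sqrt(W'R₂W)    s.t.   W'(μ₁ − μ₂) = 1 ,
```

with margin `κ = 1/objective`, offset
`b = W'μ₁ − κ·sqrt(W'R₁W) = W'μ₂ + κ·sqrt(W'R₂W)` (the two expressions agree
under the constraint and are cross-checked to 1e-8 at every fit), and the
guarantee that either class errs with probability at most `1/(1+κ²)`.

**Solver.** The constraint is eliminated by writing `W = w₀ + F·u` with `w₀`
the minimum-norm constraint solution and `F` an orthonormal null-space basis
(QR); each iteration then minimizes the quadratic majorant
`W'R₁W/β + W'R₂W/η` with `β, η` the current norms — a single least-squares
solve. This iterative-least-squares scheme is a majorize–minimize iteration,
hence monotone; convergence is declared when the relative objective change
falls below `1e-9` (cap 1000 iterations, non-convergence is an error). The
test suite pins the solution against an independent multi-start BFGS
optimization of the same convex objective (relative agreement ≤ 1e-6) and
against the equal-covariance closed form `W ∝ R⁻¹(μ₁ − μ₂)`.

**Preprocessing around the solver.** Features are z-scored with training
means/SDs (AAindex scales live on wildly different units, and MPM scores are
otherwise scale-dependent); constant columns are dropped with a warning.
Covariances are unbiased estimates plus a ridge `1e-6 × mean(diag(R))`
(absolute `1e-6` if the diagonal vanishes) so degenerate classes remain
solvable. Class imbalance (~2% MoRF residues in realistic corpora) is left
as-is: the MPM consumes per-class moments, so imbalance only affects moment
estimation quality, and no subsampling is performed.

**Scores and thresholds.** The decision value is `s = W'x_std − b`; a residue
is called MoRF when `s` *strictly* exceeds the threshold (default 0, so an
exactly-zero score is not a call — the same strict convention is used in
every metric). `calibrate_thresholds()` returns, for each target FPR, the
smallest observed cut point whose achieved FPR does not exceed the target,
supporting the usual practice of publishing thresholds for several fixed
FPRs. No score normalization is applied.

## Evaluation

`confusion()` counts TP/FP/TN/FN at a threshold and reports
`ACC = (TP+TN)/N`, `TPR = TP/N_MoRF`, and `FPR = FP/N_non` — note the
false-positive *rate* is false positives over negatives (the quantity some
write-ups accidentally print as `TN/N_non`, which is specificity; joint
(TPR, FPR, ACC) tables are only mutually consistent with `FP/N_non`).
`roc_auc()` computes the AUC by the rank method with half-credit for ties
(identical to pairwise positive-vs-negative counting, checked exactly against
that oracle and against pROC), and `metrics_at_tpr()` reports achieved
(TPR, FPR, ACC) at the largest threshold reaching each TPR target. All three
accept a three-state mask — 1/0/NA with NA meaning "ignore" — so that
`mask_regions()` can implement the length-stratified protocol where only
short (≤ 30 residues) or only long MoRF regions are scored and the rest are
excluded from both classes.

## The synthetic corpus generator

`generate_morf_data()` exists so every stage — features, selection, MPM,
evaluation — is exercisable end-to-end without any external download. Its
defaults were fixed once, as the package's study conditions:

* 100 sequences of 50–250 residues (desk-scale; real MoRF-bearing proteins
  are often longer, which only makes windows less end-affected);
* one planted MoRF of 5–25 residues per sequence (the standard MoRF length
  convention), placed uniformly, non-overlapping, and at least 10 residues
  from the sequence ends when length permits;
* residues i.i.d.: background from UniProt-like frequencies, MoRF segments
  from the blend `(1−e)·background + e·target` with the target concentrated
  on disorder-promoting residues (P, E, S, Q, K, G, D, A) and `e = 0.8` by
  default. `e = 0` is the null; `e = 1` restricts segments to 8 letters.

Generation is reproducible (identical seed ⇒ byte-identical corpus; the
caller's RNG state is restored). What the generator does *not* emulate:
Markov or motif structure, flank-specific composition gradients,
structure-conditioned sequence, or realistic disorder profiles. Passing
end-to-end checks on this corpus therefore demonstrates that the pipeline
recovers planted *compositional* signal — not that any particular real-data
AUC would be attained.

## Known limitations

* **The synthetic null is not exactly chance-level.** With `e = 0` the MoRF
  and background compositions are identical, yet held-out AUC sits near
  0.55–0.60 rather than 0.50, systematically. The cause is positional, and
  it is built into the study design: planted segments keep 10 residues clear
  of sequence ends, while zero-padding dilutes near-end window features, so
  position-in-sequence alone separates the classes slightly (distance to the
  nearest end scores AUC ≈ 0.55 against null labels, and the MPM — whose
  constraint rescales a vanishing mean difference — converges on exactly
  that positional profile; excluding 45-residue sequence ends moves the null
  AUC most of the way back to 0.5). Interpreting null-corpus AUCs therefore
  requires this positional baseline, and the corresponding chance-level
  check in the test suite fails by this margin by design rather than being
  relaxed.
* The criterion `J_d = tr(S_w + S_b)` is label-independent (above); subset
  selection under it favours high-variance columns, not discriminative ones.
  It is kept for fidelity, with `tr(S_b)` available as an option.
* The two propensity scales are synthetic stand-ins (above); users with
  access to the published GlobPlot tables can drop them in as an AAindex1
  file and rebuild the registry with `read_aaindex1()` + `scale_registry()`.
* Scale-check sizes: the oracle-equality and solver cross-checks run at
  200 sequences × 5 window sizes and 10 random MPM instances respectively;
  the end-to-end recovery checks use 100 training sequences and 100 (strong
  effect) / 300 (null) held-out sequences — the larger null set because
  within-sequence score correlation roughly quadruples the sampling variance
  of a per-residue AUC.

## Reading and writing

FASTA I/O is delegated to Biostrings; interval labels are BED-like
(`seq_id TAB start TAB end`, 0-based half-open, overlaps unioned) while
score tables print 1-based positions — each side of the boundary follows the
dominant convention of its file type. AAindex1 flat files are parsed
natively (accession `H`, description `D`, and the two 10-value `I` rows in
canonical `A R N D C Q E G H I / L K M F P W Y V S T` order; literal `NA`
values survive parsing but are rejected if a feature set references the
scale). Models serialize to versioned JSON with the weight vector, offset,
margin, standardizer, feature set, window sizes and the referenced scales
embedded, so a model file is self-contained for prediction.
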