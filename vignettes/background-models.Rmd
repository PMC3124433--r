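---
title: "Background models for single amino acid repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background models for single amino acid repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saarbg)
```

## The problem

Single amino acid repeats (SAARs) — maximal homopolymeric runs such as
`LLLLL` — are far more frequent in eukaryotic proteins than any standard
sequence model predicts. Deciding whether a particular repeat observation is
*unusual* therefore hinges on the background model: a model of functionally
meaningless variation against which observations are scored. This package
provides two families of backgrounds and the machinery to validate them and
to use them in an enrichment test:

1. **Markov-chain baselines** (orders 0–3) with *exact* expected counts of
   maximal runs, the classical local-dependency models.
2. **Zero-inflated two-stage regression models**: a logistic gate for the
   probability that a protein contains any repeat of a given residue and
   length, combined with a conditional count regressor — either a sparse
   Bayesian kernel machine (ZIRVM) or a fixed polynomial basis (ZIPol) —
   on log-scale covariates.

Everything is exercised on seeded synthetic proteomes with ground truth, so
the full pipeline is testable without any sequence download.

## Counting repeats

A repeat of residue $a$ and length $n$ means a *maximal run* of $a$ of
length at least $n$; maximality is pinned by the decomposition of a
sequence into blocks. What is modelled throughout is the cumulative count
$c(n)$, the number of maximal runs of length $\ge n$ in one protein: it is
monotone in $n$, and summing $c(n)$ over all $n \ge 1$ recovers the total
residue occurrence count, two invariants the test suite checks on random
sequences.

```{r}
find_maximal_runs("ACDFLLLLLGWSLLV", "L")
cumulative_counts(find_maximal_runs("ACDFLLLLLGWSLLV", "L"), 6)
```

Ambiguity letters (B, J, O, U, X, Z) break runs, count towards the protein
length $l$, and contribute to no standard-residue frequency $f_{AA}$. This
is a conservative choice — it can only reduce repeat counts — and is ours;
database conventions vary. Positions are 1-based; a signal peptide covers
positions $1..c$ ("cleavage after position $c$") and the mature sequence
the rest.

## Exact Markov expectations

For a chain of order $k$ fitted from $(k{+}1)$-tuple frequencies (tuples
never span two proteins; contexts never seen in training receive an
add-one-smoothed uniform row), the expected number of maximal runs of
length $\ge n$ in a length-$L$ sequence is computed exactly by summing over
start positions $i$ the probability of

$$\{\,i = 1 \text{ or } X_{i-1} \neq a\,\}\ \cap\ \{X_i = \dots = X_{i+n-1} = a\},$$

with the position marginals propagated by a forward recursion over
$k$-letter contexts initialised at the empirical context distribution. The
order-0 case has the closed form $p^n\,(1 + (L-n)(1-p))$, which the test
suite uses as an analytic cross-check of the recursion; orders 0–2 are
additionally verified against exhaustive enumeration of all strings on a
binary alphabet. Model uncertainty for the pooled observed/expected ratio
is estimated by Monte-Carlo simulation from the chain (default 1,000
replicates, seeded) rather than by a Gaussian approximation: it is
assumption-free and directly testable against the exact expectation.

Ratios are always pooled — $\sum \text{observed} / \sum \text{expected}$
over a protein set — because per-protein ratios are undefined for the many
repeat-free proteins.

## The zero-inflated models

Per residue $a$, training proceeds in two stages on covariates measured
per protein:

* **Stage 1 (presence gate).** For each repeat length $n$, a logistic
  regression of the indicator $c(n) \ge 1$ on $(\log l, \log(f_a +
  \varepsilon))$ with $\varepsilon = 1/(2l)$ guarding $\log 0$. A
  classification threshold balancing false positives against false
  negatives is fitted and stored for every $(a, n)$.
* **Stage 2 (conditional count).** A regression of $\log c(n)$ on $(\log
  n, \log l, \log(f_a + \varepsilon))$, fitted only on repeat-containing
  observations, after a weighted subsample that balances bins of protein
  length, composition and repeat length (total capped at 2,000 points) to
  counter the strong skew of repeat abundance. The regressor is either the
  sparse Bayesian kernel machine below (ZIRVM) or an ordinary
  least-squares fit on the full polynomial basis of total degree 3 in the
  three covariates — 20 terms, identical across residues (ZIPol).

Two modelling choices deserve explanation because we measured their
consequences and chose against the simpler alternative:

* **Soft versus thresholded gate.** Combining the stages by a hard
  threshold (predict $\exp(\hat m(x))$ when the gate probability passes
  its balanced threshold, else 0) conditions the count stage on exactly
  the proteins where the count surface is highest. Whenever the presence
  classes overlap appreciably — always, at moderate sample sizes — the
  pooled prediction acquires a residue-dependent selection bias of 5–15%.
  The default therefore combines the stages as the mixture $\hat p(x)
  \cdot \widehat{E}[c \mid c \ge 1, x]$, which is immune by construction;
  thresholded gating remains available (`soft_gate = FALSE` in
  `training_config()`, `soft = FALSE` in `predict_expected_count()`), and
  the thresholds are fitted and stored either way. At very large training
  sizes the gate probabilities polarise and the two rules coincide.
* **Retransformation.** The count stage models $\log c$; plain
  exponentiation estimates the conditional *median*-like quantity and
  under-predicts $E[c]$ wherever the conditional counts are dispersed (at
  short repeat lengths, where $c$ of 2 or 3 is common). Predictions are
  therefore multiplied by a smearing factor — the mean exponentiated
  training residual, computed per repeat length — which is ~1 at lengths
  where nearly every positive count is exactly 1 and rises to ~1.1 where
  the dispersion sits. Measured on synthetic proteomes this moves pooled
  validation ratios from a 7–10% systematic offset to within ~3% of 1.

### The sparse Bayesian kernel stage

The ZIRVM count stage is a relevance vector machine: a Gaussian kernel
basis centred on the (standardised) training points plus a bias column,
with an individual precision hyperparameter per basis weight. Precisions
are optimised by marginal-likelihood maximisation with the fast sequential
scheme — bases are added, deleted or re-estimated one at a time, always
applying the action with the largest likelihood gain; when the basis set
is stable at the current noise level the noise variance is re-estimated,
and the two steps alternate to joint convergence. Most precisions diverge
and their bases are pruned, leaving a handful of relevance vectors; the
whole per-residue model (gate coefficients, thresholds, kernel weights)
retains orders of magnitude fewer parameters than a third-order Markov
chain.

Numerical safeguards, each triggered by a measurable failure mode: bases
nearly collinear with an active one are never added (the posterior becomes
numerically singular); the noise precision is capped relative to the
response variance (on noiseless data the likelihood is unbounded);
re-estimation of a basis that repeatedly claims the same gain is frozen
until the active set changes (cancellation at extreme precisions can
fabricate gains). The classical full re-estimation route (`method = "em"`)
is retained as an independent implementation — with geometric damping of
the precision updates to suppress its 2-cycles — and the two routes are
required to agree in the test suite, alongside a cross-check against
`kernlab::rvm`.

The kernel width defaults to the median heuristic on pairwise training
distances, which is adequate for the smooth, monotone count surfaces this
pipeline fits and costs one fit. `width = "evidence"` compares a small
width grid by marginal likelihood and matters when the response has
features narrower than the typical covariate distance.

## Validation machinery

Model quality is assessed by repeated random hold-out validation: `R`
(default 100) independent splits into two-thirds training and one-third
test — read as repeated subsampling, since 100 *disjoint* folds at a 2:1
ratio are arithmetically impossible. Per repetition and $(a, n)$ cell the
test score is the pooled observed/predicted ratio; the score SD is the
model uncertainty, and an empirical p-value compares the score
distribution to the perfect score of 1 using the add-one convention
$p = 2(\min(\#\{s \le 1\}, \#\{s \ge 1\}) + 1)/(R + 1)$, which can never
return 0 from a finite number of repetitions. Per-residue summaries use
the RMSE of $\log(\text{obs}/\text{pred})$ over repeat lengths —
log-scale, so over- and under-prediction weigh symmetrically — with a
continuity correction of one half when exactly one side of a cell is
zero. Multiplicity across repeat lengths is handled by Holm's step-down
adjustment.

## The signal-peptide use case

Signal peptides are transient N-terminal targeting sequences with a
hydrophobic core. To test repeat enrichment in signal peptides relative to
the mature parts, predictions from two signal-peptide predictors are
combined conservatively (both must agree on the cleavage site, at least
one score must meet its default threshold, and the worse score at least
half of its threshold), the background is trained **on the mature
sequences** of the called proteins, and per $(a, n)$ both the whole-protein
and the mature-sequence pooled ratios are computed against it. The
statistic is their difference, reported in units of the cross-validation
score SD, with a one-sided empirical p-value against a null distribution
of *pairwise differences* between cross-validation scores — our reading
of "compiled as before" for a difference statistic: it has the right
scale, costs nothing beyond the validation run, and errs conservative
because it ignores the positive correlation between the two ratios.
Cells whose mature-side pooled count falls below `min_observed` (default
10) are reported untestable rather than risking spurious flags from one
or two counts — the same support logic that excludes tryptophan, whose
long repeats are too rare to validate, from model training. Holm
adjustment is again per residue across repeat lengths; the first-phase
check of a common background (`deviation_from_background()`) uses
two-sided p-values per its hypothesis.

## What the synthetic proteomes emulate

`synthetic_config()` defaults define the study conditions used throughout
the tests: 5,000 proteins; log-normal lengths (median 330 residues, sdlog
0.45, floor 30); per-protein composition drawn from a Dirichlet around
typical database frequencies (concentration 100, so residue frequencies
vary a few-fold across proteins as they do across real sequence families);
and a zero-inflated run-injection process. Per protein and residue an
injection channel opens with probability 0.15; when open, a Poisson number
of runs — mean 2 at the reference length 300, scaled by $l$ and by
$f_a$ relative to the base frequency, so that repeat abundance genuinely
depends on the covariates the regressions use — overwrites non-overlapping
positions (overwriting keeps the length law exact; infeasible placements
are resampled, then logged and skipped).

Injected run lengths are bimodal: doublets/triplets (bulk, length 3 with
probability 0.55) plus an expanded component of length $5 +
\text{Poisson}(1)$ with weight 0.25. The bimodality is deliberate and
load-bearing. A geometric tail has a constant continuation hazard, which
is exactly reproducible by a fitted high-order chain (measured order-3
pooled ratio ≈ 1.0), and a heavy *mixture-of-geometrics* tail makes
high-order chains **over**-predict, because tuple windows are dominated by
the persistent runs whose blended continuation then extends the abundant
composition-driven short runs too far. Runs that either stay short or
expand to just beyond the local-dependency range — the signature of
slippage-driven repeat expansion — are what produce the regime actually
observed for real repeats: every Markov order under-predicts, less so
with increasing order.

Signal peptides, when enabled, are *prepended* (initiator methionine, a
charged start, an A/L/I/V/F-rich hydrophobic core, a short polar stretch),
so the mature sequence remains exactly the unmodified generator output;
with probability $\delta$ a leucine run of length $\ge 5$ is embedded in
the core. Ground truth records compositions, injections and boundaries,
and each protein derives its RNG stream from the master seed by a counter,
so partial regeneration is stable.

What the generator does **not** emulate: homology and shared domain
structure between proteins, position-dependent composition beyond the
signal segment, approximate/degenerate repeats, and any evolutionary
mechanism. Passing tests therefore show that the estimators recover the
structure they assume, at realistic sizes — not that real proteomes follow
that structure.

## Problem sizes and runtime choices

The package's study conditions are deliberately desk-scale: proteomes of
5,000 proteins (enrichment replicates use 800 with half the proteins
secreted), stage-1 fits capped at $10^5$ points, the stage-2 balanced
subsample capped at 2,000 (the cap that matters in practice), 100
hold-out repetitions for model validation and 50 within each enrichment
replicate, and repeat lengths 5–10 for modelling — lengths below five are
expected by chance for typical protein lengths and are kept only for the
counting identities. At these sizes the full validation pipeline runs in
a few minutes on one core.

## Known limitations

* The pairwise-difference null for the enrichment test is conservative;
  with strong effects (as in the power analyses) this is immaterial, but
  marginal enrichments will be under-called.
* The mixture gate means the stored classification thresholds do not
  influence default predictions; they are reported for the thresholded
  variant.
* Stage-2 extrapolation beyond the trained repeat-length range is refused
  rather than attempted.
* Tryptophan is excluded by default for want of validatable repeat
  counts; any residue with no repeat-containing protein is skipped with a
  warning at training time.
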