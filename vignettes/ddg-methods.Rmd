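---
title: "Methods: sequence-based prediction of mutation-induced stability changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based prediction of mutation-induced stability changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqddg)
```

## The prediction problem

A single amino-acid substitution changes a protein's folding free energy by
ΔΔG = ΔG(mutant) − ΔG(wild-type) (kcal/mol). `seqddg` estimates ΔΔG from
sequence-derived information only: the protein's residue string and a
position-specific scoring matrix (PSSM) produced by an iterative profile
search such as PSI-BLAST. No structure is used, which is the point — the
method remains applicable when no structure or reliable model exists.

Under our declared sign convention positive ΔΔG is destabilizing. The
convention is configurable at the evaluation layer
(`stability_score_correlation(..., destabilizing_positive =)`) because
experimental compilations differ; what matters is that the package states
one and carries it explicitly.

### Assumptions

* Single-chain proteins and single point missense mutations; positions are
  1-based and mutations use `WposM` notation.
* The PSSM's rows align 1:1 with the sequence (checked at prediction time).
* Experimental training labels are exchangeable within a protein — the
  cross-validation protocol shuffles records, not proteins. For an estimate
  of generalization to *unrelated* proteins use `homology_partition()`,
  which is stricter and gives systematically lower correlations.

## Feature construction

Four groups, concatenated in fixed order; 319 columns at defaults.

**PsePSSM (160 columns).** The PSSM is first squashed elementwise by the
logistic function `f(x) = 1/(1+e^{-x})` so scores live in (0,1). The
descriptor is the 20 column means followed, for each lag `g = 1..lag_max`,
by the 20 lagged mean squared differences
`φ_j^g = (1/(L−g)) Σ_{i=1}^{L−g} (P_{i,j} − P_{i+g,j})²`.
The means summarize overall column conservation; the lag terms measure how
fast conservation decorrelates along the chain. `lag_max = 7` by default;
values ≥ L are rejected because the denominator becomes non-positive.

**Window conservation scores (140 columns).** The rows of the normalized
PSSM at the mutation site and `window_flank = 3` residues on each side
(an `XXXCXXX` stretch), flattened row-major. Windows that extend past a
terminus are zero-padded: padding keeps the dimensionality fixed for every
mutation, and a zero row is a natural "no information" value on the (0,1)
normalized scale. (The alternative — clamping to the terminal row — would
duplicate real conservation signal where none was observed.)

**Sequence neighbors (10 columns).** The `neighbor_span = 5` residues to
the left (outermost first) and right (innermost first) of the site, encoded
as ordinal integer labels: the 0-based index of the residue in the fixed
PSI-BLAST column order, with 20 as the out-of-range pad label. We chose
ordinal over one-hot as the default because each neighbor is a single
categorical attribute with 20 levels and gradient-boosted trees split on
such codes natively; a `"onehot"` switch (21 indicators per neighbor) is
available in `feature_config()` for learners that need it.

**Physicochemical properties (9 columns).** For the substitution wt→mut:
net volume, net hydrophobicity, mutation type, net flexibility, chemical
property, size, polarity, hydrogen bond, and label hydrophobicity. "Net"
scales are `scale(mut) − scale(wt)` (antisymmetric by construction);
categorical attributes are the integer class code of the *mutant* residue;
"mutation type" is the chemical-class transition code
`7·(class(wt)−1) + class(mut)`, which distinguishes direction. The scales
(Zamyatnin volumes, Kyte–Doolittle hydropathy, Bhaskaran–Ponnuswamy
flexibility, standard class assignments) ship as a versioned data table
(`physchem_table("1.0")`); swapping scales requires no code change.

A deliberate structural property, verified by tests: the first three groups
depend only on the protein and the mutated *position*; only the
physicochemical block sees the mutant residue.

### Alphabet order

All residue indexing uses PSI-BLAST's native ASCII column order
(`ARNDCQEGHILKMFPSTWYV`), recorded on every PSSM object. Nothing assumes
alphabetical order.

### PSSM normalization

The logistic squash is the default and what the PsePSSM literature uses;
`normalize_pssm()` also offers `"identity"` (raw log-odds) and `"zscore"`
(per-column standardization) because the best choice is not settled for
every downstream learner. The PsePSSM and window groups both consume the
normalized matrix, keeping the two evolutionary groups on one scale.

## Model and evaluation protocol

The learner is a gradient-boosted regression-tree ensemble (squared-error
loss) via `xgboost`. Defaults: 500 rounds, depth 4, learning rate 0.05, no
row/column subsampling, λ = 1, single thread, seeded — fully deterministic.
`grid_search()` tunes over a user grid (default: trees {200, 500}, depth
{3, 5, 7}, η {0.05, 0.1}, subsample {0.8, 1.0}) by k-fold CV with one
shared fold split, choosing the best mean CV Pearson correlation with ties
broken by lower MSE, then grid order — an exhaustive, reproducible rule.

`repeated_cv()` implements the evaluation protocol: per repeat, a fresh
seeded shuffle, folds of sizes differing by ≤ 1, every record tested
exactly once per repeat; per-fold PCC/MSE/MAE with means and standard
deviations over all repeat × fold cells. At full scale the protocol is 100
repeats of 5-fold CV; tests and the acceptance script use 1–5 repeats,
which bounds the Monte-Carlo error of the mean PCC at our problem sizes
well below the tolerances we check against.

`group_importance()` sums the ensemble's per-feature gain importances
within each feature group and normalizes to 1 across groups; groups never
split on get 0.

### Homology-aware splitting

`sequence_identity()` is Needleman–Wunsch global alignment with match +1,
mismatch 0, gap −1, identity = matches / alignment length — a simple,
symmetric, reproducible scheme (delegated to `Biostrings`). No community
standard exists for the "30 % identity" screen used in stability
benchmarks, so the package declares its scheme rather than guessing
another tool's. `homology_partition()` greedily fills a test pool in
seed-shuffled protein order while the pool respects the identity bound
against all remaining proteins and the record-count cap; greedy is not
optimal but is deterministic and adequate at the scales involved
(hundreds of proteins). If no protein can be isolated the function errors
rather than silently returning a leaky split.

### Fisher z comparison

`fisher_z_test()` treats the two correlations as coming from independent
samples: `z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3))`, two-sided
normal p. When two predictors are evaluated on the *same* mutations a
dependent-correlation test would be more powerful; we implement the
independent form, which is conservative in that situation, and report
two-sided p-values throughout.

## The synthetic-data generator

`synth_dataset()` emulates exactly the inputs the predictor consumes:

* random sequences (uniform background by default, configurable);
* per-protein PSSMs whose column profiles favor the true residue with a
  tunable `conservation` sharpness, written as integer half-bit log-odds
  (`round(2·log₂(p/background))`) — integers because that is what
  PSI-BLAST prints, which also makes the ASCII file round-trip exact;
* random substitutions validated against their sequences;
* targets `y = w·features + N(0, σ²)` with weights `w` on named feature
  columns.

Because the signal is linear in stored features, the best achievable test
correlation is the closed form `sd(signal)/√(var(signal)+σ²)`, and
`synth_config(target_ceiling =)` calibrates σ to a requested ceiling from
the realized signal spread. The default weights put all signal on three
physicochemical columns (net volume 0.012 /Å³, net hydrophobicity 0.18,
net flexibility 3.5), chosen once so that generated ΔΔG values have a
spread of roughly 1 kcal/mol and a range of a few kcal/mol — the magnitude
of real mutation-induced stability changes. A nonlinear variant
(`interaction =`) adds a product term for model-selection tests that need
depth to matter.

What the generator does *not* emulate: the destabilizing-mutation bias of
real thermodynamic databases, correlations between features and residue
identity that arise from real evolution, PSSM estimation noise from finite
alignments, or shared homology between proteins. Passing recovery tests
therefore demonstrate that the pipeline is implemented correctly — features
computed as defined, protocol leak-free, model able to extract known
signal — not that any particular correlation will be reached on
experimental compilations.

## Problem sizes and numerical choices

The reference computation (tests and `scripts/acceptance.R`) uses 40
proteins × 50 mutations (n = 2000), ceiling 0.9, with 1–2 repetitions of
5-fold CV; the protocol-arithmetic checks use n = 100 with 100 repeats and
a deliberately tiny model. At these sizes the recovery study reproduces the
ceiling to within ≈ 0.03–0.04 (trees approximate the linear signal, never
exactly) and the noiseless variant reaches CV PCC ≥ 0.998.

Other numerical decisions:

* PsePSSM equals a naive double-loop evaluation of its definition to
  1e−12 (property-tested) — the vectorized path introduces no drift.
* All seeded helpers save and restore the caller's RNG state, so library
  calls never perturb user scripts.
* Degenerate inputs fail loudly: `wt == mut` specs, wild-type/sequence
  mismatches, lags ≥ L, non-20-column PSSM rows (with line numbers),
  zero-variance correlation inputs, |r| = 1 or n ≤ 3 in the z-test.
* Grid ties are broken deterministically (PCC, then MSE, then grid order);
  CV fold assignments are generated up front from the seed, so model
  training cannot perturb the folds.

## Known limitations

* Trained on synthetic data the package ships no fitted model of real
  ΔΔG; users supply their own experimental compilation and PSSMs to train
  a production model.
* The greedy homology partition may return fewer test proteins than the
  requested fraction when homology clusters are large.
* The identity scheme is intentionally simple; substitution-matrix-based
  identity (e.g. BLOSUM-weighted) would alter borderline 30 % decisions.
* The independent-sample Fisher z-test is conservative for paired
  comparisons on a common test set.
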