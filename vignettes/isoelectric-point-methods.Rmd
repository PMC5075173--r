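---
title: "Methods: charge model, curation, benchmarking and pKa optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: charge model, curation, benchmarking and pKa optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipcalc)
```

## The charge model and its assumptions

`ipcalc` models a polypeptide as nine independent ionizable groups: the
side chains of Cys, Asp, Glu, His, Lys, Arg, Tyr and the free amino and
carboxyl termini. Each group's fractional charge at a given pH follows the
Henderson–Hasselbalch logistic: negative groups contribute
$-1/(1+10^{pK_a - pH})$, positive groups $+1/(1+10^{pH - pK_a})$, and the
net charge is the multiplicity-weighted sum. The isoelectric point is the
pH at which the net charge vanishes.

This is deliberately a *simple* model. It assumes free termini (both can be
disabled for chemically blocked ends), all cysteines as free thiols (no
disulfides), no post-translational modifications, and no electrostatic or
solvent-accessibility coupling between groups. These are exactly the
factors that make experimental pI deviate from any sequence-only
prediction; the benchmarking machinery in this package exists to quantify
that residual error, not to eliminate it.

Sequence handling: input is upper-cased and whitespace-stripped. Letters
outside the 20-residue alphabet (ambiguity codes `B/Z/J/X`, rare residues
`U/O`, stops, gaps) carry no charge model and are skipped with one
aggregated warning. Selenocysteine (`U`) is *not* mapped onto Cys: the
model enumerates exactly seven side chains, and silently giving Sec a thiol
pKa would be a stronger claim than skipping it.

## Solving for the isoelectric point

The net charge is strictly decreasing in pH, so the root is unique and
bisection is exact and fast. Design choices:

* **Bracket [0, 14].** The standard pH scale. Both endpoints are
  sign-checked first; a custom pKa set that yields constant sign on the
  bracket (e.g. only basic groups with the C-terminus disabled) raises an
  error rather than returning a fabricated value.
* **Warm start at pH 6.68** — the average pI over a large protein database
  — implemented as one initial sign test that selects the sub-bracket
  `[0, 6.68]` or `[6.68, 14]` before regular halving. This preserves the
  classic convergence behavior (~13 iterations to 0.001) while keeping a
  guaranteed bracket.
* **Convergence**: bracket width ≤ `precision` (default 0.001 pH); the
  midpoint is reported, so the answer is within `precision/2` of the true
  root. The iteration count is bounded by `ceil(log2(14/precision))`.

A sequence with *no* active ionizable group has identically zero charge and
no pI; that is an error, not a number.

## The pKa registry

Seventeen published nine-parameter sets are built in. Notable storage
decisions, each carried as a `provenance` note on the set:

* **Patrickios** is a six-parameter teaching model: Cys, His and Tyr do not
  ionize at all. The three groups are stored as `NA` (zero contribution)
  and the set is flagged `simplified = TRUE`, which excludes it from every
  consensus panel. Its printed six values are mapped by column: termini
  11.2/4.2, Asp = Glu = 4.2, Lys = Arg = 11.2.
* **Grimsley** Arg (12.04) and **Dawson** termini (8.2/3.2) are later
  imputations (average over other sets; borrowed from Sillero), stored as
  printed with notes.
* The **Wikipedia** set has no primary literature reference; it is kept as
  a literal constant table and says so.
* **Bjellqvist** and **ProMoST** exist in fuller positional variants (17
  and 72 parameters); only their nine-parameter reductions are included
  here — positional models are out of scope.

Two registry-wide sanity invariants are enforced by tests: every value lies
in (0, 14), and in every set the acidic side chains sit below the basic
ones (`pKa(D) < pKa(K)`, `pKa(E) < pKa(R)`), which guards against
transcription errors.

User sets are flat `GROUP<TAB>value` text files; writing uses 17
significant digits so every set round-trips bit-exactly.

## Dataset curation

Experimental pI compilations are noisy: replicate measurements, duplicate
entries across source databases, and outright annotation errors. The
pipeline mirrors the established curation recipe:

1. **Merge & average.** Records without any parseable measurement are
   dropped (counted). Byte-identical sequences are merged, pooling all
   measurements; the consensus pI is their arithmetic mean.
2. **Outlier removal.** A record is discarded when the *squared* difference
   between its consensus pI and the mean pI predicted by a panel of
   literature pKa sets exceeds a threshold — 3 for proteins (≈ 1.73 pH) and
   0.25 for peptides (0.5 pH). The inequality is strict (`>`); the boundary
   case stays in. The panel excludes Patrickios and the IPC sets so that no
   optimized method is favored by the filter it will later be scored on.
   "Mean squared error" is read as the per-record squared deviation — the
   only reading consistent with the ≈1.73-pH gloss.
3. **Redundancy clustering.** Greedy incremental clustering in decreasing
   length order (the CD-HIT scheme): a record joins the first cluster whose
   representative it matches at ≥ 0.99 global identity, defined as matching
   positions over the shorter sequence, end-anchored and ungapped. At this
   threshold sequences are near-identical, so a full alignment engine adds
   nothing; the approximation is documented rather than hidden.
4. **Split.** `round(0.75·N)` records to training, the rest to test,
   reproducibly from a seed. The test quarter is untouched by optimization.

Counts reconcile at every run:
`input = dropped + merged + outliers + redundant + kept`.

## Benchmark statistics

* **RMSD** in pH units is the primary score.
* **Percent difference** between two methods is `100·(10^{ΔRMSD} − 1)`,
  because pH is a base-10 log scale. The formula is antisymmetric in sign
  around equality and monotone in its first argument.
* **Outliers**: count of records with squared error above the threshold.
* **Avg_pI** is computed per record (mean prediction over the panel for
  *that* sequence), never as an average of table rows; the benchmark table
  asserts this internal consistency in tests.
* **R²** is reported as a diagnostic only. A nine-parameter charge model is
  not a linear explanation of experimental pI, and a high correlation does
  not certify accuracy; RMSD does the scoring.

Formatted output rounds to the conventional one decimal for percent and
two for pI; machine-readable output (TSV/JSON) always carries full
precision, since published tables rounded inconsistently and full precision
is the only reproducible contract.

## pKa-set optimization

The cost of a candidate nine-parameter vector is the RMSD between the
dataset's consensus pI labels and the pI computed under the candidate. The
search:

* **Bounds** of ±2 pH units around the seed set (a published pKa table),
  clamped to (0, 14). Every evaluated point, and hence the final averaged
  set, stays inside the box.
* **Local refinement** uses `stats::optim` L-BFGS-B — a bounded
  quasi-Newton method with finite-difference gradients. The contract that
  matters (bounded descent: never return a point worse than the start) is
  enforced by a guard, so the specific minimizer is pluggable.
* **Solver precision inside the cost** is 1e-5 (`solver_precision`), finer
  than the 0.001 reporting default. Bisection output is quantized to its
  precision; at 0.001 that quantization is the same order as the
  finite-difference steps and gradients degenerate into noise. At 1e-5 the
  surface is smooth for the optimizer at ~50 % extra iterations per solve.
  The user-facing `pi_cost()` defaults to 0.001 so that it exactly equals
  `rmsd()` over ordinary solver outputs.
* **Basin-hopping**: `n_hops` local minimizations, the first from the seed,
  each later one from a uniform ±`step_size` perturbation of the current
  solution, accepted by the Metropolis rule at `mc_temperature`; the
  best-ever point wins. Hop count, step (0.25 pH), temperature (1.0 in RMSD
  units) and restart count are free hyperparameters — the literature names
  only the algorithm family — and the defaults (100 hops, 10 restarts) are
  configurable; the test suite runs reduced counts because on synthetic
  data the cost surface within a ±2 box around a good seed is tame: a
  single bounded descent already recovers a hidden generating set to ~1e-4.
* **Nested cross-validation**: the outer 75/25 split is the curation
  step's; inside the 75 %, 10-fold CV optimizes on 9 folds and costs the
  held-out fold, and the ten solutions are averaged parameter-wise
  (`final = mean(per_fold)`). `cv_rmsd` (mean held-out cost) is the
  reported generalization estimate; multi-seed/restart selection uses it,
  never the training cost.

Gradients are numerical throughout: the bisection solver is not
differentiable analytically, and finite differences over a smooth
(fine-precision) cost are entirely adequate for nine parameters.

## The synthetic generator: what a green test establishes

`generate_fixture()` draws sequences with ionizable letters at a
controllable fraction of positions (default 0.25, roughly the natural
frequency of the seven residues), labels each with its *solver* pI under a
chosen generating set, adds Gaussian measurement noise (default σ = 0.25
pH, the scale of good peptide data), and plants three kinds of structure:

* **replicates** — a record carries two independent measurements;
* **duplicates** — a record appears twice as separate entries
  (`duplicate_fraction`; this field exists precisely so the merge step has
  something real to merge);
* **outliers** — labels displaced by 2–4 pH units *away from the
  consensus-panel prediction*. Displacing relative to the record's own
  label would not guarantee detection, because the curation rule compares
  against the panel mean, not the generating set; anchoring the shift to
  the panel makes the planted set exactly recoverable, which is what the
  curation acceptance test demands. If clamping to (0, 14) would pull the
  error back under 2 units, the shift flips direction.

What the generator does *not* emulate: realistic proteome residue
frequencies, post-translational modifications, disulfide chemistry,
correlated measurement error between databases, or any relationship
between sequence and measurement noise. Consequently a green
parameter-recovery test establishes that the optimizer correctly inverts
the package's own forward model under stated noise — it does not establish
that an optimized set will beat published sets on real 2D-PAGE data, and
the published headline RMSDs (~0.87 pH proteins, ~0.25 peptides) are not
reproducible without the original experimental databases. The structural
finding that held-out error exceeds training error is verified on
synthetic data with deliberately small training sets, where the
overfitting gap is measurable above sampling noise.

## Numerical and degenerate-input choices

* Ties in the benchmark table keep the order the sets were supplied in
  (stable sort) — deterministic reports.
* `split_train_test` sizes the training set as `round(0.75·N)` and clamps
  to keep both halves non-empty.
* Measurement values must lie in (0, 14); generator draws are clamped to
  [0.05, 13.95].
* Empty sequences, measurement-free datasets, empty panels, too-few
  records and unknown set names all raise early, specific errors.
* RNG discipline: every stochastic routine (`split_train_test`, the
  generator, the optimizer) seeds a *local* RNG scope and restores the
  caller's state, so library calls never perturb a user's simulation
  stream; CLI outputs are byte-identical given the same `--seed`.

## Known limitations

* The nine-parameter model ignores PTMs, disulfides and electrostatic
  coupling — irreducible bias on real proteins, particularly eukaryotic.
* The clustering identity is end-anchored and ungapped; at thresholds far
  below 0.99 (where indels matter) a real aligner would be required.
* Custom pKa sets with inverted or extreme values can place the
  zero-charge point outside [0, 14] or make monotone assumptions vacuous;
  the solver detects and reports the no-root case rather than guessing.
* Basin-hopping hyperparameters are heuristics; for rugged real-data cost
  surfaces the configured defaults (more hops, more restarts) matter more
  than they do on synthetic fixtures.
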