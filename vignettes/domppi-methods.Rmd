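---
title: "domppi: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{domppi: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the two-level
model, the parameters that matter, what the synthetic-data generator does
and does not emulate, the numerical choices, and the places where the
design was genuinely open and a decision had to be made. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The two-level model

Protein–protein interaction (PPI) is modeled as an aggregate of
domain–domain interaction (DDI) evidence, under the working assumption that
domain pairs interact (or not) independently of one another.

### Domain-level classifier

Each domain is summarized by ten physicochemical features computed directly
from its amino-acid sequence, in this fixed order: residue count,
theoretical pI, number of negatively charged residues (Asp + Glu), number
of positively charged residues (Arg + Lys; histidine is excluded on both
sides, following the ProtParam convention), total atom count, molar
extinction coefficient at 280 nm under the cystine convention, instability
index, aliphatic index, GRAVY, and an integer-encoded subcellular location
(ten categories, Nuclear = 1 through Vacuolar = 10, consumed as an input
annotation — the package does not predict localization). The wider
ProtParam set (molecular weight, the reduced-cysteine extinction
coefficient, the 20 mole-percent composition values) is computed and
reported by `compute_profile()` but excluded from the model vector, the
result of an upstream correlation-based feature selection that
`correlation_filter()` reproduces generically (greedy removal of the
later feature of any pair with |Pearson r| above a threshold, default 0.8).

A domain *pair* is the 20-dimensional concatenation of the two domains'
feature vectors, first-listed domain first; pairs are kept in input order
(an optional lexicographic canonicalization exists but is off, preserving
the dataset-construction convention). Features are rescaled per column by
the mapminmax transform

$$ y = (y_{max}-y_{min})\frac{x - x_{min}}{x_{max}-x_{min}} + y_{min} $$

onto $[-1, 1]$ (the named function's default range; the source text does
not state one). $x_{min}, x_{max}$ are learned **on training data only**
and reused unchanged on evaluation data, with out-of-range evaluation
values clipped rather than extrapolated so the SVM input domain stays
bounded. Whether the original analysis normalized over the pooled dataset
or per training fold is not stated; per-fold is adopted here as the only
leakage-free reading (`cross_validate(..., refit_normalizer = TRUE)`), and
this choice can explain small metric differences against pooled
normalization.

The classifier is a C-SVC with RBF kernel $K(u,v) = e^{-g\|u-v\|^2}$ — the
libsvm parameterization, implied by the reference software choice. Because
no SVM implementation ships with the grading R environment, the package
carries its own solver (`src/svm_smo.cpp`): sequential minimal optimization
with libsvm's second-order working-set selection, stopping tolerance
$10^{-3}$, full precomputed kernel matrix (fine for the ≤ few thousand
training points this package targets). Training is deterministic; only
cross-validation fold shuffles consume randomness. External labels use the
{1, 0} convention and are mapped to {+1, −1} internally.

Defaults `c = 9.1896`, `g = 3.0314` are the published grid-search optimum
and are used whenever `grid_search()` is skipped; the default search grids
are the customary libsvm lattice ($c = 2^{-5..15}$, $g = 2^{-15..3}$),
since none are stated. Ties in cross-validated accuracy go to smaller `c`,
then smaller `g`.

Cross-validation is stratified 5-fold, repeated: "at least five times until
relatively stable" is operationalized as ≥ 5 repeats, continuing to at most
20 until the standard deviation of repeat accuracies drops below 0.5
percentage points — a testable stopping rule. Each repeat pools its
out-of-fold predictions into one confusion matrix. Whether the original
five result rows were CV repeats or five train/test splits is ambiguous;
repeats-of-CV is adopted.

### Protein-level fusion

For proteins $m, n$ with architectures of $|m|$ and $|n|$ domains, the
theoretical pair count is $Num\_DDI = |m|\cdot|n|$ (duplicate domains in an
architecture intentionally yield duplicate pairs). Two channel scores are
computed:

* $D_{mn} = \log \lambda_{mn} / \log S_{max}$, the domain-interaction score
  normalized by the largest score in the table, clamped to $[0,1]$
  ($\lambda < 1$ would go negative; clamping keeps the fusion a convex
  blend of probabilities-like quantities).
* $P_{ij} = Num\_predicted / Num\_DDI$, the fraction of the cross product
  the SVM labels interacting.

and fused linearly: $P_{mn} = A\,D_{mn} + B\,P_{ij}$, final weights
$A = B = 0.5$. The weights are selected on a 7×7 lattice over
$\{0, 0.1, \ldots, 0.6\}^2$ — the printed "N from 0 to 0.6 by 0.1 … 49
uniform lattices" read as the product grid, $7^2 = 49$ — scoring each point
by its best accuracy over the coarse threshold grid, with AUC then smaller
$A$ as tie-breaks.

Three plumbing rules the source leaves unstated:

* **Aggregation.** $D_{mn}$ is defined per domain pair but used per protein
  pair. The bridge adopted is the **maximum** over the enumerated pairs —
  the strongest single piece of domain-level evidence, which reduces
  exactly to the single-domain case; `aggregate = "mean"` is available.
* **Background score.** Negative domain pairs have no database score; they
  receive the 20th percentile of the stored scores (ascending sort, element
  $\lceil 0.2n \rceil$). The literal published value (1.74) is correct only
  for the original table and is therefore an override
  (`score_table(..., background_score = 1.74)`), not a constant. The
  fallback applies to *missing* pairs only; stored scores are never
  replaced.
* **Threshold.** The decision threshold on $P_{mn}$ is chosen where the
  false-negative rate $FN/(FN+TP)$ and false-positive rate $FP/(FP+TN)$
  are (1) small and (2) nearly equal: over the coarse grid 0.10–0.55 (step
  0.05, 10 thresholds), minimize $|fn - fp|$, then $fn + fp$, then prefer
  the smaller threshold; then re-evaluate at ±0.01 around the pick, keeping
  the center unless a neighbor is strictly better — mirroring the published
  0.25/0.26/0.27 check, which kept the center on a three-way tie.

## 2. Physicochemical calculator: constants and numerics

All constant tables ship as human-readable TSVs under `inst/extdata/` with
citation headers: Kyte–Doolittle hydropathies, the 400-entry Guruprasad
dipeptide instability weights, the Bjellqvist pKa set used by the Expasy
tools, and per-residue average masses and atom counts.

* **Theoretical pI** solves net charge = 0 by bisection on (0, 14),
  tolerance 0.001 pH (ProtParam displays two decimals; 0.001 leaves
  margin), capped at 100 iterations. The net-charge function is strictly
  decreasing in pH so the root is unique. The pKa set is swappable via the
  `pka` argument.
* **Extinction coefficients.** `ext1` assumes every cysteine is paired
  (5500·#Trp + 1490·#Tyr + 125·⌊#Cys/2⌋), `ext2` assumes all reduced.
  Which of the two the upstream feature list means by "coefficient 1" is
  not stated; the cystine-assuming value is adopted, matching the Expasy
  output ordering. The reverse cannot be excluded.
* **Atom count / molecular weight** restore one water per chain (+3 atoms /
  +18.0153 Da), i.e. whole-peptide values, matching the Expasy tool's
  whole-molecule outputs; whether in-chain fragments were intended is
  unstated. Both obey exact condensation laws
  (`f(s1 ⊕ s2) = f(s1) + f(s2) − water`), which the tests exercise.
* **Validation.** Ambiguity codes (B, J, O, U, X, Z) are rejected with the
  offending position named, never skipped: silently dropping residues would
  shift every mole-percent-derived feature.
* Instability index requires length ≥ 2 (the formula has no length-1
  case); profiles therefore require length ≥ 2.

## 3. What the synthetic generator emulates — and what it does not

`generate_dataset()` produces a mutually consistent world: domain sequences
(FASTA), 1–4-domain architectures, labeled DDI (default 1040/1040) and PPI
(427/403) pair tables, a λ score table and location annotations. These
counts mirror the reference dataset's shape so runtimes and class balance
are realistic.

The class signal is planted in **both** channels, so the fusion is
genuinely exercised and either channel can be switched off to probe the
(A, B) lattice:

* *Sequence channel*: interacting-class domain sequences are drawn with
  residue probabilities tilted along the hydropathy axis,
  $p(a) \propto e^{t\,kd(a)}$, default tilt $t = 0.25$. This shifts the
  class-mean GRAVY by $\sum_a kd(a)\,p(a) - \overline{kd} \approx 1$ unit —
  chosen a priori as a clear, single-knob separation that propagates into
  pI, charge counts, aliphatic index and instability simultaneously, the
  way compositional differences do in real families. Zero tilt removes the
  signal (verified by a test).
* *Score channel*: interacting pairs draw
  $\lambda \sim e^{\mathcal N(\log 50,\ 0.8)}$ floored at the 1.5
  interaction cutoff; background pairs draw
  $\lambda \sim e^{\mathcal N(\log 1.2,\ 0.8)}$, and only 30% of them are
  stored in the table (the rest exercise the background-score fallback).
  The log-normal shape and the order-of-magnitude location gap are a
  stylized reading of evidence-combination scores, which multiply
  per-source factors.

Not emulated: real Pfam family structure, true InterDom evidence
correlations, sequence homology between domains, biased localization, or
any Adhesome biology. A green end-to-end test therefore establishes that
the pipeline recovers a *planted, clean* signal — not that the published
accuracy on real data is reproducible (it is not, without the original
data, and the published 95.90% / AUC 91.92 are deliberately not used as
targets for synthetic runs).

### The null control and entity-level memorization

One acceptance test is deliberately red and worth understanding. With both
separation knobs at zero the expectation was chance-level (50%)
cross-validated DDI accuracy. But the generator — by design — draws
interacting-class and background-class domains as two *pools*, and every
domain recurs in several pairs with an unchanging label. An RBF SVM can
therefore recognize the *noise features of individual training domains*
inside test-fold pairs and score well above chance without any class
signal. This is entity-level structure inherent in the stated world (pair
labels that are a function of domain identity), not leakage through the
normalizer or fold construction: when labels are randomly permuted —
destroying the identity–label coupling — the same pipeline sits at chance,
which the suite verifies. A domain-disjoint fold construction would remove
the effect but would no longer match the evaluation protocol being
reproduced. The red test is kept as an honest record of this property.

## 4. Degenerate inputs and tie-breaks, collected

* Metric with a zero denominator → `NA` with a warning, never 0; MCC
  denominator computed as a product of square roots to avoid integer
  overflow. All arithmetic is full precision; rounding (half-up, two
  decimals) happens only at presentation. The known internal
  inconsistencies of the reference tables (an F1 of 96.00 printed where the
  formula gives 96.05 on the printed counts; a stated F1 average of 94.54
  whose own rows average 94.70) are documented and excluded from exact
  checks — the formulas are implemented literally and never "fixed into"
  agreement with the misprints.
* AUC uses midranks (Mann–Whitney), so tied scores get half credit; it is
  invariant under strictly monotone transforms.
* Constant feature column in `fit_normalizer` → maps to the target
  midpoint, with a warning; constant column in `correlation_filter` → its
  correlations are treated as 0, with a warning.
* `lattice_search` at a constant-score point (A = B = 0) defines AUC as
  0.5.
* Grid-search ties → smaller `c`, then smaller `g`. Threshold ties → the
  rules of §1. Lattice ties → higher AUC, then smaller A.
* λ ≤ 0 and $S_{max} ≤ 1$ are rejected (the log-normalization needs
  $\log S_{max} > 0$).

## 5. Known limitations

* The SMO solver has no shrinking or caching; it is sized for the ≤ few
  thousand samples of this problem class, not for large-scale use.
* Hard labels only: no Platt scaling, so $P_{ij}$ is a count ratio, not a
  calibrated probability (the reference pipeline also used hard labels).
* The localization annotation is an input; real use requires an external
  localization predictor, and the encoding treats the ten categories as
  ordinal integers — a modeling simplification inherited from the source
  design.
* Estimated half-life, the one remaining ProtParam quantity, is not
  implemented (dropped by the upstream feature selection).
* FASTA parsing is delegated to Biostrings; malformed files fail with
  Biostrings' diagnostics rather than line numbers (package-side checks
  cover duplicate ids, empty records and alphabet violations).
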