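---
title: "Topological QSAR models of PFAS binding to nuclear hormone receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological QSAR models of PFAS binding to nuclear hormone receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasscreen)
```

## The problem

Per- and polyfluoroalkyl substances (PFAS) are suspected endocrine
disruptors: docking studies place many of them in the ligand-binding
domains of the peroxisome proliferator-activated receptors (PPAR
α/β/γ) and the thyroid hormone receptors (TR α/β). Docking every
candidate structure is expensive, but for homologous PFAS families the
docking score turns out to be almost linear in a couple of cheap 2D
topological descriptors. That observation supports a two-step screening
strategy, which this package implements end to end:

1. **Calibrate** a small multiple-linear-regression (MLR) model of the
   docking score (binding score, BS, kcal/mol; more negative = stronger
   predicted binding) on a few dozen docked compounds, using
   standard-scaled topological descriptors.
2. **Screen** arbitrarily many structures by computing their
   descriptors, evaluating the frozen equation, classifying the
   predicted score into four binding-probability classes, and flagging
   compounds outside the model's applicability domain.

## Descriptors

All descriptors are computed on the hydrogen-suppressed molecular graph
(vertices = heavy atoms, edges = bonds, bond order ignored); implicit
hydrogen counts are kept per atom for the constitutional descriptor.

* **X%** — percentage of halogen atoms over *all* atoms, hydrogens
  included: `100 · n_X / (A + n_H)`. The denominator choice matters:
  only with implicit hydrogens counted does the 8:2 fluorotelomer
  unsaturated acid (C10H2F16O2) give X% = 53.33, the reference value
  used in the acceptance checks.
* **ICR** — radial centric information index: Shannon entropy (bits) of
  the partition of heavy atoms into classes of equal eccentricity,
  `−Σ (n_g/A) log2(n_g/A)`. It grows with chain length and with the
  number of distinct radial shells, and is bounded by `log2(A)`.
  Descriptor engines differ on whether the centric partition uses
  eccentricities or distance-from-center; no printed value
  discriminates between them, so the eccentricity convention (the
  standard information-index definition) was chosen.
* **PW2** — path/walk-2 Randić shape index. Two conventions exist: the
  atom-averaged ratio `(1/A) Σ p2(i)/w2(i)` and the molecule-level
  quotient `Σp2 / Σw2`. Common descriptor software uses the former, a
  plain reading of "quotient of path count and walk count" suggests the
  latter. Both are implemented (`pw2(g, method=)`); the atom-averaged
  form is the default. Atoms with no 2-walks contribute zero.
* **TPC** — total path count: `ln(A + P)` with `P` the number of simple
  paths of length ≥ 1 between unordered heavy-atom pairs, i.e. paths of
  length ≥ 0 with each atom counted as a zero-length path. This
  convention reproduces the printed reference value 6.39 for the
  34-heavy-atom 10:2 fluorotelomer alcohol; the alternative
  `ln(1 + A + P)` differs by < 0.01 there and was rejected for that
  reason. For trees `P = A(A−1)/2` exactly (used as a fast path); cyclic
  graphs fall back to exhaustive depth-first enumeration.

SMILES parsing is delegated to OpenBabel (via ChemmineR/ChemmineOB);
implicit hydrogens are reconstructed from standard SMILES valence rules
(C 4; N 3; O 2; halogens 1; S 2/4/6; P 3/5, smallest valence not below
the bond-order sum, adjusted by formal charge), which handles sulfonic
and phosphonic head groups correctly. Stereochemistry is ignored — all
four descriptors are 2D. Multi-fragment input is rejected; structures
are assumed pre-curated single fragments (no salt stripping or
neutralization is attempted).

## Model calibration

* **1:Z split.** Compounds are sorted by endpoint ascending (stable
  sort; ties keep input order — the convention is arbitrary but
  reproducible) and every Z-th compound is held out: n = 43 gives
  29/14 at Z = 3 and 33/10 at Z = 4, the two designs used by the five
  receptor models.
* **Scaling.** Descriptors are standard-scaled with training-set means
  and sample SDs (n−1 denominator, the dominant convention in QSAR
  software; a single flag in `standard_scale()` would flip it).
  Validation and screening data always reuse the training parameters.
* **MLR.** Ordinary least squares with intercept, standard errors on
  n − p − 1 degrees of freedom. Because the predictors are standardized,
  the intercept equals the training endpoint mean and coefficients are
  directly comparable effect sizes (kcal/mol per SD).
* **Descriptor selection.** A genetic algorithm over fixed-size subsets
  (size 2, matching all published models) maximizes leave-one-out Q²
  under a hard feasibility constraint: any candidate pair with pairwise
  |r| > 0.6 is discarded outright rather than penalized. GA
  hyperparameters are conventional defaults — population 50, 100
  generations, tournament selection of size 3, union-resampling
  crossover, per-gene mutation 0.01, elitism 1 — and a seed is
  mandatory. On every pool size used in the tests the GA result is
  verified against exhaustive enumeration, which is also exported
  (`exhaustive_select()`).

## Validation statistics

The full report mirrors the conventional QSAR table: R², RMSE and MAE of
calibration (n-denominator RMSE — the common QSAR definition, not the
n−p−1 regression estimate); leave-one-out Q² with RMSE/MAE of
cross-validation; external Q²F1/Q²F2/Q²F3, RMSE/MAE of prediction, and
Lin's concordance correlation coefficient (sample-moment form); and the
Y-scrambling mean R². Two implementation notes:

* The LOO loop refits the scaler inside each fold to avoid leakage. For
  OLS this is algebraically identical to the PRESS/hat-matrix shortcut
  (scaling is an affine map, so predictions are unchanged); the shortcut
  is used inside the GA fitness for speed and the equivalence is
  asserted by a test.
* Y-scrambling reports the *mean* R² over seeded permutations of the
  endpoint. For a p-descriptor model the chance-correlation expectation
  is `p/(n−1)` — 0.071 at n = 29 and 0.0625 at n = 33 — which is the
  magnitude the published models report and what the synthetic pipeline
  reproduces. The identity permutation is not excluded; its weight
  vanishes with the number of iterations.

## Applicability domain

Leverage of a (scaled, intercept-augmented) descriptor row is
`h = x'(X'X)⁻¹x`; training leverages sum to p + 1. The warning threshold
is `h* = 3(p+1)/n` — 0.310 for the n = 29 models and 0.273 for n = 33.
In-domain requires strictly `h < h*`; boundary equality counts as out.
Labeled compounds are additionally screened by standardized residuals
(residual / RMSE of the set the compound belongs to: calibration RMSE
for training, external RMSE for validation) with |z| > 3 flagging an
outlier — the Williams-plot rules. Unlabeled screening compounds use
the Insubria-graph rule instead: in-domain iff `h < h*` *and* the
predicted score falls inside the training endpoint range. The range
check uses the *observed* training endpoints by default; the wording in
the source material is ambiguous between observed and predicted ranges,
so `assess_domain(range_basis = "predicted")` exposes the alternative.
Reason codes are assigned with precedence high-leverage >
residual-outlier > out-of-range.

A characteristic behavior worth knowing: the shortest member of a
homologous family (e.g. trifluoroacetic acid among the carboxylic
acids) typically exceeds h* against a longer-chain training set — it is
structurally extreme even though its prediction may be accurate. The
analysis scripts reproduce this.

## Screening with the frozen equations

The registry (`inst/extdata/receptor_registry.json`, loaded by
`frozen_registry()`) stores the five published equations digit for
digit: intercepts, standardized coefficients, their standard errors,
PDB codes, and the threshold triples T1 < T2 < T3. Classification is

* `high` for BS < T1,
* `moderately_high` for T1 ≤ BS < T2,
* `moderate` for T2 ≤ BS < T3,
* `low` for BS ≥ T3.

A score exactly at a threshold goes to the *weaker* class. That
boundary rule is pinned by a printed assignment (a screening compound
at exactly the T1 threshold of TRβ reported in the moderately-high
class); one conflicting printed range elsewhere is consistent with
2-decimal rounding and was not allowed to override it.

The published equations act on standardized descriptors, but the
original training means and SDs were never published. `screen()` and
`frozen_model()` therefore require an explicit **reference dataset** to
realize the equations on raw descriptors — a re-derived training table
or the synthetic benchmark. Screening descriptors are always scaled by
the reference statistics (not rescaled per screening set), and the
reference set doubles as the AD geometry. Class counts from the
bundled synthetic reference are therefore illustrative, not a
reproduction of the published screening counts, which depended on an
external compound database and a commercial descriptor engine.

## The synthetic generator

`homologous_series()` builds the five structural families by template
concatenation of CF2 units: carboxylic acids `COOH-(CF2)n-CF3`
(n = 0 is trifluoroacetic acid), sulfonic acids `SO3H-(CF2)n-CF3`,
phosphonic acids `PO3H2-(CF2)n-CF3`, fluorotelomer alcohols
`OH-(CH2)m-(CF2)n-CF3`, and dicarboxylic acids `COOH-(CF2)n-COOH`.
`decoy_structures()` adds randomized branched, cyclic, ether-linked,
and lightly fluorinated structures that exercise the out-of-domain
code paths. `make_benchmark()` assembles the default 43-compound
calibration set (10 + 8 + 8 + 9 + 8 across the five groups, including
trifluoroacetic acid) and simulates the endpoint as

`BS = β0 + Σ βj zj + ε,  ε ~ N(0, σ²)`

with the descriptors standard-scaled within the set. The defaults copy
the published PPARα equation — β0 = −7.499, β = (−0.947 on ICR, −0.394
on PW2) — with σ = 0.35 kcal/mol, the midpoint of the published
calibration-RMSE range (0.276–0.384). With these settings the fitted
validation statistics land near the published magnitudes and the
recovered coefficients carry standard errors ≈ 0.06–0.07, matching the
printed ones.

What the generator does **not** emulate: real docking scores for named
compounds (no docking is performed), the structural diversity of a
real screening database (organometallics, aromatics, multi-functional
structures), and any residual heteroscedasticity — noise is
homoscedastic Gaussian because no residual diagnostics were available
to justify anything richer. Passing tests therefore demonstrate the
statistical machinery, not the accuracy of any specific receptor
prediction on real compounds.

## Numerical choices and problem sizes

* Descriptors are computed and consumed at full precision; printed
  reports round to 2 decimals (descriptors) or 3 decimals
  (statistics).
* Model and report JSON documents serialize numbers at 17 significant
  digits, so write/read round-trips are bit-exact.
* All stochastic stages (GA, Y-scrambling, decoys, score simulation)
  require an explicit seed and restore the caller's RNG state.
* Test and analysis problem sizes: benchmark n = 43 (29/14 split),
  1000 Y-scrambling permutations, 100-molecule random panels for the
  descriptor property suites, 100-seed envelopes for coefficient
  recovery. These sizes keep the whole suite under a minute while
  leaving the statistical assertions comfortably powered.

## Known limitations

* Only connectivity enters the descriptors: no aromaticity perception,
  tautomers, 3D geometry, or stereochemistry — adequate for the four
  target descriptors, wrong for any descriptor that needs them.
* Simple-path enumeration is exponential in pathological dense graphs;
  molecular graphs (tree-like, few small rings) are far from that
  regime, and trees bypass enumeration entirely.
* The GA is exact only in the sense that it matches exhaustive search
  on the pool sizes tested (≤ 12); on much larger pools it is a
  heuristic, as any GA is.
* `classify_score()` trusts the frozen thresholds; the threshold
  boundary convention of the original screening tool is only pinned at
  2-decimal precision.
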