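---
title: "Field-based 3D-QSAR: models, parameters, and design choices"
author: "fieldqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-based 3D-QSAR: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and assumptions

`fieldqsar` models the activity of a series of *rigid, mutually aligned*
small molecules as a linear function (through latent PLS factors) of
molecular interaction fields sampled on a rectilinear lattice. Three
assumptions are load-bearing:

1. **Alignment is given.** Coordinates are taken exactly as supplied and
   never re-oriented; conformer generation and shape alignment are out of
   scope. A grid-anchored model is not translation-portable: predicting a
   molecule whose centroid lies far outside the training region triggers
   a warning rather than a silent, meaningless number.
2. **One conformer per molecule.** Fields are computed from a single
   rigid geometry; no ensemble averaging.
3. **Per-atom parameters suffice.** Every atom needs a van der Waals
   radius, a Lennard-Jones well depth, a hydrophobicity constant, a
   partial charge and donor/acceptor flags before any field is computed
   (`assignParameters()`); field formulas never inspect connectivity at
   evaluation time.

# Fields

Two families, seven field types in total.

**Force fields** (kcal/mol, per grid point q):

- steric: $\sum_i \epsilon_i\,[(R_i/r_{iq})^{12} - 2(R_i/r_{iq})^6]$ with
  $R_i$ = atom radius + probe radius and
  $\epsilon_i = \sqrt{\epsilon_{atom}\,\epsilon_{probe}}$
  (Lorentz–Berthelot). At the pair-minimum distance the value is exactly
  $-\epsilon_i$, which the tests pin down.
- electrostatic: $\sum_i 332.06\, z_{probe}\, q_i /(\epsilon(r)\,r_{iq})$
  with the distance-dependent dielectric $\epsilon(r) = r$, i.e. a
  $1/r^2$ law. The Coulomb constant 332.06 kcal·Å/(mol·e²) and the
  dielectric model are stated package choices; the probe is the
  conventional sp3 carbon with charge +1 (radius 1.70 Å, well depth
  0.10 kcal/mol, `defaultProbe()`).

Both are clamped symmetrically to ±30 kcal/mol. Whether a truncation
threshold should clamp both signs or only the repulsive steric wall is
genuinely open in the field; we clamp symmetrically, and the choice is
isolated in one argument (`clamp`). At points where the steric energy
saturates the clamp the probe is inside the molecule and the
electrostatic value is physically meaningless; following classic grid-
QSAR practice it is replaced by the column mean over the non-saturated
training molecules (`es_at_clash = "mean"`), with `"clamp"` available as
the alternative. The fill means are stored in the model and re-applied
when predicting new molecules.

**Gaussian similarity fields** (dimensionless):
$\sum_i w_i e^{-\alpha r_{iq}^2}$, no cutoff, no clamping,
$\alpha = 0.3$ Å⁻² by default. Weights: radius³ (steric), signed partial
charge (electrostatic), a coarse Crippen-style per-element constant
(hydrophobic; shipped in `inst/extdata/atom_params.csv` together with
Bondi radii and well depths), and 0/1 indicators for acceptors and
donors. The donor/acceptor encoding is rule-based: a donor is a hydrogen
bonded to N or O; an acceptor is an N or O that is neither positively
charged (for N: total bond order ≥ 4) nor amide-like (N single-bonded to
a carbon double-bonded to O or S). No pseudo-atom extension points are
used.

# Grid

The lattice encloses the union bounding box of the *training* molecules,
expanded 3 Å on every side, sampled at 1 Å; per axis
$n = \lfloor(\text{extent} + 2\,\text{margin})/\text{spacing}\rfloor + 1$.
Points within 2 Å of any training atom are eliminated, and per field
block every column with across-molecule standard deviation below 0.05 is
dropped. Two documented numerical choices here: the SD is the
*population* SD (divide by n), and the variance filter runs after the
electrostatic fill so the filter sees the values the model will see.
Test and prediction molecules are evaluated analytically at the retained
points of the training grid; atoms outside the lattice are allowed.

# PLS modelling

NIPALS PLS1 with column centering and per-block variance equalization:
each block is scaled so its total column variance is 1, which makes
kcal/mol blocks and dimensionless similarity blocks commensurable and
makes the contribution fractions meaningful. The maximum number of
factors defaults to 5. Coefficients are back-transformed to original
field units, so prediction is a plain dot product plus intercept.

- **Q²(LOO)**: each fold refits everything that depends on the training
  rows — centering and block scaling included — and
  $Q^2 = 1 - \mathrm{PRESS}/\sum(y-\bar y)^2$. A degenerate fold predicts
  the fold-training mean. The implementation is pinned against an
  independently coded naive loop (deflation-based prediction, no closed-
  form regression vector) to 1e-10.
- **y-scrambling**: mean training R² over 50 seeded permutations of the
  activities; a capacity / chance-correlation control.
- **Stability**: the commercial statistic this mirrors has no published
  definition, so the package defines it as the mean Pearson correlation
  between full-model and subsample-model predictions over the full
  training set (20 seeded subsamples of 90%). Values are therefore *not*
  numerically comparable to tables produced with the proprietary
  definition; the qualitative reading (1 = composition-independent) is.
- **Contribution fractions**: per field,
  $\sum_j |c_j|\sigma_j$ normalized over fields — the standard
  SD-weighted measure; non-negative, sums to 1.
- **Combination scan**: all $2^k - 1$ non-empty subsets of the supplied
  field types, each row carrying SD, R²_training, scrambled R², both
  external R² flavors, stability, Q² and contributions. Published tables
  rarely say whether the external R² is the squared Pearson correlation
  or the predictive $1 - \mathrm{PRESS}/\mathrm{SS}$; the scan reports
  both (`r2_test`, `r2_test_pred`) and ranks by `r2_test` (descending),
  then R²_training, then fewer fields — a stated tie-break, since "best
  training and best test" can disagree.

# External validation

`externalReport()` computes squared Pearson and predictive R² (against
the training mean) plus RMSE. `golbraikhTropsha()` applies the canonical
acceptability bundle with its standard thresholds (Q² > 0.5, r² > 0.6,
through-origin slope in [0.85, 1.15] with $(r^2-r_0^2)/r^2 < 0.1$ in at
least one direction, $|r_0^2 - r_0'^2| < 0.3$). The thresholds are fixed
constants of the test, not tunables.

# Contour maps

Per retained point, the contour statistic is $c_j\sigma_j$ — the
SD-weighted coefficient, which avoids overweighting low-variance points
that a raw-coefficient map would inflate. Favored regions are points at
or above the 90th percentile of the scores, disfavored at or below the
10th; ties at a shared threshold go to the favored set so the sets stay
disjoint (and a 50/50 split partitions all points). Constant scores
yield empty sets with a warning. Sets carry the conventional display
colors (steric green/yellow, electrostatic blue/red, HBA red/magenta,
HBD purple/cyan) and a 26-neighborhood connected-component label so
distinct spatial regions can be referred to individually — the labels
are data-driven and make no claim of correspondence with any manually
annotated figure. `writeDx()`/`readDx()` handle OpenDX volumes
(z-fastest file order, round-trip tested).

# Drug-likeness screening

Descriptors come from Open Babel: molecular weight, Wildman–Crippen-type
logP, Ertl TPSA, molar refractivity and rotatable bonds; donor/acceptor
and atom counts are rule-based as above (Lipinski acceptors = N + O).
One logP estimator is used for *all* rules and named in the report
header — web tools mix estimators per filter, which is a known source of
discrepancies. Lipinski is reported both in its original usage
(tolerating one violation) and strictly; Ghose, Veber and Egan are
strict. All bounds are inclusive. A synthetic-accessibility score is
deliberately absent: it requires an external fragment-frequency corpus,
and a fabricated stand-in would be worse than no value.

# The synthetic series generator

`syntheticSpec()`/`generateSeries()` emulate the study conditions the
pipeline targets: a rigid shared scaffold (an amide + aliphatic linker +
basic amine motif, ten parameterized atoms, bit-identical across
molecules), two substituent sites drawing from a six-option palette
(H, methyl, hydroxyl, chloro, ether oxygen, amino) and Gaussian activity
noise of SD 0.2 pEC50 units at n = 40 — noise and size chosen to mimic a
well-behaved analogue series. The palette deliberately includes an
acceptor-only oxygen so the donor and acceptor indicator fields are not
collinear: without it, oppositely weighted HBA/HBD effects planted in
the same region are unidentifiable and coefficient-sign recovery is
meaningless.

Activity is *planted in field space*: each effect term is a weight times
the mean of one field type over a spherical grid region (defaults: a
steric effect at site 1, an acceptor and a donor effect at site 2),
measured relative to the bare scaffold so the intercept (5.5) is the
scaffold's own activity and values land in a realistic pEC50 window
(roughly 6.6–10 at the defaults). Planting in field space rather than
atom space means an error anywhere in grid construction, field
evaluation, filtering or PLS breaks recovery — which is the point.
`recoveryCheck()` runs the full pipeline and reports Q²(LOO), the
fraction of retained in-region coefficients whose sign matches the
planted weight, and hold-out RMSE on a fresh seeded series.

What the generator does **not** emulate: conformational flexibility,
alignment noise, charge-model error, activity cliffs, series with
multiple scaffolds, or assay heterogeneity. Passing the recovery checks
demonstrates the pipeline's internal correctness under its stated
assumptions, not predictive performance on real congeneric series.

# Numerical choices and degenerate inputs

- An atom exactly on a grid point is treated as clamp-saturated; no
  division error escapes.
- Squared distances are computed from coordinate differences, not the
  expanded inner-product form, so jointly translating molecules and grid
  leaves every field value bit-identical.
- Zero-variance y, empty active-point sets, and blocks that lose every
  column to the variance filter are hard errors naming the culprit; a
  failed model inside the combination scan becomes a flagged row rather
  than aborting the scan.
- All stochastic routines (scrambling, stability, the generator) take
  explicit seeds and restore the caller's RNG state.

# Problem sizes

The test suite builds everything it needs in code: series of 8–40
generated molecules on lattices of roughly 1 000–1 300 points
(a few hundred retained variables), oracle comparisons on sub-1000-point
grids, and a 43/19 train/test split in the acceptance script, mirroring
a 62-compound study design. The full suite runs in well under a minute
on one CPU; the acceptance script in seconds.

# Known limitations

- Gasteiger fallback charges are a different charge model than the
  quantum-derived schemes used by commercial pipelines; absolute
  electrostatic field values are not comparable across charge models.
- The stability statistic is package-defined (see above).
- The hydrophobicity atom constants are per-element defaults, not a
  fitted Crippen parameterization; they are adequate for modelling and
  testing, not for reproducing published hydrophobic-field maps.
- No applicability-domain machinery beyond the far-centroid warning.
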