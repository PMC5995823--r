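---
title: "Words and grammar of the peptide backbone: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Words and grammar of the peptide backbone: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepgrammar)
```

`pepgrammar` treats the backbone of a peptide as a sentence: each residue
contributes one φ-ψ dihedral pair (a *word*, or unit), and only certain
sequences of words occur in low-energy conformations (the *grammar*). This
vignette explains the statistical models behind both metaphors, the
numerical conventions the package commits to, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
more than one reasonable choice existed.

## Units, indexing and angle conventions

Unit *i* of an *n*-residue peptide X₁X₂…Xₙ carries the (φ, ψ) pair of
residue *i* + 1, so a peptide has *n* − 1 units, written as the lower-case
sequence plus a 1-based index (`"gfgg2"`). Residue 1 contributes no unit:
it has no φ (no preceding carbonyl carbon), and its ψ is fixed at 180° when
structures are rebuilt. All angles live in degrees in the half-open
interval (−180, 180], with −180 mapped to +180 so every angle has one
canonical representative.

A *low-energy* conformer is one within 10 kcal/mol of its ensemble's
global minimum; energies are consumed as relative kcal/mol and re-based so
the minimum sits at zero. No unit conversions from electronic-structure
outputs are performed — quantum-chemistry stages sit entirely outside this
package, which produces *trial* structures for them and analyses their
results.

## Backbone geometry

`build_backbone()` realizes a unit string as Cartesian coordinates by
sequential natural-extension-reference-frame (NeRF) placement with fixed
ideal internal coordinates: bond lengths N–Cα 1.458 Å, Cα–C 1.525 Å,
C–N 1.329 Å, C=O 1.231 Å; bond angles N–Cα–C 111.2°, Cα–C–N 116.2°,
C–N–Cα 121.7°; planar trans peptide bonds (ω = 180° exactly). Cβ is placed
at ideal tetrahedral geometry for non-glycine residues; termini are built
neutral, with no hydrogens. These are deliberate simplifications: trial
structures are starting points for external optimization, not final
structures, so idealized geometry costs nothing while keeping the builder
exactly invertible — `extract_units(build_backbone(u))` reproduces `u` to
10⁻⁶ °, a property the test suite exercises on random unit strings.

Two conventions deserve a note because the field leaves them open:

* **C-terminal ψ.** The last residue has no following nitrogen, yet its
  unit is well-defined in the learning set (the third class of units below
  consists of exactly such C-terminal units). The package closes the
  C-terminal ψ on the carboxyl oxygen written as OXT (falling back to O if
  no OXT is present when reading foreign files); the carbonyl O is placed
  trans to it. Dihedral signs follow the IUPAC convention, cross-checked
  in the tests against an independent extractor (`bio3d::torsion.pdb`).
* **Terminal chemistry.** Neutral NH₂/COOH termini are emitted, not
  zwitterions; the choice only affects rebuilt Cartesian output, never the
  dihedral analysis.

## Words: pairwise error rates, MDS, classes

`pairwise_error_rate()` trains a random forest (500 trees by default) to
separate two units' (φ, ψ) samples, after down-sampling the larger sample
to the smaller so that chance level is exactly 0.5, and reports the
out-of-bag misclassification rate. OOB estimation is used rather than a
held-out split because unit samples are small (tens to a few hundred
low-energy conformers) and every observation should inform both training
and error estimation. Features are (sin φ, cos φ, sin ψ, cos ψ), which
respects the periodicity of the torus; raw wrapped degrees are available
behind the `encode` flag of `rf_control()`.

A high error rate means two units are statistically interchangeable. The
full matrix over the learning set (packaged as
`inst/extdata/table1_error_rates.csv`, 19 units of the peptides GTG, GVG,
VGG, FGG, MGG, GVGG, GTGG, GFGG, values printed to one decimal, diagonal
undefined) is embedded by classical (Torgerson) scaling: map error rate
*e* to a dissimilarity, double-center −d²/2, eigendecompose, report
eigenvalues normalized by the largest.

**The transform question.** The error-to-dissimilarity map is a genuine
free choice, and the package makes it a pluggable parameter of
`mds_embed()` with two named options:

* `one_minus` (default): d = 1 − e, the simplest monotone decreasing map.
  On the packaged matrix it yields normalized eigenvalues

```{r}
emb <- mds_embed(load_table1())
round(emb$eig[1:5], 3)
```

* `proximity`: d = √(1 − 2e), the random-forest proximity convention, in
  which chance-level error (e = 0.5) means *identical* distributions and
  hence zero distance. On the packaged matrix:

```{r}
round(mds_embed(load_table1(), transform = "proximity")$eig[1:5], 3)
```

The published spectrum for this matrix is 1, 0.54, 0.26, 0.22, 0.16. The
default transform reproduces the dominant structure (two leading
eigenvalues far above the rest, justifying the 2D map) and puts the second
eigenvalue within 0.03 of the published value, but stretches the tail; the
proximity transform reproduces all five published values within 0.05. The
original analysis does not state its transform; the proximity convention
is evidently the closer match, and the package documents rather than
hides the discrepancy of the default. A caveat either way: a few printed
error rates reach 0.7, above the 0.5 chance level of a balanced two-class
OOB estimate, so the estimator behind the published matrix cannot be the
balanced OOB rate this package computes; under the proximity transform
such entries are clamped to distance 0. For this reason the package
reproduces the published matrix's *spectrum and classes* but makes no
attempt to reproduce individual printed cells with its own estimator.

**Clustering and the number of classes.** `cluster_units()` applies
average-linkage agglomerative clustering to the 2D coordinates. When k is
not supplied it is chosen by mean silhouette width over k ∈ 2..6 — with a
parsimony rule: the smallest k whose mean silhouette lies within 0.02 of
the maximum is selected, not the argmax. The rule exists because
silhouette profiles on small point sets are frequently flat near the top;
on the packaged matrix the profile is 0.741 at k = 3 versus 0.750 at
k = 4, a difference far below what is interpretable, and the coarser
partition is the defensible choice. With it the three published classes
are recovered exactly:

```{r}
cluster_units(emb)
```

The classes have a clean structural reading: class 1 units sit between two
glycines (the central residue may vary — F, T, V), class 2 units have a
non-glycine N-side neighbour, class 3 units are C-terminal. Units of the
same class license fragment substitution (`substitute_fragment()`): an
ensemble whose units are all class-equivalent to a requested fragment's
can stand in for it, with residue identities replaced at rebuild time.

## Grammar: the adjacent-unit combination rule

`enumerate_pair_dataset()` builds the training corpus exactly as a
divide-and-conquer search would: within each ensemble, the distinct
observed values of unit *i* and unit *i* + 1 among low-energy conformers
are recombined in a full cross product, and a combination is labeled
favorable iff all four of its angles lie within 3° (circular, per angle)
of some observed low-energy conformer. The 3° rule is applied per angle
rather than as a joint norm — "noise of 3°" most naturally bounds each
dihedral — and the threshold is the `noise_deg` parameter for anyone who
disagrees. Every observed conformer matches itself, so real combinations
are always positive; combinatorial negatives typically dominate, and
`train_grammar()` weights classes inversely to frequency rather than
discarding data. The alternative — subsampling negatives before the split
— was considered and rejected because it throws away exactly the
hard-negative structure the screen must learn.

Three further choices matter:

* **In-sample error** is the training-set misclassification of the fitted
  forest (resubstitution), with the OOB rate reported alongside. The
  out-of-sample error is the plain misclassification rate on the held-out
  fraction (40% by default) of a stratified seeded split.
* **Features.** The grammar forest uses a `full` encoding: sin, cos *and*
  wrapped degrees for each of the four angles. Pure sin/cos encoding —
  natural as it seems — measurably hurts this classifier: a single tree
  split on sin θ admits the mirror angle 180° − θ, and with a few hundred
  training points the resulting leaves leak background combinations into
  the favorable class at the percent level. Adding the raw wrapped angle
  lets splits be axis-aligned in angle space while the sin/cos pair still
  handles the wrap. None of the basins used anywhere in the package
  straddle ±180°, so the discontinuity of the degree features is inert.
* **Stability.** `stability_check()` retrains at several training
  fractions (0.5, 0.6, 0.7 by default) and reports whether all errors stay
  under a stated threshold, the package's version of the observation that
  the learned rule does not depend on the data division.

`screen_trials()` applies the trained rule to the junction of spliced
trials. Only the single junction pair of a two-fragment splice is
screened; the general rule is stated once for the junction only, and
multi-way divisions are out of scope.

## Splicing arithmetic

For a target of *n* residues built from an N-side fragment of n₁ and a
C-side fragment of n₂ residues, the minimal lengths are
n₁ = int((n−1)/2) + 2 and n₂ = int(n/2) + 1. The N fragment supplies
target units 1..n₁−2 from its own units; C-fragment unit *k* maps to
target unit *k* + (n − n₂). At the shared junction residue the
C-fragment's value is authoritative — its first used unit *becomes* the
(n₁−1)-th unit of the target and the N-side value for that unit is
discarded. The screened junction is the pair (n₁−2, n₁−1). A property
test verifies that for every n ≤ 12 and every admissible (n₁, n₂) the two
fragments cover target units 1..n−1 as a gap-free, overlap-free
partition. Trials are ordered lexicographically by parent conformer ids
so all downstream output is deterministic; `dedupe_trials()` removes
near-duplicates with a greedy first-keeper pass (per-angle tolerance 3°
by default).

## Density of states and the cost model

Each conformer at relative energy E contributes a normalized Gaussian
φ(x) = (1/(α√π))·exp(−(x−E)²/α²) with α = 0.24 kcal/mol by default, so
curves integrate to the conformer count; the default grid spans 0–4
kcal/mol at 0.01 steps, padded by 5α on each side so the normalization
property holds on the grid. `compare_dos()` reduces the visual comparison
of two curves to ∫min/∫max by trapezoidal quadrature.

`builtin_table2()` packages the published trial-structure counts for the
systematic, path-matrix and random-forest-assisted methods at n = 3..10.
The systematic column grows geometrically: calibrating a ratio on the
n = 3, 4 entries reproduces every later entry to three significant
figures (the published later entries are themselves printed to three
figures, which is why the comparison stops there). The published
per-residue growth factors — about 4.7 for the path-matrix method and
about 1.2 for the RF-assisted method over n = 4..10 — are geometric means
of successive ratios, reported to two significant figures. The published
extrapolation behind the RF column for n ≥ 7 ("about 50 more low-energy
conformers per added residue") is stored as data, not re-derived: the map
from conformer counts to trial counts it assumes is not specified, so
implementing it as a formula would be invention. Note one internal
inconsistency in the published numbers, preserved as printed: the GGGG
trial count appears both as 4,069 (text) and 4,096 (table); the table
value is packaged.

## The synthetic-data generator

`sample_ensemble()` emulates the one property of low-energy conformer
ensembles this package's claims rest on: multimodal per-unit φ-ψ
distributions with restricted adjacent-unit combinations. Five basins at
textbook Ramachandran positions (αR (−63, −43), β (−120, 130),
PPII (−75, 150), αL (57, 47), γ (−85, 70)) carry per-unit weights;
adjacent units draw basin pairs only from an allowed set, sampled
sequentially with a backward feasibility pass so an inconsistent rule
fails loudly rather than dead-ending. Angular noise is Gaussian with
σ = 10°, truncated at ±3σ so planted ground truth stays unambiguous
(the closest default basins, β and PPII, are 49° apart, so their ±30°
supports can overlap marginally — which is why planted-truth bookkeeping
records the *sampled* basin path as an attribute rather than inferring it
from positions). Energies are a placeholder — first conformer at 0, the
rest uniform on (0, 10] — because no energetic claim is tested on
synthetic data.

`make_grammar_benchmark()` plants a learnable combination rule: positives
are drawn inside allowed basin pairs; negatives are drawn from
*disallowed* basin pairs and kept only at max-per-angle distance
≥ 3σ + margin from every allowed pair centre, so `margin` is the gap
between the favorable region's edge and the nearest unfavorable
combination. Negatives are basin-shaped rather than uniform on the torus
deliberately: the combinations a junction screen faces are cross products
of individually plausible unit values, so unfavorable examples
concentrate where real screening decisions happen. (Uniform background
negatives were tried and make the problem *harder* in an unrepresentative
way — 500 points cannot delimit a boundary in four angular dimensions,
and the resulting errors are background false accepts that no real
screen would encounter.) On this benchmark at margin 30° the grammar
forest stays below 2% error, in and out of sample, across seeds and split
fractions 0.5–0.7, reproducing the headline learnability claim on
generated data.

What passing these tests does **not** show: that real peptide ensembles
are basin mixtures with 10° isotropic noise (real basins are anisotropic
and skewed), that real favorable regions are separated from unfavorable
ones by any fixed margin, or anything about residues absent from the
learning set — charged side chains above all. The synthetic results
validate the machinery, not the chemistry.

## Problem sizes and determinism

The test suite and the acceptance script run on deliberately modest sizes
— ensembles of 25–200 conformers, 200–500-tree forests, benchmarks of
500 + 500 combinations — chosen as the smallest sizes at which the planted
structure is recovered with margin to spare; the word-recovery experiment,
for instance, achieves a perfect adjusted Rand index at 200 conformers per
unit. Every stochastic step (sampling, down-sampling, splits, forest
growth) takes an explicit integer seed, RNG state is restored after each
seeded operation, and reruns with equal configurations produce identical
outputs, including byte-identical CLI artifacts.

## Known limitations

* The package's pairwise error estimator cannot reproduce individual
  published matrix cells (see the estimator caveat above); the packaged
  matrix is data, not a regression target.
* Only two-fragment splices with a single screened junction are
  supported.
* The backbone builder emits idealized geometry; anyone needing relaxed
  structures must optimize the output externally, which is the intended
  workflow.
* cis peptide bonds, side-chain χ angles and hydrogen placement are out
  of scope.
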