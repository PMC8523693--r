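---
title: "Statistical models and design choices in glycodia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical models and design choices in glycodia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycodia)
```

## The problem

Peptide-centric DIA analysis queries a spectral library of glycopeptide
precursors against multiplexed fragment-ion chromatograms. An intact
glycopeptide identification can fail in two partly independent ways — the
peptide backbone assignment can be wrong, or the glycan can be wrong — so a
single target-decoy competition does not control either error honestly.
glycodia implements the statistical core of such a workflow: consensus
library construction from DDA identifications, three-class decoy
generation, a two-dimensional FDR built on a bivariate four-groups mixture
model, Bayesian inference over co-isolated glycoforms, semi-empirical
library extension, and hierarchical quantification. Chromatogram
extraction itself is out of scope: the package consumes peak-group and
transition feature tables (OpenSWATH-style) and produces scored tables.

## Glycan trees and Y ions

Glycans are rooted trees of monosaccharides in canonical parenthesis
notation (one-letter codes: H hexose, N HexNAc, F fucose, A NeuAc, G
NeuGc, X xylose). A Y ion retains the intact peptide plus a
root-containing connected subtree of the glycan; `enumerate_y_fragments()`
returns the set of such subtrees keyed by monosaccharide *composition*,
since Y ions of equal composition have equal m/z and are therefore
indistinguishable in a chromatogram. Two deliberate choices follow:

* **Similarity ranking (background glycoform selection)** uses the Jaccard
  coefficient of the fragment sets *excluding* Y0. The naked peptide is a
  fragment of every glycoform and carries no discriminating power.
* **Isomer merging**: structures of one composition with identical
  fragment sets are combined into a single hypothesis; they cannot be
  separated by Y-ion evidence even in principle.

Residue masses are fixed from monoisotopic elemental composition and kept
in a config-overridable registry. The mass of the HexNAc cross-ring
fragment (`Y$`, 0,2X0) is not standardized in the search-engine ecosystem;
we use 83.03711 Da (C4H5NO) and expose it as an argument everywhere it is
consumed.

## Library construction

For every glycopeptide precursor the GPSMs of each plausible glycan
structure have their identification scores summed; only GPSMs of the
top-sum structure survive (ties broken by canonical string order, for
determinism). Spectra are annotated by matching theoretical fragments — Y
ions at 1+..3+ including Y0/Y1/`Y$`, b/y at 1+..2+, and their
HexNAc/cross-ring variants — to the nearest peak within 20 ppm. Consensus
building discards replicates whose median dot product to the others falls
below 0.5 (dot products computed on intensity vectors aligned by
annotation identity, not m/z binning — the entries are annotated peak
lists), keeps peaks present in strictly more than 60% of the surviving
replicates, and averages intensities weighted by identification score.
When all replicates are mutually dissimilar the single best-scoring one is
kept rather than emitting nothing.

Transition filtering removes fragments outside the MS2 scan range
(200-2000 Da default) or inside *any* isolation window containing the
precursor (a precursor near a window edge is co-isolated by two
overlapping windows), keeps the 10 + 10 most intense peptide/glycan
transitions (intensity ties broken by ascending m/z), flags the top 6 + 6
as quantifiers, and drops entries with fewer than 3 transitions on either
part. RT calibration is LOWESS (span 2/3, 3 robustness iterations) through
anchor pairs, applied by interpolation with boundary clamping; at least 10
anchors are required, and anchors can be exported as TraML.

## Decoys

Three decoy classes are appended, one of each per target, giving a
combined library four times the target size:

* *peptide decoys*: sequence reversed with C-terminal K/R fixed (the
  glycosite marker travels with its residue); reversal preserves peptide
  mass, so Y ions are untouched while b/y ions move. Palindromic or
  colliding reversals fall back to a seeded interior shuffle (20 retries,
  then the entry is skipped with a warning).
* *glycan decoys*: every Y-ion m/z except Y0 and `Y$` shifted by an
  independent continuous uniform draw in [1, 30) Da applied to the
  singly-charged fragment mass (divided by charge above 1+). Per-fragment
  independence maximizes decoy spectrum randomness.
* *both decoys*: both transformations.

Decoy RTs equal their targets so decoys compete in the same extraction
windows.

## The two-dimensional FDR

Each candidate peak group carries peptide-evidence and glycan-evidence
sub-score blocks. Per axis, a semi-supervised learner (initialized with
the best single sub-score, 10 iterations of confident-positive selection
at 1% target-decoy FDR followed by an LDA refit, 3-fold cross-validated
scoring) produces a D-score; the axis-appropriate pseudo-labels are the
key structural idea — for the peptide axis, targets *and glycan decoys*
are pseudo-targets, because a glycan decoy still carries a genuine
peptide.

Writing s_P, s_G for the D-scores and pi_ij for the proportion of target
peak groups whose peptide (i) and glycan (j) assignments are null (0) or
correct (1), the class densities observed for targets (TT), glycan decoys
(TD), peptide decoys (DT) and both decoys (DD) are mixtures of four
component densities f_ij. The both-decoy density identifies f_00; the
single-decoy densities then identify f_10 and f_01 by subtraction (clipped
at zero and renormalized to unit mass, since a difference of kernel
estimates can dip negative). The proportions are estimated by Storey's
method (lambda = 0.4, overridable) on empirical p-values against the
appropriate decoy distributions: pi_00 + pi_01 from the peptide axis,
pi_00 + pi_10 from the glycan axis, pi_00 from the combined score against
both decoys; the remainder is clipped and renormalized so the four
proportions sum to one exactly.

PEPs follow as density ratios: PEP of a null peptide part, of a null
glycan part, of both null, and of their union, which satisfies the
inclusion-exclusion identity PEP_union = PEP_P + PEP_G - PEP_both
(asserted to 1e-10 in the tests, pre-monotonization). q-values are running
means of PEPs over acceptance sets, per run at peak-group level and
globally at glycopeptide level (best peak group per glycopeptide across
runs). The default report filter is run q < 5% in every run, q < 1% in at
least one run, and global glycopeptide q < 1%.

### Numerical choices

* Densities are bivariate Gaussian KDEs on a 128x128 grid spanning the
  observed scores plus a three-bandwidth margin, normal-reference
  bandwidth per axis.
* The PEP ratio is regularized by adding a common epsilon (1e-12 of the
  peak target density) to numerator and denominator, so the PEP tends to 1
  — the conservative limit — where all densities vanish. The epsilon is
  common to all four components, which keeps the inclusion-exclusion
  identity exact.
* Monotonization is a cumulative-minimum sweep under the product order on
  the grid (PEP non-increasing in each D-score), the isotonic solution
  that only lowers values at higher scores. Before the sweep, grid cells
  whose target density is below 5% of its peak are reset to PEP 1: such
  cells hold too few peak groups for a stable density ratio, and kernel
  tails there can otherwise produce a spuriously low PEP that the sweep
  would propagate across the grid. The 5% floor was chosen from
  diagnostic runs at n = 4000 and held fixed for the calibration
  experiments reported by the test suite.
* Components are combined first, then each reported component (including
  the union) is monotonized on its own grid; whether the source workflow
  monotonizes before or after combination is not documented, and the
  difference is below the calibration tolerances we assert.

## Glycoform inference

Wide isolation windows co-fragment glycoforms: same peptide, different
glycan, near precursor m/z. For each target precursor, candidate
background glycoforms are database glycans on the same peptide whose
precursor m/z falls inside the target's isolation window, isomer-merged,
ranked by the Y-fragment Jaccard similarity to the target, and capped at
n_bg = 50 (ties at the cap resolved by canonical string order). For the
union of hypotheses, all theoretical Y ions are generated in silico as
*identification transitions* (even those already observed), each mapped to
the hypotheses that can produce it, plus one unfragmented-precursor
transition per hypothesis.

Transition chromatograms are scored against decoy identification
transitions (random same-length peptide with PTMs kept, resampled until
the peptide mass differs by at least 1 Da; Y ions built from the decoy
peptide mass and the target glycan fragments). Per-transition PEPs come
from a univariate kernel mixture of target versus decoy discriminant
scores with a Storey null proportion, monotonized in the score.

The Bayesian hierarchical model then integrates, for hypotheses A_0
(incorrect detection) and A_1..A_N (glycoforms): priors from the MS2
peak-group PEP, split equally over candidate glycan compositions and then
over fragment-distinct isomer groups within each composition; an MS1
conditional keyed on membership of the 10 ppm precursor-tolerance set; MS2
unfragmented-precursor conditionals per hypothesis; and a product of
transition conditionals (1 - PEP for originating hypotheses, PEP
otherwise). All products accumulate in log space with a per-factor floor
of 1e-12. Posteriors are normalized at the precursor stage and again
after transition integration; composition-level posterior probabilities
sum the isomer groups. The glycoform PEP of a peak group is 1 minus the
posterior of its library glycan composition, and glycoform q-values reuse
the averaging machinery; background-only best hits are excluded from
target reporting.

## Semi-empirical library extension

For a target (peptide P, glycan G, charge n+), the k = 3 nearest library
spectra of P (ranked by Euclidean distance between glycan composition
vectors — Hex, HexNAc, NeuAc, Fuc counts) donate the peptide-part
fragments, and the k nearest spectra of G (ranked by amino-acid
composition distance) donate the glycan-part fragments; each part is
merged with the library consensus rules, fragment m/z values are
recomputed for the target coordinates, and the parts are scaled so the
peptide-to-glycan sum-intensity ratio equals the mean ratio over both
neighbor sets. The predicted RT is a Gaussian-weighted mean over the
peptide-sharing neighbors, charge states pooled, with weight
exp(-d^2 / (2 sigma^2)) and sigma^2 the mean squared distance; all-zero
distances degrade to uniform weights. Distance ties at rank k are resolved
by library order. Predicted entries must pass the same transition filters
as experimental ones, and extension only considers combinations from an
explicit allow-list, with base entries taking precedence.

## Quantification

Peak-group intensity matrices (missing is NA, never zero) are
median-normalized per run to the grand median of run medians, then
aggregated: glycopeptide = sum of the 3 most intense peak groups per
sample (membership recomputed per sample, matching the per-sample
phrasing of the aggregation rule), site-specific glycan = sum of the 3
most intense glycopeptides, protein glycosite = sum of all site-specific
glycans. CVs across technical replicates use the sample standard
deviation and require at least two values.

## What the synthetic data emulates — and what it does not

The `simulate_*` generators produce the statistical structure the models
assume, at desk scale:

* `simulate_glycan_db()`: random N-glycan trees grown from the
  trimannosyl-chitobiose core `(N(N(H(H)(H))))` — a stand-in for a real
  glycan structure database, which is pluggable via a one-structure-per-
  line TSV.
* `simulate_library()`: sequon-bearing tryptic-like peptides with
  separable log-normal fragment intensities (peptide-part pattern depends
  only on the peptide, glycan-part only on the glycan composition) and
  RTs from a smooth hydrophobicity model plus a glycan-size offset. This
  is exactly the separability the KNN predictor assumes, so
  cross-validation results on it are an upper bound, not a forecast for
  real spectra.
* `simulate_peak_group_features()`: four-class Gaussian sub-scores with
  the decoy classes drawn from their theoretical mixtures; the class
  separation (default 3 within-class standard deviations, carried by the
  co-elution analogue of each axis) is the one knob. Real sub-scores are
  neither Gaussian nor independent; passing calibration here shows the
  estimator is correct under its own assumptions, not that real data meet
  them.
* `simulate_entrapment_benchmark()`: targets carry H/N-only glycans; the
  entrapment set duplicates every peptide with a fucosylated variant (one
  hexose swapped for fucose, 15.99 Da lighter) constrained to land in the
  same isolation window, so shared-core Y ions show signal for target and
  entrapment entries alike and only glycoform-discriminating transitions
  plus MS1/MS2-precursor evidence can separate them. Entrapment entries
  are constructed MS2-detectable, which makes the no-inference entrapment
  rate ~50% — a deliberately adversarial design; on real data most
  entrapment entries already fail peak-group scoring.

Every generator is byte-reproducible under its seed.

## Problem sizes

The test suite validates calibration on 20,000 target peak groups across
5 seeds (realized false discovery proportion at q <= 0.01 within
[0, 0.02]) and the entrapment benchmark on 2,000 target precursors with
an equal-size entrapment set (binomial 95% CI half-width of the
entrapment percentage below 0.5 points). These sizes keep the full suite
under a few minutes on one CPU while leaving the Monte-Carlo margins
meaningful; the acceptance script reruns the entrapment benchmark from
scratch at the same size.

## Known limitations

* Glycan topology is taken from the upstream search engine; no linkage or
  anomericity information is modeled, and O-glycan multi-site
  localization is out of scope.
* The sub-score sets are open-ended by design (any `pep_*`/`gly_*`
  columns); the package does not define feature extraction.
* Density-ratio PEPs inherit the usual kernel-estimation caveats in
  sparse score regions; the density floor makes these regions
  conservative rather than accurate.
* The semi-empirical predictor cannot create fragment patterns absent
  from the experimental library; it recombines, it does not extrapolate.
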