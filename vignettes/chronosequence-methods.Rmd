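---
title: "Methods: from peak lists to permutation statistics on a permafrost chronosequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from peak lists to permutation statistics on a permafrost chronosequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryodomics)
```

This vignette is the package's account of its methods: the models and
procedures, the assumptions behind them, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The study design the package serves

A chronosequence pairs sites that differ primarily in age. For permafrost,
three ice-rich Pleistocene age classes (labelled here 19 ka, 27 ka, 33 ka,
four replicate cores each) are characterized on two molecular layers:

* water-extractable dissolved organic matter (DOM), measured by
  direct-infusion negative-mode FT-ICR MS and reduced to a sample-by-formula
  intensity matrix;
* microbial functional potential, measured by shotgun metagenomics and
  reduced to feature-by-sample count tables of KEGG orthologs (KOs) and
  carbohydrate-active enzyme (CAZyme) families.

The scientific questions are directional — does formula richness decline
with age, does the mean oxidation state of carbon decline, do fermentation
products accumulate, does CAZyme content per genome shrink — and
correlative: does the multivariate structure of the metagenome track the
multivariate structure of the DOM?

## Formula assignment

Negative-mode electrospray of DOM produces predominantly singly charged
deprotonated ions, so a peak at m/z `m` is treated as a neutral molecule of
mass `m + 1.00727646` Da (the proton mass absorbs the electron bookkeeping).
Candidate CHNOS formulas are enumerated inside element bounds (C 1–60,
H 1–122, N 0–4, O 0–30, S 0–2) by solving for the hydrogen count nearest
the residual mass on each (C, N, O, S) lattice point — exhaustive, because
the tolerance window is orders of magnitude narrower than one hydrogen
mass — and filtered for chemical plausibility:

* H:C within 0.3–2.25 and O:C ≤ 1.2 (the populated region of the van
  Krevelen plane for natural organic matter);
* double-bond equivalents `DBE = 1 + c − h/2 + n/2` a non-negative integer
  (even-electron neutral molecules; this enforces the H/N parity rule);
* DBE ≤ 25.

The DBE ceiling deserves a note, because it is the one filter that earns
its place quantitatively as well as chemically. The mass lattice contains a
near-degenerate substitution: exchanging C21H12 for O13S changes a formula's
mass by only 0.14 mDa, so above roughly 300 Da both partners of such a pair
can sit inside a 0.5 ppm window. The partners differ by 27 DBE, so one of
the two is always far outside the range of plausible natural-product
skeletons; without a DBE cap, a minimum-|error| chooser loses a few percent
of high-mass peaks to these decoys under realistic (0.1 ppm) mass error.
With the cap, assignment recovers > 99% of true peaks at 0.1 ppm error and
0.5 ppm tolerance — measured against generator truth records in the test
suite. All bounds and filters are user-configurable in
`assignment_params()`.

Remaining ambiguities are resolved deterministically: minimum |error in
ppm|, then fewer heteroatoms (n + s), then lower n. Peaks below the
signal-to-noise threshold (default 6, matching the ">6 sigma" convention
for FT-ICR baseline noise) are reported as `filtered`, never silently
dropped. Isotope fine structure, multiply charged ions and recalibration
are out of scope.

## DOM chemistry metrics

The nominal oxidation state of carbon is computed from stoichiometry:

$$\mathrm{NOSC} = 4 - \frac{4c + h - 3n - 2o - 2s}{c}$$

More reduced compounds score lower; NOSC is used as an indirect measure of
how thermodynamically favorable a substrate pool is for microbial
respiration. The per-sample summary is the **unweighted** mean over
detected formulas — a deliberate presence-based choice, since electrospray
intensities are not quantitative across compound classes; an
intensity-weighted variant exists behind an argument but is off by default.

Compound classes come from an ordered rule table over H:C, O:C, the
modified aromaticity index `AImod = (1 + c − 0.5o − s − 0.5h)/(c − 0.5o −
s − n)` (floored at 0), and nitrogen content; the first matching rule wins
and condensed aromatics (AImod ≥ 0.67) outrank everything. The default
boundaries are conventional van Krevelen ranges for the seven classes
commonly drawn on DOM plots; they are a documented stand-in, fully
overridable via `default_class_boundaries()`, because published boundary
tables differ in detail.

The chemodiversity partition treats a formula as present in an age class if
it is detected in *any* replicate of that class, then partitions the union
of detected formulas into per-class unique cells, pairwise-shared cells and
the all-classes core by exact set algebra — the cells always sum to the
total, which is also how the tests verify it.

The SCFA share of DOC is a molar-carbon ratio: `100 * sum(SCFA
concentration x carbons per molecule) / DOC molar carbon`. Because
published tables too often leave concentration bases ambiguous, the
function requires explicit units per analyte (`mg/L` converts through the
analyte's molar mass; DOC must arrive as `mg C/L` or molar carbon) and
refuses to guess.

## Functional profiles

Count tables are normalized two ways, serving different questions:
relative abundance (reads per database total) for compositional analyses,
and division by a single-copy marker gene (ribosomal protein L14, K02874)
for per-genome trends; three alternative markers are carried so robustness
of any marker-normalized claim can be checked by swapping. Shannon
diversity is reported in nats. The per-family screen fits a one-way ANOVA
of relative abundance on age class for every family and flags raw
P < 0.01, with no multiple-testing correction by default — mirroring the
screening convention it reproduces — and a Benjamini–Hochberg option off
by default. The screen's F statistics are computed by a vectorized
between/within decomposition (identical to `aov()` per feature, verified
in tests) so thousands of families are screened in milliseconds. Two
degenerate rules are fixed: a family constant everywhere with no
between-group signal gets p = 1 (identical data cannot show differences);
zero within-group variance with real separation gets p = 0. The screen
runs on relative abundances, not marker-normalized values: marker
normalization is introduced only for the aggregate per-genome trend.

## Univariate chemistry comparisons

Each analyte is routed by a Shapiro–Wilk test on the one-way-ANOVA
residuals at alpha = 0.05 (residuals, not raw values, because the group
means are nuisance location shifts). Normal-looking residuals go to ANOVA
with Tukey HSD; otherwise Kruskal–Wallis with pairwise Welch tests,
Holm-adjusted — Holm because it is uniformly valid with no independence
assumption; Bonferroni and BH are available. Pairwise decisions are
summarized as compact letter displays via insert-and-absorb, and the
letter/significance consistency (groups share a letter iff their pairwise
p ≥ alpha) is asserted property-style in the tests. Constant data take a
documented degenerate path: p = 1, one shared letter.

## Permutation multivariate statistics

These are the package's own implementations, not wrappers; established
libraries appear only as independent cross-checks in the test suite.

* **Bray–Curtis**: `d(x,y) = sum|x−y| / sum(x+y)`.
* **MRPP**: observed statistic `delta = sum (n_i/N) * (mean within-group
  distance)`; significance by label permutation, one-sided (small delta =
  separation); effect size `A = 1 − delta_obs / mean(delta_perm)`, i.e. the
  permutation estimate of the chance-corrected agreement. Groups of size 1
  carry no within-group information and are excluded with a warning.
* **PERMANOVA**: Gower-centered inner-product matrix `G = −½ J (D∘D) J`;
  sequential sums of squares by projecting G onto nested design matrices
  (`SS_j = tr(H_j G) − tr(H_{j−1} G)`), pseudo-F against the residual mean
  square, p by simultaneous row/column permutation of the distance matrix.
  Raw observations are permuted — the simplest exchangeability model for a
  single chronosequence factor — which differs from residual-permutation
  variants; with sequential SS, term order matters for non-orthogonal
  designs and the order used is always reported.
* **Mantel**: Pearson correlation of lower triangles (Spearman available),
  p by permuting one matrix, one-sided greater.
* **NMDS**: Kruskal stress-1 minimized by alternating monotone regression
  (pool-adjacent-violators) with a Guttman-transform update; ties in the
  input dissimilarities are handled by the primary approach (tied
  dissimilarities impose no mutual order constraint, realized by ordering
  tie blocks by current configuration distance). k = 2 by default — the
  dimensionality these ordinations are plotted in — with 20 starts (first
  metric, rest random), convergence at stress improvement < 1e-6, best
  start returned, centered and rotated to principal axes. Non-convergence
  is flagged, never silent.
* **envfit**: each variable regressed on the ordination coordinates; r² of
  the fit, unit-length direction as the arrow, p by permuting the variable.
* **UPGMA**: closest-pair agglomeration with cluster-size-weighted average
  linkage, merge height at half the pair distance, deterministic
  lexicographic tie-break, Newick serialization; the implied cophenetic
  matrix is ultrametric by construction.

Every permutation p-value uses the `(b+1)/(m+1)` estimator, so p can never
be 0 and is exactly reproducible given `n_perm` and a seed.

## What the synthetic generator emulates — and what it does not

The generator plants exactly the structure the analysis is designed to
detect, with defaults chosen once as the package's study conditions:

* three age classes x four replicates; formula pools of 1200 CHNOS
  formulas over 150–800 Da drawn from a plausibility-filtered lattice with
  a class mixture dominated by lignin-like formulas (45%), the remainder
  spread over tannin, condensed-aromatic, protein, carbohydrate, lipid and
  unsaturated-hydrocarbon classes — the composition ordering reported for
  plant-derived permafrost DOM;
* declining per-class formula richness (400/330/260) and an additive mean
  NOSC shift (0/−0.1/−0.25), planted by biasing the class-specific extras
  around a shifted NOSC target while a common core (shared fraction 0.6 of
  the smallest richness) is present in all classes;
* per-replicate detection probability 0.9 ("dropout") and log-normal
  intensities (meanlog 0, sdlog 1) — distributional choices, not
  inferences, since replicate variability and intensity distributions are
  rarely published;
* peak lists as the exact inverse of assignment: deprotonated m/z with
  Gaussian ppm error (default 0.1 ppm, the accuracy class of a high-field
  FT-ICR instrument) plus Poisson noise peaks (20/spectrum) uniform in m/z;
* count tables drawn multinomially (KO table at 1e5 reads/sample) from a
  fixed log-normal composition, with 10% of CAZyme families shifted
  multiplicatively up to x10 along the age order, marker genes pinned at
  near-constant expected relative abundance, a per-class CAZyme read-yield
  trend (1/0.85/0.7) that plants the declining marker-normalized CAZyme
  abundance, and an optional convex coupling (weight 0.5) of each sample's
  composition to its DOM profile through a fixed random loading matrix —
  which makes the DOM/metagenome Mantel correlation positive by
  construction;
* chemistry tables drawn from per-class truncated Gaussians whose means
  and standard deviations default to a published permafrost filtrate
  characterization (DOC and most SCFAs rising with age; acetate
  0.91/7.68/40.45 mg/L).

What it does **not** emulate: isotopologue peaks, mass-calibration drift,
compound-class-dependent ionization efficiency, read-level sequencing
error, phylogenetic structure among genomes, compositional closure effects
beyond the multinomial, or spatial correlation among replicate cores.
Passing tests therefore demonstrate that the pipeline recovers planted
structure of the stated kind under idealized noise — not that any given
field data set satisfies these assumptions.

## Numerical and design choices

* Atomic masses are IUPAC monoisotopic values held in one internal table;
  ppm errors are referenced to the observed neutral mass.
* The Shapiro–Wilk gate, ANOVA/Tukey, Kruskal–Wallis and Welch tests are
  base-R implementations (`shapiro.test`, `aov`, `ptukey`, `kruskal.test`,
  `t.test`); re-implementing them would add risk without value.
* Degenerate inputs follow explicit rules stated above rather than NA
  propagation: constant data give p = 1; all-zero samples and absent/zero
  markers are hard errors naming the offending samples.
* Seeds: every stochastic function takes a `seed` and restores the
  caller's RNG state (`with_seed()`), so generators are pure functions of
  (design, seed); the pipeline derives per-stage seeds from one master
  seed by fixed small offsets.
* Problem sizes in the shipped tests and acceptance script — 12 samples,
  ~1200-formula pools, ~3500 synthetic peaks per run, 1000-family null
  screens, 999–4999 permutations, 1000-replicate calibration loops — were
  chosen so the statistical assertions have tight Monte-Carlo error while
  a full run stays in the minutes range on one core.

## Known limitations

* The van Krevelen boundary table is a conventional stand-in; published
  class boundaries differ, and class-proportion outputs shift accordingly.
* PERMANOVA reports sequential (Type-I-style) sums of squares only; for
  correlated predictors the attribution depends on term order.
* NMDS minimizes stress locally; restarts mitigate but cannot guarantee the
  global optimum on pathological inputs (the converged flag and stress are
  always reported).
* Formula assignment handles singly charged CHNOS ions only; P-containing
  formulas, adducts and multimers are out of scope.
* MRPP's A statistic uses the permutation estimate of the expected delta;
  implementations that use the analytic expectation will differ slightly in
  A (not in delta or p).
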