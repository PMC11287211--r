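---
title: "Models and methods behind corrisoil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind corrisoil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrisoil)
```

`corrisoil` packages four linked analyses of corrinoid (vitamin B₁₂ family)
ecology in soil microbial communities, plus the synthetic-data generators
used to test them. This vignette explains each model, its assumptions, the
parameters that matter, and the numerical and design choices made where the
design was genuinely open.

## Corrinoid ecological roles from genome annotations

A genome's relationship to corrinoids is predicted from two marker sets:

* **biosynthesis markers** — three corrin-ring synthesis steps whose
  anaerobic/aerobic ortholog pairs collapse onto three KOs (cbiC/cobH
  K06042, cbiF/cobM K05936, cbiL/cobI K03394). Their presence is strongly
  correlated with a complete de novo pathway, so one detection suffices to
  call biosynthetic capacity; this deliberately trades a small
  false-positive risk for robustness to incomplete MAGs.
* **corrinoid-dependent functions** — a named map from function (methionine
  synthase, methylmalonyl-CoA mutase, epoxyqueuosine reductase ...) to
  identifiers, each paired where one exists with its corrinoid-independent
  alternative (MetE, the methylcitrate pathway, QueH, Class I/III RNR).

The role rule is a total function of the two counts: producer
(both present), producer/non-user (biosynthesis only), dependent
(dependent only), independent (neither). Producer/non-users have never been
confirmed in a complete genome, so they are flagged `unverified` and a
warning is raised.

Two identifier-level decisions are worth spelling out. KO **K00525** mixes
the Class I (corrinoid-independent) and Class II (corrinoid-dependent)
ribonucleotide reductases; Class II is therefore detected through Pfam
**PF08471**, and K00525 is excluded from every default set — including the
Class I set, so that no genome is called RNR-independent on the ambiguous
KO alone (the β subunit K00526 and the anaerobic Class III K21636 carry
that call). Second, the complete corrinoid-dependent identifier catalogue
is community-curated and evolving; the defaults in `marker_config()` seed
the focal functions and are fully editable in code or through the YAML
template in `inst/extdata/corrinoid_markers.yml`. Published percentages
depend on the catalogue used, so any reproduction should state its config.

`redundancy_report()` reports two denominators on purpose: percentages of
all genomes, and percentages of genomes in which either enzyme version was
detected. Statements like "55% of RNR-carrying genomes keep only the
corrinoid-independent enzyme" use the second.

Taxonomy strings are parsed as semicolon-delimited ranks; missing ranks
become `unassigned_<rank>` so per-phylum marginal counts always sum to the
table total.

## Bioassay calibration

The indicator strain's OD₆₀₀ response to cobalamin is saturating and
monotone but has no agreed parametric form, so the calibration is a
**monotone piecewise-linear interpolant of mean OD versus
log₁₀(concentration)** — transparent, exactly invertible at the calibration
knots, and auditable for monotonicity (mean ODs that decrease by more than
`monotone_tol`, default 0.01 OD, reject the fit; a completely flat
calibration is rejected outright). Replicate wells are averaged before
inversion by default; per-well inversion is a flag.

Censoring uses three thresholds:

* **LOD OD** = blank mean + 3 × blank sd (`lod_multiplier` configurable);
  readings at or below it are `below_LOD`.
* readings above the highest calibration OD are `above_saturation`; the
  response saturates near 1 nM cobalamin (`saturation_conc`).
* the **quantitation range** runs from the lowest standard responding above
  the blank mean to the concentration at which the curve enters its plateau
  (first standard reaching 95% of the maximum mean OD, `plateau_frac`), or
  the top standard if none does earlier.

Every output is in **cobalamin equivalents**: the assay responds to distinct
corrinoids with different sensitivities and no corrinoid-specific
correction is attempted.

## Serial-extraction partition model

Serial extraction of soil with a phosphate-buffered medium is modelled as
repeated equilibrium partitioning. With a round-invariant partition
coefficient $K_d = [\mathrm{B12}_{aq}]/[\mathrm{B12}_{soil}]$ and the
aqueous phase equilibrating against the post-round soil pool, the soil pool
shrinks by the constant factor $1/(1 + K_d\,v_{aq}/v_{soil})$ each round,
the aqueous series decays geometrically, and each consecutive pair of
rounds identifies

$$K_d = \frac{v_{soil}\,(aq_n - aq_{n+1})}{v_{aq}\,aq_{n+1}}.$$

A variant of this combined formula with $aq_n$ in the denominator
circulates; it is **not** consistent with the recursion above (the two
agree only as $K_d v_{aq}/v_{soil} \to 0$), so the self-consistent form is
the default and `form = "printed"` computes the literal variant for
comparison. The self-consistent form also reproduces the back-extrapolation
factor exactly: the pool $k$ rounds earlier is the current pool times
$(1 + K_d v_{aq}/v_{soil})^k$, which inverts forward depletion without
error.

Choices and caveats:

* **Geometry defaults** are the study design: 0.01 L extractant against
  0.001 L of soil (1 g at density 1 g/ml).
* **The round window is a required explicit argument.** Early rounds of
  real extractions carry desorption/lysis transients (the study used rounds
  6–9); the estimator never infers a window. On transient-free synthetic
  series all pairs are used.
* **Censored rounds are never zero-filled**: `total_pool()` propagates
  below-LOD rounds as a `[0, LOD]` interval into lower/upper bounds.
* Per-pair estimates are summarised by their mean and the **sd over
  pairs** — a spread, not an error-propagated uncertainty.
* `partition_upper_bound()` bounds $K_d$ from a spike-and-non-detection
  experiment under the stated assumption that the spike adsorbs fully; the
  assumption is echoed in the result record because it is not checkable
  from the inputs.
* Non-equilibrium sorption kinetics, corrinoid speciation and the
  intracellular/extracellular split are out of scope; all pools are
  cobalamin equivalents.

Unit bookkeeping is centralised: aqueous concentrations enter in nM,
removals are `aq_conc × vol_aq / soil_mass` converted once to pmol/g.
`molecules_per_cell()` applies Avogadro's number and reports the nearest
power of ten, the resolution at which such estimates are comparable.

## Community statistics

The 16S analyses operate on a `feature_table` (zOTU × sample counts, sample
metadata, taxonomy). Counts are converted to relative abundances per sample
— the table is compositional; no rarefaction is performed, and that choice
is visible in the code rather than buried in a pipeline. Aggregation at a
rank sums counts of zOTUs sharing the label, so per-sample totals are
invariant across ranks.

Standard steps delegate to the field's standard implementations behind this
package's interface: Bray–Curtis and binary Jaccard to `vegan::vegdist()`,
ANOSIM to `vegan::anosim()`, PERMANOVA to `vegan::adonis2()`,
principal-coordinates analysis to `stats::cmdscale()`, Kruskal–Wallis and
Mann–Whitney to `stats::kruskal.test()`/`stats::wilcox.test()`. The test
suite cross-checks them against independent oracles (hand-computed
dissimilarities, a brute-force rank implementation of ANOSIM R, the
sums-of-squared-distances pseudo-F formula, `ape::pcoa()`, exact
permutation enumeration for Mann–Whitney).

Decisions that shape results:

* **No multiple-testing correction by default.** The responsiveness screen
  calls significance at raw p ≤ 0.05, the screen's native convention; a
  Benjamini–Hochberg column (`p_adj`, within timepoint) is always emitted
  alongside so the multiplicity cost stays visible.
* **Two distinct "fraction responsive" summaries** are separate functions,
  never conflated: `responsive_fraction_count()` (taxa significant at any
  timepoint over all observed taxa — the enrichment-style summary) and
  `responsive_fraction_abundance()` (summed mean relative abundance of
  significant taxa per timepoint — the microcosm-style summary).
* **Degenerate taxa are skipped, not tested**: taxa observed in fewer than
  two treatment groups, or identical in every sample (tie-corrected H
  undefined), are reported with `status = "skipped"`.
* **Uninoculated controls** are excluded from treatment screens but kept
  for inoculated-versus-control ordination checks; the exclusion is
  metadata-driven (`inoculated` flag).
* **Permutation tests** default to 999 permutations with a mandatory
  recorded seed; the observed statistics themselves are deterministic, and
  p-values follow the `(1 + hits)/(1 + n_perm)` convention. Fewer than 99
  permutations triggers a warning.
* **Negative PCoA eigenvalues** (expected for non-Euclidean
  dissimilarities) are reported unchanged and excluded from
  variance-explained proportions; a Cailliez correction is available by
  flag but off by default.

One calibration caveat discovered while validating the screen: with 7
treatment groups of 5–6 replicates, the chi-square approximation to the
Kruskal–Wallis H is **systematically conservative** — Monte-Carlo
simulation of the tie-free null at that design attains ≈ 0.034 at nominal
0.05 (≈ 0.044 even at 10 replicates). A null screen therefore flags
slightly fewer than 5% of taxa, and the suite checks the screen's
false-positive rate against a matched continuous-null simulation rather
than against the nominal level. Real screens at these replicate counts are
slightly conservative, not anticonservative.

## Synthetic data: what it emulates, and what it does not

Each generator returns the dataset plus a `truth` record (parameters, seed,
planted effects); regeneration from the same arguments and seed is
identical, and recovery tests read the truth rather than re-deriving it.

* `gen_annotations()` samples roles from a mix (default ≈ 79% dependent,
  20% producer — a grassland-soil-like composition) and plants markers that
  force each role, plus decoy annotations the classifier must ignore.
  `gen_mag_study_table()` is a deterministic 503-genome instantiation
  planting a published role/redundancy breakdown exactly; it is a synthetic
  stand-in for a real annotation supplement and exercises the rule engine,
  not the annotations themselves.
* `gen_extraction_series()` forward-simulates the equilibrium recursion
  (default pool 34 pmol/g, the scale measured for a corrinoid-rich
  grassland soil) with multiplicative lognormal measurement noise (default
  log-sd 0.05, a typical bioassay CV). Mass is conserved exactly in the
  noiseless truth. Real extractions additionally show early-round
  transients, which the generator deliberately omits — hence recovery tests
  on synthetic data say nothing about window choice on real series.
* `gen_standard_curve()` draws ODs from a saturating hyperbolic response
  with plateau near 1 nM.
* `gen_community()` emulates the two 16S designs: *enrichment* (media M9
  and R2, 7 corrinoid treatments — none, cobalamin, cobinamide, four
  lower-ligand variants — 6 replicates plus one uninoculated control,
  weeks 1/2/12/14) and *microcosm* (soil, 5 replicates, days
  0/3/10/30/50). Baseline expected abundances are log-normal
  (`baseline_sdlog = 1`); responder zOTUs are multiplied by a per-corrinoid
  fold-change (suppression via FC < 1 supported) before renormalisation;
  counts are multinomial at the given depth (default 50 000 reads, typical
  for amplicon libraries), with an optional Dirichlet-multinomial
  overdispersion parameter — multinomial-first because no noise model is
  dictated by the designs, and the simplest model is the most transparent
  null. Each responder gets a dedicated lineage so its signal propagates
  cleanly to higher ranks. Uninoculated controls receive a half-contaminant
  profile at a tenth of the depth, emulating cross-contamination reads.

What passing tests on these tables show is that the statistics recover
planted structure under multinomial sampling; they do not show robustness
to features the generator omits — temporal autocorrelation, taxon-taxon
interactions, compositional spillover beyond renormalisation, variable
library sizes, or chimeric/contaminant reads beyond the uninoculated
profile.

## Problem sizes and runtimes

The suite runs at desk scale by design: role tests on a few hundred
genomes, partition recovery on 100 seeded 12-round series, screen
calibration on 1000–2000-taxon null tables at one timepoint, permutation
tests at 99–999 permutations. These sizes keep every Monte-Carlo band wide
enough to be stable across seeds while exercising the same code paths as a
full-size analysis.

## Known limitations

* Role classification is only as good as the annotation catalogue;
  transporter-based corrinoid-uptake prediction is deliberately absent
  (annotations are too sparse to call reliably).
* The bioassay model is an interpolant, not a mechanistic growth model;
  between-knot accuracy depends on calibration density.
* The partition model assumes a single well-mixed adsorbed pool with
  round-invariant $K_d$; multi-site sorption or kinetic limitation would
  bias pair estimates in ways the model cannot flag.
* The screen's p ≤ 0.05 convention, retained for comparability, implies a
  non-trivial false-positive burden across thousands of taxon × timepoint
  tests; the emitted BH column is the corrective.
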