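# corrisoil

Corrinoids — the vitamin B₁₂ (cobalamin) family of cobalt-containing
cofactors — are required by most microbes but synthesised de novo by few, so
they are shared nutrients whose structure and availability can shape whole
microbial communities. `corrisoil` implements the computational side of a
corrinoid ecology study of soil, for microbiome researchers who want to run
the same analyses on their own genomes, bioassay plates, extraction series
and 16S amplicon tables:

1. **Genome role classification** (`classify_roles()`, `role_summary()`,
   `redundancy_report()`): each genome/MAG is assigned one of four corrinoid
   ecological roles from its KO/Pfam annotations. With *B* ≥ 1 corrin-ring
   biosynthesis markers (cbiC/cobH K06042, cbiF/cobM K05936, cbiL/cobI
   K03394) and *D* ≥ 1 corrinoid-dependent functions:
   producer (*B* ≥ 1, *D* ≥ 1), producer/non-user (*B* ≥ 1, *D* = 0),
   dependent (*B* = 0, *D* ≥ 1), independent (*B* = 0, *D* = 0).
   Class II (corrinoid-dependent) ribonucleotide reductase is detected via
   Pfam PF08471 because KO K00525 conflates the Class I and II enzymes.
   `redundancy_report()` tallies, per function, genomes carrying the
   corrinoid-dependent enzyme, its corrinoid-independent alternative, both,
   or neither.
2. **Bioassay calibration** (`fit_standard_curve()`,
   `od_to_concentration()`, `quantify_plate()`): OD₆₀₀ readings of a
   corrinoid-requiring indicator strain are converted to cobalamin-equivalent
   concentrations through a monotone piecewise-linear interpolant of OD vs
   log₁₀(concentration), with a blank + 3·sd limit of detection and
   saturation censoring (the response plateaus near 1 nM cobalamin).
3. **Soil partition model** (`estimate_kd()`, `back_extrapolate()`,
   `total_pool()`, `molecules_per_cell()`, `partition_upper_bound()`):
   serial phosphate-buffer extractions of soil deplete an adsorbed corrinoid
   pool geometrically under an equilibrium partition coefficient
   K_d = [B12_aq]/[B12_soil]. Each consecutive pair of rounds gives
   K_d = vol_soil (aq_n − aq_{n+1}) / (vol_aq · aq_{n+1}), and the
   pre-extraction pool is the late-round pool times
   (1 + K_d · vol_aq/vol_soil)^k.
4. **Community statistics** (`bray_curtis()`, `jaccard()`,
   `pcoa_ordination()`, `anosim_test()`, `permanova_test()`, `kw_screen()`,
   `responsive_fraction_count()`, `responsive_fraction_abundance()`,
   `pairwise_mw()`): taxonomy-level aggregation of zOTU tables, Bray–Curtis
   and Jaccard dissimilarity, principal-coordinates analysis, ANOSIM R and
   PERMANOVA pseudo-F permutation tests, and a per-taxon Kruskal–Wallis
   screen for corrinoid-responsive taxa with Mann–Whitney pairwise
   follow-ups.
5. **Synthetic data** (`gen_annotations()`, `gen_extraction_series()`,
   `gen_standard_curve()`, `gen_community()`): ground-truthed generators
   that emulate each study design (seven corrinoid treatments, replicated
   enrichment cultures and soil microcosms, multinomial sequencing depth),
   so every stage is testable without downloads.

Inputs are plain data frames or plain-text files (TSV/CSV; see
`read_annotations()`, `read_series()`, `read_feature_table()`), outputs are
tibbles, fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a 12-round serial extraction of a soil containing 34 pmol
cobalamin equivalents per gram with true K_d = 0.04 and 5% measurement
noise, then recover the partition coefficient and the pool:

```r
library(corrisoil)

g <- gen_extraction_series(true_kd = 0.04, initial_pool_pmol_per_g = 34,
                           n_rounds = 12, noise_sd = 0.05, seed = 1)
fit <- estimate_kd(g$series, rounds_use = 1:12)
fit
#> <partition_fit>
#>   K_d = 0.03963 +/- 0.009098 (11 pair estimates, rounds 1-12, self_consistent form)

total_pool(g$series, residual_pmol_per_g = g$truth$residual_pmol_per_g)
#> # A tibble: 1 × 5
#>   total_pmol_per_g lower upper n_rounds n_censored
#>              <dbl> <dbl> <dbl>    <int>      <int>
#> 1             33.9  33.9  33.9       12          0

molecules_per_cell(34)
#> # A tibble: 1 × 2
#>   molecules_per_cell order_of_magnitude
#>                <dbl>              <dbl>
#> 1             20475.              10000
```

The estimator recovers K_d to within one pair-level standard deviation, the
summed removals plus residual reconstruct the 34 pmol/g pool, and at 10⁹
cells per gram that pool corresponds to ~2 × 10⁴ corrinoid molecules per
cell — order of magnitude 10⁴.

Screen a simulated soil-microcosm 16S experiment (seven corrinoid
treatments, five replicates, two planted responder orders at fold-change 6)
for corrinoid-responsive taxa:

```r
gc <- gen_community("microcosm", n_taxa = 300, responders = c(1L, 2L),
                    fold_changes = 6, depth = 50000, timepoints = 3, seed = 1)
sc <- kw_screen(gc$table, rank = "order", timepoints = 3)
responsive_fraction_count(sc)
#> # A tibble: 1 × 4
#>   rank  n_responsive n_taxa fraction
#>   <chr>        <int>  <int>    <dbl>
#> 1 order            2     39   0.0513

anosim_test(bray_curtis(gc$table, rank = "order"),
            gc$table$samples$corrinoid, n_perm = 999, seed = 1)
#> # A tibble: 1 × 8
#>   method statistic_name statistic p_value n_perm  seed n_samples n_groups
#>   <chr>  <chr>              <dbl>   <dbl>  <dbl> <dbl>     <int>    <int>
#> 1 anosim R                  0.189   0.002    999     1        35        7
```

Exactly the two planted responder orders are recovered (2 of 39 observed
orders), and the community-level ANOSIM confirms that samples cluster by
corrinoid treatment (R = 0.19, p = 0.002).

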