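# beequant

Quantitative bee community metabarcoding with rRNA copy-number correction.

Pooled-specimen amplicon sequencing (one leg per trapped bee, pooled per
sample, 28S rRNA amplicons) reliably tells you *which* genera are in a
sample, but not *how many* specimens: the rRNA operon occurs in tandem
arrays whose copy number varies enormously between taxa, so read counts
over- or under-represent taxa by orders of magnitude. `beequant` implements
the full analysis around this problem for monitoring-style bee surveys:

* **Synthetic data with known truth** — study designs (management ×
  location × date pools), negative-binomial specimen communities,
  marker-like reference sequences with controlled pairwise divergence, and
  multinomial amplicon reads with substitution errors, FASTQ qualities,
  specimen dropout and a beetle-leg calibrator spike-in.
* **Read processing** — expected-error filtering
  (discard reads with `E = Σ 10^(-Q/10) ≥ 1`), exact dereplication with
  replicate thresholds, and global-alignment assignment to a reference
  database at ≥99% identity, with explicit unassigned/ambiguous/calibrator
  accounting.
* **Quantitation** — per-taxon correction factors `c_i` estimated by a
  genetic algorithm from samples whose genus sets are concordant between
  morphology and sequencing. The forward model is
  `p_i = n_i c_i / Σ_j n_j c_j` (read share = specimen count × factor,
  renormalized); the fitness is the summed squared error between model and
  observed read proportions; factors are reported normalized to min = 1 and
  applied in reverse (`q_i ∝ r_i / c_i`) to predict specimen abundance from
  reads.
* **Community analytics** — presence-based richness from either data type
  and their Pearson correlation, sample-based rarefaction
  (`S(t) = S_obs − Σ_i C(T−T_i, t)/C(T, t)`) with Chao2 extrapolation, and
  PCA ordination of relative abundances with per-group minimum convex
  polygons.

Everything takes and returns tibbles, chains with the pipe, and has
`tidy()`/`glance()`/`autoplot()` methods for the fitted objects.

## Worked example

Simulate a small two-location season, sequence it, process the reads, and
recover correction factors from a noiseless calibration experiment:

```r
library(beequant)

design    <- study_design(management_types = c("CRP", "NPAM"),
                          locations = c("Arrowwood", "Kulm"), n_dates = 4)
profiles  <- bee_taxon_profiles(6)
refdb     <- generate_reference_db(7, length = 507, min_divergence = 9, seed = 1,
                                   taxon_ids = c(profiles$taxon_id, "Tenebrio"))
specimens <- generate_specimen_table(design, profiles, seed = 2)
reads     <- simulate_reads(specimens,
                            dplyr::bind_rows(profiles, calibrator_profile()),
                            refdb, reads_per_sample = 4000,
                            per_base_error = 0.001, calibrator_count = 2, seed = 3)
counts    <- process_reads(reads, refdb, mode = "community",
                           calibrator_taxon = "Tenebrio")
counts
#> # A tibble: 16 × 10
#>   sample_id         Hylaeus Hoplitis Lasioglossum Megachile Bombus Agapostemon
#> 1 CRP_Arrowwood_d01       0        5          105        28   2877           3
#> 2 CRP_Arrowwood_d02       2        0           84        14   2899          13
#> ...
```

Bombus dominates the reads despite modest specimen counts — that is the
copy-number distortion the correction factors undo. Molecular and
morphological richness correlate positively but imperfectly
(`richness_correlation()` gives r = 0.48 here: rare low-copy taxa drop below
the detection thresholds), which is why quantitation needs the calibration
step:

```r
exp <- factor_recovery_experiment(seed = 1)   # 15 genera + calibrator,
exp$comparison                                # population 1000, 1e5 iterations
#> # A tibble: 16 × 4
#>    taxon          truth recovered relative_error
#>  1 Hylaeus          1        1           0
#>  2 Hoplitis        14.9     14.8         0.00395
#>  3 Lasioglossum    30       29.9         0.00350
#>  4 Megachile      124.     124.          0.00347
#>  5 Bombus        1248     1244.         0.00343
#> ...
```

On noiseless forward-model data the genetic algorithm recovers the true
factors — spanning 1× to 1,248× — to within half a percent in about a
minute. `autoplot(exp$fit)` shows the SSE trajectory;
`estimate_abundance_tbl(counts, factors, specimens)` applies fitted factors
back to read counts to predict specimen abundance.

Thin command-line wrappers over the same functions live in `inst/scripts/`
(`process.R`, `quantify.R`, `analyze.R`).

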