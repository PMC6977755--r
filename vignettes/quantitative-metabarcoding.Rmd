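---
title: "Quantitative bee metabarcoding: models, correction factors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative bee metabarcoding: models, correction factors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beequant)
```

## The problem

Amplicon sequencing of pooled insect tissue (one leg per specimen, pooled per
trap sample) identifies *which* taxa are present, but the share of reads a
taxon receives is a poor estimate of its share of specimens. The dominant
distortion for rRNA loci is gene copy number: the rRNA operon occurs in
tandem arrays whose copy number varies by orders of magnitude between taxa,
compounded by the number of haploid genomes per cell and cells per leg.
`beequant` implements a complete, testable pipeline around this problem:
simulation of communities and reads with known ground truth, read processing
into count tables, estimation of per-taxon correction factors, and the
community-level analytics used to compare morphological and molecular
identification.

## The forward model

For a sample containing $n_i$ specimens of taxon $i$ with correction factor
$c_i$, the expected proportion of reads assigned to taxon $i$ is

$$p_i = \frac{n_i c_i}{\sum_j n_j c_j}.$$

`expected_proportions()` computes this; `estimate_abundance()` inverts it,
$q_i \propto r_i / c_i$, turning read counts $r_i$ back into specimen
proportions. The two are exact inverses, which the test suite asserts as a
property. The factors are identified only up to a common scale — multiplying
every $c_i$ by a constant leaves every $p_i$ unchanged — so all reported
factors are normalized to a minimum of 1 (`normalize_factors()`), i.e. fold
units relative to the lowest-copy taxon.

A known spike-in calibrator (two beetle legs added to every pool) anchors
the estimation: it enters the specimen table as a pseudo-taxon with count 2
in every sample and is carried through the objective like any other taxon.

## Read processing

Reads are filtered with the expected-error statistic
$E = \sum_b 10^{-Q_b/10}$: a read is discarded when $E \ge 1$, i.e. when it
carries at least one predicted error. Note the strict inequality — a
100-base read uniformly at Q20 has exactly $E = 1$ and is discarded. This is
deliberately stricter than the common "keep $E \le$ maxee" convention.

Surviving reads are dereplicated by exact full-length string equality;
uniques below a replicate threshold are dropped (10 when validating
per-taxon reference pools, 2 for community samples — singletons are almost
always sequencing errors at these depths). Each unique is then globally
(end-to-end) aligned against every reference sequence. Identity is matching
columns divided by **total alignment columns, gaps included**, so length
variants are penalized; whether the comparable published threshold counted
gaps is not documented, and the gap-inclusive choice is the conservative
one. Assignment requires at least 99% identity to a single best reference;
exact ties at the best identity are counted as `ambiguous` and contribute to
no taxon (deterministic and conservative — nothing is silently assigned),
and sub-threshold uniques are `unassigned`. Calibrator hits are tallied
separately. Per sample, mapped + unassigned + ambiguous + calibrator always
equals the post-filter read count; this accounting identity is asserted in
the tests.

At 507 bp, 99% identity tolerates at most 5 substitutions; a 9-nt
nearest-neighbour divergence between references therefore keeps taxa
separate, while a 1-nt divergence collapses them — both regimes are
exercised with the generator's high- and low-divergence modes.

## Correction-factor estimation

Factors are estimated only from *concordant* samples — samples whose genus
set is identical under morphological and molecular identification
(`select_concordant_samples()`) — because the objective needs the same taxon
set on both sides. The fitness of a candidate factor vector is the sum of
squared errors between forward-model proportions and observed read
proportions over all calibration samples and taxa (calibrator included;
unassigned and ambiguous reads excluded from the denominator). SSE is
computed on proportions, not raw counts: read depth varies per sample and
the forward model only predicts composition.

`ga_run()` implements the genetic algorithm: 1,000 genomes, all initialized
at a factor of 10 for every taxon; each iteration the population is ranked,
the worst third is culled, and the best third is duplicated, with duplicates
mutated and originals kept untouched (so the best fitness is monotone
non-increasing — asserted as a property). Mutation adds a draw from
$N(0, 5^2)$ to a **single randomly chosen factor coordinate** of the
duplicate, clamped below at 0.01 to preserve positivity.

The single-coordinate mutation is a considered choice. Perturbing every
coordinate of a 16-taxon genome at once means that, near the optimum, a
duplicate only improves if all 16 draws land well simultaneously; in our
experiments the best SSE then stalls around $10^{-3}$ and the small-factor
taxa pin at the clamp, leaving normalized factors tens of fold off.
Single-gene mutation turns the algorithm into a population-based randomized
coordinate descent: the same 1e5-iteration budget reaches SSE near
$10^{-8}$ and sub-1% recovery error on noiseless data. The all-coordinate
variant remains available via `mutation_genes`.

The desk-scale default is $10^5$ iterations (minutes on one CPU with the
vectorized batch scoring); `iterations = 1e7` reproduces a full-scale run.
Eight logarithmically spaced checkpoints record the convergence trajectory.

## The recovery experiment

`factor_recovery_experiment()` is the package's standard validation: 15 bee
genera plus the calibrator over 15 concordant samples, observed proportions
set *exactly* to the forward model, so the truth is recoverable by
construction. True factors use the five published estimates (Hylaeus 1x,
Hoplitis 14.9x, Lasioglossum 30.0x, Megachile 124.5x, Bombus 1,248x) plus
ten plausible values spanning 2.5-500x for the remaining genera and 50x for
the beetle calibrator. Mean per-sample abundances give the four most
frequently trapped genera (Agapostemon, Bombus, Hylaeus, Lasioglossum) the
highest means (8-15 specimens), with a tail of rarer genera at 1-4;
per-sample counts are negative binomial with size 2, and any taxon absent
from every sample is given one specimen in a random sample so that its
factor stays identifiable. These conditions were fixed once, as a realistic
vane-trap community; they are not tuned per run.

```{r recovery, eval = FALSE}
exp <- factor_recovery_experiment(seed = 1)
exp$comparison      # truth vs recovered, per taxon
autoplot(exp$fit)   # SSE trajectory at the eight checkpoints
```

## The synthetic-data generator

The generator emulates the full study: a 2-management x 4-location x
28-date design (224 community pools, `study_design()`), one taxa pool per
observed morphotaxon (56 with the default community), negative-binomial
per-trap abundances summed over pooled traps, reference sequences of 507 bp
grown so nearest-neighbour divergence sits near a configurable minimum
(9 nt for the discriminating-locus mode, <= 1 nt for the collapsing-locus
mode), multinomial reads from the forward model, i.i.d. substitution
errors with constant-quality Phred+33 strings
($Q = \mathrm{round}(-10\log_{10} p)$, capped to $[2, 40]$ — the simplest
model consistent with the expected-error filter), per-specimen
tissue-degradation dropout, and a two-leg calibrator spike-in. Reads are
emitted merged and chimera-free.

What it deliberately does not emulate: PCR-cycle bias and chimera formation,
indels and quality-varying error profiles, primer-site variation, and
morphological misidentification. Passing tests on this generator therefore
demonstrate the correctness of the algorithms under the stated model, not
robustness to every artefact of real libraries; with degraded field
material the calibration step still depends on fresh, unbiased tissue.

The per-trap abundance distribution is not constrained by any published
parameter, so the generator exposes mean and dispersion as free
configuration with the defaults above.

## Community analytics

Richness is presence-based per sample (calibrator and tally columns
excluded), so it can be computed identically from specimen tables and
read-count tables; their Pearson correlation summarizes qualitative
agreement. Sample-based rarefaction uses the exact hypergeometric
interpolation

$$S(t) = S_{obs} - \sum_i \binom{T - T_i}{t} \Big/ \binom{T}{t},$$

which equals the mean richness over all $\binom{T}{t}$ subsets of sampling
units (asserted against exhaustive enumeration for small $T$, and against an
independent exact implementation), and extrapolates beyond $T$ with the
Chao2 estimate $\hat Q_0 = \frac{T-1}{T} \frac{Q_1^2}{2 Q_2}$ (with the
standard $Q_1(Q_1-1)/2$ substitution when $Q_2 = 0$). Confidence intervals
are out of scope; the curves are point estimates. Binomial coefficients are
computed on the log scale (`lchoose`) to avoid overflow at large $T$.

PCA ordinates per-sample **relative abundances** (row-normalized counts),
centered and unscaled. The transformation is a package choice: relative
abundance removes depth/effort differences between pools and is standard
for compositional community data; raw counts remain available via
`relative = FALSE`. Group structure is displayed as the minimum convex
polygon of each group's scores on the first two components. All-zero
samples (failed pools) are dropped from the ordination with a warning
rather than an error, since a season's data can legitimately contain one.
Inferential models of abundance and richness (GLMMs) are out of scope;
`community_summary()` provides descriptive means with normal-approximation
confidence intervals per location and management.

## Numerical and degenerate-case choices

* GA fitness for a whole population is scored with three matrix products
  (an algebraic expansion of the per-genome SSE, asserted equal to the
  scalar objective in the tests); only mutated duplicates are rescored.
* Seeds: every stochastic function takes an explicit seed and leaves the
  global RNG untouched (`withr::with_seed`);
  `factor_recovery_experiment(seed = s)` uses `s` for the simulation and
  `s + 1` for the optimizer.
* Reference generation rejection-samples up to 1,000 attempts per sequence
  and then raises an infeasible-configuration error.
* A sample whose surviving specimen mass is zero yields an empty or
  all-calibrator read batch, not an error; a calibration sample with zero
  mapped-plus-calibrator reads *is* an error, since its proportions are
  undefined.
* Identity ties are resolved by tallying, never by picking a reference;
  tie detection uses a 1e-9 tolerance on identity.
* Problem sizes in the shipped tests: rarefaction oracles enumerate
  subsets at $T \le 5$; read simulations use up to $10^5$ reads; the
  recovery experiment runs population 1,000 for $10^5$ iterations and the
  small three-taxon variant population 200 for $10^5$ iterations — the
  sizes at which noiseless recovery is comfortably inside the asserted
  tolerances on one CPU.

## Limitations

Correction factors are estimated at genus level from concordant samples
only; they absorb every taxon-specific multiplicative bias (copy number,
ploidy, cell count, extraction efficiency) into one number and cannot
separate those causes. Factors estimated from degraded tissue will fold
degradation into the factor. The GA provides point estimates without
uncertainty; resampling the calibration samples is the pragmatic route to
intervals if needed.
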