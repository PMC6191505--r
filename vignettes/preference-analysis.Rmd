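---
title: "Quantifying host-symbiont preferences with permutation nulls"
author: "sympref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying host-symbiont preferences with permutation nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sympref)
```

## The problem

Root-associated symbiont surveys (here: ectomycorrhizal fungi on their host
trees, profiled by amplicon sequencing of root-tip samples) produce a
sample-by-OTU read-count table together with the host species of every
sample. The scientific question is whether hosts *prefer* particular
symbionts — and symbionts particular hosts — beyond what random assortment
of samples would produce. `sympref` implements that analysis as a tested,
reusable pipeline: incidence-matrix construction, specialization indices,
and shuffle-label permutation inference, plus a synthetic-community
generator so that every stage can be verified against known ground truth.

## From reads to the bipartite incidence matrix

1. **Rarefaction** (`rarefy_counts()`). Each sample is subsampled without
   replacement to a common depth (default 1,073 reads, the regime of the
   motivating survey); samples whose totals fall below the depth are dropped
   and logged. Each sample draws from its own RNG substream derived from
   `(seed, sample_id)`, so results do not depend on the order of samples in
   the file. A single rule — below-depth samples are dropped — is applied;
   there is no separate pre-filter threshold.
2. **Binarization** (`binarize()`). Read counts become presence/absence;
   within-sample abundances are not comparable enough across taxa to carry
   weight.
3. **Aggregation** (`aggregate_to_species()`). The host-species × OTU matrix
   `a` has `a[i, j]` = number of samples of host `i` containing OTU `j`.
   All-zero rows and columns are removed (they are undefined for the
   indices) with a warning.

Per-OTU results are *reported* only for abundant OTUs
(`filter_abundant_otus()`, strict `> 2000` total reads by default, applied
to post-rarefaction totals unless configured otherwise): host preferences of
rare symbionts cannot be estimated reliably. The filter never restricts
matrix construction.

## Specialization indices

All logarithms are natural.

**Per-species d′.** For row `i` with interactions `a_ij`, row total `A_i`,
column totals `A_j` and grand total `m`, the Kullback–Leibler specialization
is

$$d_i = \sum_j p'_{ij} \ln\frac{p'_{ij}}{q_j}, \qquad
p'_{ij} = a_{ij}/A_i, \quad q_j = A_j/m,$$

normalized as `d′ = (d − d_min) / (d_max − d_min)` where `d_min` and
`d_max` are the extreme values achievable by *integer* reallocations of
`A_i` over the partners given the observed totals. Column totals retain the
focal row's contribution, the convention of the index's reference
implementation.

Unlike the usual greedy heuristics, both extremes are computed **exactly**:

* `d` is convex on the integral polytope
  `{0 ≤ x_j ≤ A_j, Σ x_j = A_i}`, so its maximum sits at a vertex, where
  every coordinate is 0 or at its cap except at most one. Each saturated
  column contributes `ln(m/A_i)` per unit, which collapses the search to a
  subset-sum problem over column totals, solved by a bitset dynamic
  program plus a scan over candidate partial columns. (The seemingly
  natural greedy — fill partners in ascending order of availability — is
  *not* optimal: with column totals (2, 4) and a row total of 3 it yields
  0.231 where the true maximum `ln 1.5 ≈ 0.405` is attained by placing all
  three units on the larger column.)
* `d_min` starts from largest-remainder rounding of the proportional
  allocation `A_i · q` and applies single-unit exchange repair; for a
  separable convex objective on this polytope, exchange-local optimality
  implies the global minimum, so the repaired allocation is exact.

Both are validated against exhaustive enumeration over every marginal class
with row/column sums ≤ 6 and shapes up to 3×3 (5,500+ classes) in the test
suite. If a single partner is available, `d_max = d_min` and `d′` is defined
as 0 (with a warning). Bound violations beyond an absolute tolerance of
1e-9 raise an internal error rather than being clamped.

**Network-level H2′** (`h2_prime()`). The two-dimensional entropy
`H2 = −Σ (a_ij/m) ln(a_ij/m)` is normalized between the extremal entropies
achievable under the observed marginals:
`H2′ = (H2_max − H2) / (H2_max − H2_min)`. For matrices up to 4×4 (totals
≤ 48) both extremes are exact, via a dynamic program over columns whose
state is the vector of remaining row marginals. Larger matrices use the
standard heuristics — largest-remainder rounding of the independence table
`A_i A_j / m` for the maximum, a largest-remaining-marginal greedy packing
for the minimum, both refined by steepest 2×2 exchange repair when the
matrix has at most 100 cells — and the observed matrix itself is always
admitted as a feasible bound candidate, which guarantees
`H2_min ≤ H2 ≤ H2_max` and hence `H2′ ∈ [0, 1]` without clamping. The
heuristic fills are the one place where exactness is traded for run time on
large matrices; they are enumeration-exact on the small family covered by
the tests.

**Checkerboard C-score** (`c_score()`). For each pair of species `(u, v)`
of one guild of the binarized matrix, with partner counts `r` and shared
partners `S_uv`,

$$C_{uv} = \frac{(r_u - S_{uv})(r_v - S_{uv})}{r_u\, r_v} \in [0, 1],$$

and the guild score is the mean over all distinct pairs: 1 means perfect
segregation, 0 complete co-occurrence. The per-pair `r_u r_v`
normalization is the default because it keeps guild scores in [0, 1]; the
unnormalized Stone–Roberts mean is available behind a flag.

## The shuffle-label null and the effect sizes

The only null model used is the **shuffle-sample null**
(`shuffle_host_labels()`): host labels are permuted across samples, which
preserves every sample's OTU content and every host's sample count, and
destroys only the sample-to-host association. Notable invariants follow:
the species-matrix column totals and grand total do not change under the
null, which the implementation exploits by caching the d′ extremal bounds
by row total.

For each statistic `T` the pipeline reports:

* the standardized score `(T_obs − mean(T_null)) / sd(T_null)` with the
  sample (n−1) standard deviation — this is the *standardized d′* for
  species and, applied to the per-pair sample counts `N(i, j)`, the
  two-dimensional preference *2DP*;
* an add-one permutation p-value
  `p = (1 + #{T_null ≥ T_obs}) / (1 + n_perm)`, upper-tailed by default
  (preference and segregation mean "observed above the null"); lower and
  two-sided variants are available. The add-one form is valid and
  conservative, and ties count toward the tail.
* Benjamini–Hochberg q-values, adjusted separately within each family of
  tests (host species; abundant OTUs; host × OTU pairs), matching the
  convention of adjusting within each analysis.

When the null sd is zero the standardized score is undefined; it is
reported as `NA` with an `sd_zero` flag, never as ±infinity. Pairs with
`2DP > 6` carry a `strong` flag — a descriptive reporting convention, not
an inferential threshold. Defaults are 10,000 permutations for the
preference statistics and 1,000 for the community-level tests. Because the
community-level comparison of a single observed value against its null
draws has historically also been summarized with a t-test, the one-sample
t-statistic of the draws against the observed value is reported alongside
the permutation p; neither is silently preferred.

Every permutation runs on a sub-seed drawn sequentially from the top-level
seed, so increasing `n_perm` extends the draw sequence without reshuffling
earlier draws, and results are reproducible bit for bit. Entities are
aligned across permutations by identifier, never by matrix position; an
entity undefined in a permuted aggregate yields a missing draw, and more
than 5% missing draws aborts with a diagnostic.

## The synthetic generator as ground truth

`generate_community()` draws each sample multinomially (`depth` trials)
from its host's profile

$$p_i = (1 - \theta)\, \text{base} + \theta\, u_i,$$

where `base` is a long-tailed rank-frequency profile (`rank^-1.5`,
renormalized; exponent configurable) and `u_i` is uniform over host `i`'s
preferred OTUs (disjoint blocks of 5 by default; block overlap between
consecutive hosts is configurable to emulate related hosts sharing
symbionts). The mixture parameterization was chosen over a
Dirichlet-concentration one because `θ` is directly interpretable and
`θ = 0` is an *exact* exchangeable null — the calibration suites rely on
that. Preferred blocks are carved from the **rare tail** of the base
profile: host-specific symbionts are modeled as taxa outside the shared
background pool. Blocks drawn from the ubiquitous core would be invisible
to presence/absence statistics (base reads alone put those OTUs in
essentially every sample), making `θ` unidentifiable — a structural
property of incidence data worth remembering when interpreting real
surveys, too.

Defaults (61 hosts × 5 samples, 2,000 OTUs, 1,073 reads per sample,
`θ = 0.3`) mirror the data regime of the motivating survey, including its
long-tailed OTU frequency distribution with most OTUs in ≤ 10 samples.
What the generator does *not* emulate: sequencing error, chimeras, PCR and
copy-number bias, spatial and environmental structure, and phylogenetic
signal in the base profiles (host profiles are exchangeable given θ). A
passing calibration or recovery test therefore shows the *statistics*
behave correctly under the stated sampling model, not that real surveys are
free of those additional effects.

## Numerical and design choices

* Logarithms in nats throughout; `0 · ln 0 = 0`.
* Greedy and rounding ties broken by input index order — results are
  deterministic.
* Rarefaction subsamples the multiset of reads without replacement
  (`rep`/`sample`/`tabulate`), matching the behavior of the classic
  `sub.sample` tools.
* The d′/H2′ extremal-bound tolerance is 1e-9 absolute; violations are
  internal errors, not clamped values.
* All randomness flows from a single seed per entry point; library code
  saves and restores the caller's RNG state.
* FDR families (hosts, OTUs, pairs) are adjusted separately.
* Degenerate inputs: single-column matrices give `d′ = 0` with a warning;
  1×1 matrices give `H2′ = 0` with a warning; guilds with fewer than two
  species with partners are an error for the C-score.

## Problem sizes used by the test and acceptance suites

Calibration and power checks run on 20 hosts × 5 samples × 200 OTUs at
depth 500 (50 exchangeable replicates; four specialization strengths ×
20 seeds with 1,000 preference and 250 network permutations) — sizes at
which the full suite completes comfortably on a single CPU while leaving
the Monte Carlo bounds meaningful. The enumeration oracle sweeps every
marginal class with sums ≤ 6 up to 3×3. The acceptance script runs the
full pipeline once at the generator's default (survey-scale) conditions
with the default 10,000 / 1,000 permutations.

## Known limitations

* H2′ extremal fills are heuristic (though bracketed and oracle-checked)
  beyond 4×4 matrices.
* The C-score normalization is the per-pair `r_u r_v` variant; other
  software sometimes reports the unnormalized mean of checkerboard units
  (exposed here behind `normalized = FALSE`), so cross-package magnitudes
  should be compared with care.
* OTU-level preferences for rare taxa are intentionally not reported;
  the abundance cutoff is a reporting filter with the usual arbitrariness
  of such thresholds (strict `> min_reads`, basis configurable pre/post
  rarefaction).
* The pipeline treats samples as exchangeable under the null; it does not
  stratify permutations by site or any other covariate.
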