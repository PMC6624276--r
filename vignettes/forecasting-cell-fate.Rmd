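---
title: "Quantifying how initial gene expression forecasts single-cell death times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying how initial gene expression forecasts single-cell death times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fateinfo)
```

## The question and the measurement model

When a clonal bacterial population meets a lethal antibiotic, cells die over
a window of one to several hours rather than all at once. Some of that
spread is forecastable: the stochastic expression level a cell happens to
have for certain genes at the moment of exposure correlates with *when* it
will die. `fateinfo` measures this forecasting power from the kind of data a
single-cell time-kill experiment produces: for each cell, an initial
covariate (reporter fluorescence at *t* = 0, initial size, early growth
rate) and a death time scored on a fixed imaging frame grid, with cells
still alive at the end of the movie right-censored.

The analysis makes three structural assumptions:

1. **Binary state.** At each frame a cell is either alive or dead; death is
   absorbing (no resurrection), so per-bin dead fractions are cumulative and
   non-decreasing in time.
2. **Censoring means survival.** A cell never observed to die counts as
   alive at every frame. This is the correct reading of a movie that simply
   ended, and it biases the statistic toward zero rather than away from it.
3. **Only ranks matter.** Cells are compared through equal-frequency bins of
   the covariate, so every result is invariant under strictly monotone
   transforms of the covariate (fluorescence units, background scaling,
   log-transforms).

## The information statistic

With cells ranked and split into *n* equal-count bins (deciles by default),
the statistic at frame *t* is `I(x_t, y) = H(x_t) - H(x_t|y)`, where
`H(x_t)` is the binary entropy (base 2, so all results are in bits) of the
overall dead fraction and `H(x_t|y)` is the **unweighted** mean of the
per-bin binary entropies. Two numerical conventions apply throughout:
`0 * log2(0) = 0`, and frames where the overall dead fraction is exactly 0
or 1 return exactly 0 bits without evaluating per-bin terms.

The unweighted `1/n` average is a deliberate definition, not an
approximation. With equal bin sizes it coincides with the count-weighted
conditional entropy, and hence the whole statistic coincides with plug-in
mutual information from the joint (bin, state) table; `mi_oracle()`
implements that joint-table estimator independently, and the test suite
holds the two equal to within 1e-12 bits across a thousand random
equal-bin configurations. When bin sizes are unequal (cell count not
divisible by the bin count) the two definitions genuinely differ, and
`mi_at_time()` keeps the unweighted form; a unit test documents the
discrepancy on a constructed 2/8 split.

Useful limiting cases, all of which are enforced by tests:

* all cells alive, or all dead: 0 bits;
* every bin with the same dead fraction: 0 bits (fate unrelated to the
  covariate);
* five bins fully dead and five fully alive: exactly 1.0 bit, the binary
  maximum.

**The arc, exactly.** If cells die one per frame in exact covariate-rank
order, the trace touches `H(k/10)` at every frame where `k` whole deciles
have died, rising to exactly 1.0 bit at half-death and falling back
symmetrically. Between those frames the single partially-dead bin
contributes conditional entropy, which carves a small sawtooth into the
ideal entropy arc. The peak is still exactly 1.0 bit at half-death; the
sawtooth is a property of binned information at finite resolution, and the
tests assert the arc at decile resolution rather than frame-by-frame
monotonicity.

**Peak extraction.** `peak_bits` is the maximum over frames; ties are
resolved to the earliest frame, a deterministic convention that matters only
for degenerate traces.

## Binning conventions

`rank_and_bin()` pools replicate positions before binning, sorts by the
covariate with ties broken by the stable order of `cell_id`, and assigns
remainder cells (when N mod n is nonzero) to the lowest-index bins, so bin
sizes differ by at most one. Bin indices are 1-based, bin 1 holding the
lowest covariate values. All of these are arbitrary but fixed conventions
chosen for reproducibility; none of them affects equal-divisible designs
such as 500 cells in 10 bins of 50.

The default of 10 bins suits the ~500-cell scale of a five-position
experiment: enough bins to resolve threshold-shaped links, enough cells per
bin (50) to estimate a dead fraction. `bin_sensitivity()` recomputes the
peak at other bin counts; on simulated data the strong-versus-null ordering
of peaks is stable across 5, 10, and 20 bins, which is the practical sense
in which conclusions should not hinge on the exact bin number.

## The permutation null

The plug-in statistic is biased upward in small samples: even unrelated
groupings yield strictly positive peaks (about 0.02-0.04 bits at 500 cells,
shrinking with N — a tested property). `permutation_test()` therefore
regroups cells into random equal-count bins (keeping each cell's death time
attached), recomputes the full trace, and records its peak, 100 times by
default. Randomization pools all positions, matching the pooled binning.
The observed peak is called significant when it exceeds the empirical 95th
percentile of the null peaks; the percentile is exposed as a parameter
because the choice of threshold is a calibration, not part of the
statistic. The permutation stream is seeded independently of the
simulation, so nulls are reproducible on real data too.

## Killing-time spread and promoter summaries

`decile_spread()` finds each bin's first frame reaching 50% death, smooths
those crossing times across the bin index with a Savitzky-Golay filter, and
reports max minus min of the smoothed values. The filter parameters default
to window 5, polynomial order 2 across the 10 deciles — the smallest window
that actually smooths while following a curved trend across so few points;
both are exposed, window 1 is the identity, and even windows or windows not
exceeding the polynomial order are rejected. Bins that never reach 50%
(heavy censoring) are excluded from the spread with a warning rather than
imputed. Because the filter parameters are conventions, spread values are
comparable within one choice of parameters, not across choices.

`promoter_statistics()` summarizes a reporter by mean fluorescence and
coefficient of variation, using the population (divide-by-N) standard
deviation by default, and `cross_promoter_correlation()` reports both
Pearson and Spearman coefficients of peak information against any
promoter-level scalar, flagging the degenerate constant-input case as `NA`.
Both coefficients are reported because "no appreciable correlation" is a
claim one should be able to check on either scale.

## What the simulator emulates — and what it does not

`simulate_experiment()` reproduces the statistical structure the analysis
relies on: five positions of 100 cells on a 5-min grid over 5 h;
right-skewed (log-normal) initial fluorescence with `fluor_log_sd = 0.4`
(CV about 0.42, a typical magnitude for reporter heterogeneity); killing
centered at 120 min so deaths concentrate in the 1-3 h window; and a
death-time mechanism `center + strength * g(q) + noise` acting on the
fluorescence quantile *q*, with `g` one of the four link shapes. The
default `link_strength = 120` min spreads the deciles' deaths over about
two hours, and `death_time_noise_sd = 30` min keeps the link strong but
noisy; neither value is fitted to any dataset — the empirical per-reporter
noise magnitude is simply not identifiable from published summaries, so
defaults were chosen once for qualitative realism. Growth rate is drawn
around 0.02/min and can couple negatively to death time
(`growth_death_coupling`), emulating slow growers surviving longer; size
couples analogously. The quantile in `g` is the theoretical log-normal CDF
of the drawn fluorescence rather than the empirical pooled rank: this keeps
per-position substreams independent — adding positions never perturbs
earlier cells — while remaining monotone in fluorescence, which is all the
link requires.

The simulator does **not** emulate: lineage structure or division (each
cell is independent), segmentation error, fluorescence measurement noise
(the covariate is observed exactly), position-level batch effects, biphasic
or pharmacodynamic killing kinetics, or resuscitation. Consequently,
passing tests demonstrate that the *analysis* recovers planted structure of
the tested shapes and rejects its absence; they do not certify behavior
under segmentation artifacts or batch structure, which real data may add.

## Problem sizes and reproducibility

The test suite and the acceptance script run the analysis at the study's
own scale — 10 bins, ~500 cells, 100 permutations — with simulation studies
of 20 outer seeds per condition for the signal/null discrimination checks;
these sizes were chosen as the smallest at which the discrimination
properties are stable. Every random quantity is seeded: the simulation seed
fixes every cell field, the permutation seed fixes the null, and re-running
any pipeline step with the same inputs and seeds reproduces output files
byte for byte.

## Known limitations

* The unweighted conditional-entropy average is only a bona fide mutual
  information for equal bin sizes; with remainders it is a closely related
  statistic, kept for fidelity to the decile construction.
* The statistic is binned, not binless: information carried by
  within-decile variation is invisible, and finite-sample bias makes raw
  peak values incomparable across very different cell counts — always read
  them against the permutation null at the same N.
* Censoring is treated as survival to movie end; if censoring were
  informative (e.g., cells leaving the field of view preferentially when
  sick) the statistic would be biased in ways the simulator does not model.
* One covariate at a time: multivariate (multi-reporter) information is out
  of scope.
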