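---
title: "Measuring copy-number heterogeneity from a single bulk profile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring copy-number heterogeneity from a single bulk profile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnh)
```

## The model

Every individual malignant cell has integer chromosomal copy numbers. A
bulk tumour sample, however, averages over millions of cells: wherever
subclones disagree about the copy number of a segment, the population
average lands strictly between integers. Copy-number heterogeneity (CNH)
turns that observation into a score.

A segmented bulk profile reports, for each genomic segment $i$ of width
$w_i$, a relative copy number $r_i$ normalized so that the width-weighted
mean over the genome is 1. If the sample contains a fraction $\alpha$ of
malignant cells (purity) whose genome has absolute copies $q_i$ and
width-weighted mean ploidy

$$\tau = \frac{\sum_i w_i q_i}{\sum_i w_i},$$

while the remaining $1-\alpha$ of cells are diploid, then

$$r_i = \frac{\alpha q_i + 2(1-\alpha)}{\alpha \tau + 2(1-\alpha)}.$$

Inverting this for a candidate $(\alpha, \tau)$ reconstructs candidate
absolute copies $q_i$, whose deviations from the nearest integers,

$$d_i = \lvert q_i - \mathrm{round}(q_i) \rvert,$$

reflect heterogeneity. Purity and ploidy are usually unknown, so the score
is minimized over a grid of biologically relevant candidates:

$$\mathrm{CNH} = \min_{\alpha, \tau}
  \frac{\sum_i d_i\, w_i}{\sum_i w_i},
  \qquad \alpha = 0.20, 0.21, \ldots, 1.00,\quad
  \tau = 1.50, 1.55, \ldots, 5.00.$$

CNH lies in $[0, 0.5]$ and can be read as the width-weighted fraction of
malignant cells that deviate by one copy from the modal karyotype. Note a
useful identity: because the profile is normalized, the width-weighted mean
of the reconstructed $q_i$ equals $\tau$ for *every* grid candidate, so the
ploidy consistency constraint is automatically satisfied and never needs to
be enforced (the fit reports it as `ploidy_residual`, which is always at
rounding error).

```{r}
sim <- simulate_tumour(n_segments = 30, h = 0.08, purity = 0.7, seed = 7)
fit <- cnh(sim$bulk)
coef(fit)
```

## Tunable parameters

* **Grid** (`cnh_grid()`): purity 0.20–1.00 in steps of 0.01, ploidy
  1.50–5.00 in steps of 0.05 (81 × 71 = 5751 candidates). Grid values are
  generated by index (`start + k * step`), not repeated addition, so the
  endpoints are exact. The ranges delimit what is biologically plausible;
  widening the ploidy range mostly adds integer-translation duplicates of
  existing solutions.
* **Known purity or ploidy** (`cnh(..., purity =, purity_window =,
  ploidy =)`): when an independent purity estimate exists, the search is
  restricted to a relative window (default 10%) around it; a known ploidy
  is snapped to the nearest grid value. A restricted minimum is never below
  the unconstrained one.
* **Noise filters**: segments whose standard deviation of the mean
  ($\sigma_\mu = s/\sqrt{n}$ over $n$ probe/bin values, sample standard
  deviation $s$) exceeds 0.01 are dropped (`filter_segments()`), and
  samples whose width-weighted mean $\langle\sigma_\mu\rangle$ exceeds
  0.006 are excluded (`filter_samples()`). Both cuts are the defaults used
  for SNP-array cohorts. Filtering precedes the final normalization, so
  removed segments do not influence the mean the inference divides by.

## The simulator: a stated world

`simulate_tumour()` builds a malignant population with a known input
heterogeneity $h$ and purity $\alpha$:

1. a template of $n$ segments (default widths log-uniform over
   $10^5$–$10^7$ bp, i.e. two decades) with baseline integer copies drawn
   from $\{1,2,3,4\}$, resampled until more than half the genome width is
   non-diploid and at least three distinct copy levels are present —
   emulating the highly altered genomes on which the measure is intended,
   and avoiding two-level profiles whose purity/ploidy are unidentifiable;
2. for each segment, a fraction $f_i \sim \mathrm{Uniform}(0, 2h)$ of
   cells (so $\mathbb{E}[f_i] = h$) gains or loses one copy; by default all
   altered cells of a segment share one direction, so the bulk mean shifts
   by $f_i \cdot \mathrm{dir}_i$. The alternative per-cell independent
   scheme keeps single-cell heterogeneity but cancels in the bulk mean — it
   is retained behind a flag for sensitivity analysis because a bulk-based
   measure cannot, by construction, see it;
3. $h$ is capped at 0.25 so that $f_i < 0.5$ almost surely and the bulk
   deviation from the nearest integer equals $f_i$ exactly (observed CNH in
   real cohorts stays well below this cap);
4. the population is diluted with diploid cells to purity $\alpha$ and the
   width-weighted profile is normalized. The default "analytic" mode takes
   the population expectation directly — equivalent to the ~$10^9$-cell
   populations the measure targets, with no sampling noise; finite
   `n_cells` draws binomial alteration counts and converges at
   $O(1/\sqrt{n_\mathrm{cells}})$.

What the simulator does *not* emulate: segmentation errors, GC and
mappability artefacts, read-count noise (a Gaussian segment-level term is
available as a crude stand-in), whole-genome doubling, or selection over
time. A green recovery test therefore establishes that the *inference* is
sound given a correct segmentation, not that any upstream pipeline is.

## Single-cell and multi-region estimators

With per-cell absolute karyotypes, heterogeneity needs no inference:
`harmonize_breakpoints()` finds the minimal segment set refining every
unit's breakpoints on the jointly covered territory, and `direct_cnh()`
reports the width-weighted fraction of cells differing from the modal
integer copy per segment. For multi-region bulk data the same estimator is
applied to rounded copies (`multiregion_cnh()`). `quasi_bulk()` pools cells
with equal weight into a bulk-like profile, connecting the direct estimate
to the grid inference — on simulated populations the two rank samples
nearly identically.

## Numerical choices

* **Rounding**: nearest integer with exact halves away from zero,
  everywhere an integer is needed (reconstructed copies, region rounding).
  At a half-integer the distance is 0.5 under any convention, so the choice
  is score-neutral, but one fixed rule keeps reported copies reproducible.
* **Ties**: all grid points within $10^{-12}$ of the minimum are kept in
  the fit (`$ties`); the reported argmin is the smallest ploidy, then the
  smallest purity. Multiple (purity, ploidy) pairs fitting equally well is
  expected — integer translations of the profile — and CNH is essentially
  identical across them.
* **Modal ties** (single-cell/multi-region): broken to the smaller
  integer.
* **Negative reconstructions**: a poor candidate can map a segment to a
  negative copy number; it is scored as-is (distance to the nearest
  integer, possibly ≤ 0) since the minimization disfavours such fits
  anyway.
* **Degenerate inputs**: single-segment or constant profiles are processed
  (some grid point always reaches 0) but warned about; the measure is
  genome-wide by design and should not be applied to single segments.
* **Ploidy-shift companions**: writing the reconstruction as
  $q = r(\tau + \beta) - \beta$ with $\beta = 2/\alpha - 2$, an exact
  integer translation $q \to q + s$ needs $\tau' = \tau + s$ and
  $\beta' = \beta - s$, i.e. $\alpha' = 2\alpha / (2 - s\alpha)$. The
  commonly quoted linear adjustment
  $\alpha' = -2/\tau' + \alpha + 2/\tau$ approximates this (they coincide
  when $\alpha = 2/\tau$); `shifted_solution()` returns both, and flags a
  shift valid only when the *exact* purity lies in the searched range —
  with the approximate value, shifts can be labelled valid although no
  equivalent grid solution exists, and the apparent invariance breaks by
  an order of magnitude.

## Known limitations

The minimum over 5751 candidates is a *biased* estimator of the true mean
integer distance, in two regimes quantified by the package's own tests:

* **Grid-resolution floor at low heterogeneity.** A homogeneous population
  gives CNH exactly 0 only when an exact solution lies on the grid (e.g.
  purity 1 with an on-grid true ploidy). Otherwise the nearest grid
  candidate leaves a floor that grows as purity falls (the mixture
  intercept $2/\alpha - 2$ changes by $\approx 2\,\delta\alpha/\alpha^2$
  per purity step): about 0.004 at purity 1, about 0.013 at purity 0.2 for
  30-segment profiles.
* **Selection bias at high heterogeneity.** When many segments sit far
  from integers, some of the thousands of candidates fit the fractional
  parts better than the truth by chance, and the minimum undershoots: with
  30-segment templates the mean shortfall is ≈ 0.013 at $h = 0.1$, ≈ 0.03
  at $h = 0.15$ and ≈ 0.06 at $h = 0.2$, shrinking with segment count but
  persisting (≈ 0.01 at $h = 0.2$ even with 400 segments). Two
  consequences follow: a purity-constrained fit (which excludes remote
  spurious minima) can exceed the unconstrained score by the same margin
  at high $h$, and absolute CNH values in the upper range should be read
  comparatively rather than as unbiased estimates of the deviating cell
  fraction. Rank order — what survival and cohort comparisons use — is
  essentially unaffected, and purity independence holds throughout (the
  spread of mean CNH across purities 0.2–1 stays below 0.02 at every
  tested $h$).

Sex chromosomes are kept by default (`drop_sex = TRUE` to exclude);
allele-specific input is out of scope.
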