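---
title: "Window-centred binning for imputing gaps in wearable heart-rate data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-centred binning for imputing gaps in wearable heart-rate data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binimpute)
```

## The problem

Minute-level heart-rate series from wrist trackers drop out in contiguous
stretches — a charging break, a sync failure, a removed watch. Because most
people keep daily routines, the same clock minute on *other* days carries a
lot of information about the missing stretch. `binimpute` studies a simple
idea: instead of training an imputation model on the whole 24-h × 30-day
record, train it only on a minute-of-day window (a *bin*) centred on the
gap, and ask when that helps.

The package arranges data as a **day matrix**: rows are days, columns are
minutes of day (0–1439), missing values are `NA`. In this orientation
cross-day routine appears as inter-feature correlation, and binning is
column subsetting — it changes the feature space an imputer sees, which is
exactly the intervention under study.

## The evaluation design

1. **Masking.** A contiguous window (15 min or 1 h, at 3–4 am or 3–4 pm) is
   deliberately removed from *one* day at a time; the removed values are
   retained, outside the matrix, as ground truth (`apply_gap()`).
   Masking one day at a time (leave-one-day-out) rather than all days at
   once is forced by the design itself: with the smallest bin — exactly the
   gap window — simultaneous masking would leave no observed value in the
   bin at all, and nothing could be imputed. A `mask_mode = "simultaneous"`
   option exists for wider bins.
2. **Binning.** A bin of size 15 min … 6 h is centred on the gap
   (`bin_bounds()`): the padding splits as evenly as integers allow, with
   the odd minute placed after the gap. Bins never wrap across midnight —
   every window in the study fits inside a day — so a window crossing the
   day boundary raises an error rather than being silently clamped. The
   token `"total"` denotes the whole 1440-minute day.
3. **Imputation.** Five algorithms, all implemented in this package,
   complete the binned matrix (below).
4. **Scoring.** Root mean square error over the removed cells
   (`imputation_rmse()`); per method, the **success rate** is the fraction
   of days whose RMSE at the smallest admissible bin is *strictly* lower
   than at `"total"` (ties count as failures); per day, the **optimal bin**
   minimises the five methods' summed RMSE, ties breaking toward the
   smallest bin.

`run_experiment()` executes the full frame × day × bin × method factorial
and emits one record per cell; all randomness flows from a single seed, so
records are byte-reproducible.

## The five imputers

All imputers receive a day matrix with `NA` cells, leave observed cells
bitwise untouched, and return a complete matrix.

**SI — per-minute mean.** Each missing cell takes the mean of its column's
observed values (grand mean if the column is empty). Note a structural
consequence of the design: under leave-one-day-out masking the donors of a
minute column are the same 29 days whether or not the matrix was binned
first, so SI's imputations — and hence its RMSE — are *identical across
all bin sizes*. Its strict-inequality success rate is zero by
construction. This is not a bug; it is what a per-column mean imputer does
in this orientation.

**EM — multivariate-normal conditional mean.** Missing coordinates of a row
are replaced by \(\mu_m + \Sigma_{mo}\Sigma_{oo}^{-1}(x_o - \mu_o)\) under
an estimated mean and ridge-regularised covariance
(\(\Sigma + \lambda I\), \(\lambda = \texttt{ridge}\cdot\overline{\sigma^2}\)).
When at least two fully observed rows exist, the moments are estimated from
them (classical regression imputation); they are then exact and the
algorithm converges in one effective step. The textbook alternative —
re-estimating moments from the *completed* matrix, imputed rows included —
has a degenerate fixed point that matters here: once a row retains
\(n-1\) or more observed coordinates, its observed residual lies exactly in
the centred row space, the conditional mean reproduces the row's own
current fill to within \(O(\lambda)\), and the iteration never leaves its
initialisation (we verified this against a dense solve; the offsets are
\(\sim10^{-7}\) at the default ridge). The completed-matrix scheme is
therefore only the fallback for scattered missingness with no complete
rows. Since the regularised covariance is a rank-\((n-1)\) matrix plus
\(\lambda I\), the conditional mean is evaluated through the Woodbury
identity with an \(n \times n\) solve whenever observed coordinates
outnumber rows, so the \(p \gg n\) whole-day regime (1440 columns, 30
rows) is exact and fast; no feature truncation is needed.

**II — iterative ridge regression.** Initialise with column means; cycle
over incomplete columns (ascending missing count), regressing each on all
other columns with ridge \(\lambda\) on the rows where it was observed, and
overwrite its missing cells with predictions; repeat until the largest
change falls below `tol` × the mean absolute observed value. Ridge rather
than plain least squares because bins make \(p \approx n\); as
`ridge -> 0` the fit recovers ordinary least squares on well-posed data
(tested). When columns outnumber training rows the coefficients come from
the equivalent dual (kernel) solve; when every incomplete column trains on
exactly the fully observed rows, the centred donor Gram matrix is shared
across columns and each column's system is that Gram minus a rank-one
term, which is what makes whole-day runs cheap.

**kNN — missing-aware nearest neighbours.** Distances between rows are
Euclidean over coordinates observed in both rows, rescaled by
\(\sqrt{p/n_{\text{shared}}}\); donors for a cell are rows observing that
column, ranked by distance (no-overlap rows rank last; ties break toward
the lower row index); the imputed value is the unweighted mean of the
`min(k, available)` nearest donors, with a simple-imputer fallback when no
donor exists. The implementation is checked cell-for-cell against an
exhaustive double-loop oracle.

**RF — iterative random forest (missForest scheme).** Initialise with
column means; per pass, train a random-forest regressor of each incomplete
column on all others (rows where the column was observed) and predict its
missing cells; stop when the relative change statistic
\(\sum(\text{new}-\text{old})^2/\sum\text{new}^2\) first increases,
returning the previous pass, or at `max_iter`. The forest is built from
first principles in compiled code: 100 bagged trees, \(\lceil p/3\rceil\)
candidate features per split, variance-reduction splits, minimum leaf of 5
bootstrap samples, and a dedicated splitmix64 generator so a seed fixes
the output bitwise on any platform. Two exact shortcuts keep the factorial
tractable: a column whose training rows are all fully observed has a
pass-invariant forest (its training data can never change), so it is
trained once; and a pass with change statistic exactly zero is a fixed
point whose values no later pass can alter, so iteration stops there.

## The synthetic study data

Device recordings are personal data and are not shipped; the package
instead generates days with the statistical structure that binning
exploits (`generate_days()`):

\[ x(d, m) = \text{baseline} + \text{circadian}(m) + \text{activity}(d, m)
   + \delta_d + \varepsilon(d, m) \]

* a 24-h sinusoid (amplitude 10 bpm around a 62 bpm baseline) with its
  trough centred in the sleep window (01:00–07:00) — a single sinusoid
  rather than a fitted spline, because the binning question only needs
  trough/peak structure and a closed form keeps Monte-Carlo checks
  analytic;
* a 25 bpm activity boost on an afternoon window (14:00–18:00) that
  shifts by an integer uniform on ±10 min each day, so the "active" frame
  is genuinely harder than the "inactive" one;
* a day-level random effect \(\delta_d \sim N(0, 2^2)\);
* minute-level AR(1) noise with lag-1 correlation 0.7 and innovations
  scaled so the marginal sd stays 3 bpm regardless of the correlation,
  keeping configurations comparable;
* step counts: exactly 0 throughout the sleep window (the operational
  definition of "inactive"), Poisson(40) in the active window, Poisson(2)
  elsewhere.

`generate_sample_stream()` emits the same model at device cadence (12
five-second samples per minute with optional within-minute jitter), so the
resampling path is testable end to end.

**What the generator does and does not emulate.** It reproduces routine
(cross-day similarity at a fixed minute), within-day nonstationarity, and
autocorrelated noise. It does *not* reproduce two features of real tracker
data that turn out to matter for the binning question: nonstationary
routines (a person's afternoon state is largely uninformative about their
3 am heart rate; here the day effect \(\delta_d\) is global by
construction) and heteroscedastic, activity-driven noise. A consequence,
measured by `scripts/acceptance.R` and the end-to-end tests: on this
synthetic model the whole-day matrix lets the linear imputers estimate
\(\delta_d\) from the masked day's ~1380 observed minutes, so EM and II
often do *better* with `"total"` than with the smallest bin, and the
modal optimal bin is `"total"`. The binning advantage reported for real
wearable data therefore should not be expected to reproduce under this
generator with a conditional-mean EM — passing the pipeline's tests shows
the machinery is correct, not that binning wins on all data-generating
processes. (A further, implementation-level point: EM imputers that draw
stochastic values around column moments rather than computing conditional
means degrade badly on whole-day data, which plausibly inflates reported
binning advantages; this package's EM is deliberately the deterministic
conditional-mean variant, which is the stronger baseline.)

## Numerical choices

* Minute buckets are half-open `[m:00, m+1:00)`; duplicate device
  timestamps are averaged (trackers retransmit).
* Missing markers are `NA` throughout; matrix CSVs write them as empty
  cells and round-trip losslessly at 17 significant digits.
* Convergence scales for EM/II are unit-free: `tol` multiplies the mean
  absolute observed value, so defaults behave the same across bpm ranges.
* Defaults: `k = 5`, `max_iter = 100/10/10` (EM/II/RF), `tol = 1e-4/1e-3`
  (EM/II), `ridge = 1e-6` (relative), `n_trees = 100`, minimum leaf 5 —
  the documented defaults of the software families these methods come
  from; none were fitted to any outcome.
* Ties: kNN donor ties break toward the lower row index; the optimal-bin
  argmin breaks toward the smallest bin; success-rate ties count as
  failures (strict reduction only).
* Degenerate inputs: an all-missing matrix, a gap window that is already
  fully missing, and a bin crossing midnight raise errors; a fully missing
  column falls back to the grand mean; `ridge = 0` on rank-deficient data
  raises an error advising a positive ridge.

## Problem sizes

The shipped evaluation uses the study's own sizes: 30 days, four gap
frames, the bin ladder 15/30/45/60/120/…/360 min plus `"total"`, five
methods — 5100 records per seed, about four minutes on one core, most of
it spent training random forests on the 1439-feature whole-day matrix.
The test suite repeats this over seeds 1–5 for the end-to-end checks and
uses smaller matrices (8 × 6 up to 30 × 1440) everywhere else.

## A worked example

```{r example, eval = FALSE}
hr <- generate_days(synth_config(seed = 1))$hr      # 30 synthetic days
ex <- apply_gap(hr, gap_spec(900, 60, target_day = 2))   # mask 3-4 pm, day 2
sub <- extract_bin(ex$masked, bin_bounds(900, 60, 120))  # 2-h centred bin
fit <- impute(sub, imputer_config("EM"))
imputation_rmse(ex$truth, fit$imputed)              # error in beats/min
```

## Known limitations

* Bins do not wrap across midnight; gaps near 00:00 or 24:00 with wide
  bins are rejected rather than spliced across calendar days.
* Single imputation only: no between-imputation variance, no multiple
  imputation.
* The success-rate and optimal-bin statistics are defined operationally
  (strict reduction vs `"total"`; argmin of the summed RMSE) and make no
  attempt to reconcile ambiguities in how such statistics are sometimes
  reported.
* No smoothing/cleaning filter is applied during minute resampling; the
  hook is the place to add one if a device needs it.
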