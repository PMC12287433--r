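---
title: "Methods: spectral features, classification and evaluation in myospect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral features, classification and evaluation in myospect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Directed differentiation of human induced pluripotent stem cells (hiPSCs)
into muscle stem cells takes roughly 80 days, and its efficiency — the
percentage of MYF5-reporter-positive cells measured by flow cytometry at
the end of the protocol — varies strongly between wells even within one
batch. A non-destructive readout that predicts, around days 24–38, which
wells will end high (MYF5+% > 20) or low (< 10) lets a production
process discard failing wells early and concentrate resources on good
ones.

`myospect` implements such a prediction pipeline for label-free
phase-contrast images, together with a synthetic plate generator so that
the whole loop can be exercised, tested and benchmarked without access
to proprietary microscope data.

## The feature: shell-integrated FFT power

Phase-contrast frames of differentiating cultures differ between
eventual high- and low-efficiency wells mainly in *texture*: denser
cultures and elongating myotube-like cells add fine, oriented structure.
Orientation is arbitrary, so the feature must be rotation invariant.

For an $H \times W$ image $x$ the package computes the discrete Fourier
power spectrum $P(u, v) = |\mathcal{F}x(u, v)|^2$ and sums it over 100
concentric annuli ("shells") of the dimensionless frequency radius

$$ r(u, v) = \sqrt{(u/H)^2 + (v/W)^2}, $$

with $u, v$ the signed frequency indices. Shell $k$ of $n = 100$ covers
$r \in ((k-1)R/n,\; kR/n]$ with $R = 0.5$, the inscribed Nyquist radius.
The DC bin carries only mean brightness and is excluded; corner bins
with $r > R$ exist only for some directions and are discarded so that
the profile is genuinely rotation-comparable. The shell sums are divided
by the total retained power.

Consequences, each covered by a test:

* **Rotation invariance** — right-angle rotations permute frequency bins
  at a fixed radius, so profiles agree to numerical precision; arbitrary
  rotations agree up to resampling error.
* **Translation invariance** — the power spectrum drops phase, so
  circular shifts change nothing.
* **Brightness invariance** — a constant offset only moves the excluded
  DC term.
* **Normalization** — components are non-negative and sum to 1 whenever
  an image has any non-DC power; a constant frame maps to the all-zero
  vector.
* **Parseval accounting** — total power equals $HW \sum x^2$, and
  non-DC power equals $HW$ times the pixel sum of squares about the
  mean, which pins down the transform scaling.

The scalar **high-frequency intensity** is the summed weight of shells
above a cutoff (default 30, i.e. shells 31–100, reading "above the
30th" as strictly above with 1-based indexing). Under the normalization
it lies in $[0, 1]$; with the uniform profile $0.01$ per shell it equals
exactly $0.70$. It proxies cell density and fine texture.

Two points the underlying procedure leaves open were settled as package
design choices:

* *Where normalization happens.* Dividing the spectrum before shell
  integration and dividing the profile after are equivalent under
  sum-then-divide; the package divides the shell sums by total retained
  power, making features exposure- and scale-invariant.
* *Windowing and log transforms.* Neither is applied by default — a
  Hann window (`window = TRUE`) trades spectral leakage against the
  exact shift/brightness invariances, and `log_power = TRUE` compresses
  dynamic range; both are exposed as flags and default off.

The cycles-per-pixel radius makes profiles comparable across image
sizes at fixed magnification — a smaller frame behaves as a sensor crop
of the same field. The synthetic generator follows the same convention
(object pixel sizes are resolution independent; expected counts scale
with frame area).

## The synthetic plate generator

The generator emulates the hierarchical structure of a differentiation
imaging campaign: `n_wells` wells split over `n_experiments` batches,
imaged on `acquisition_days` at `positions_per_well` positions. The
default design — 34 wells, eight days from 14 to 38, 21 positions —
yields $34 \times 8 \times 21 = 5{,}712$ images, 714 per day. Five of
the eight imaging days (14, 24, 31, 34, 38) are fixed by the emulated
campaign; the remaining three default to {17, 21, 28}, a plausible
twice-weekly cadence, and are configurable.

Per-well outcomes are drawn from a three-stratum mixture — low (< 10),
middle (10–20), high (> 20), uniform within stratum, capped at the
protocol's observed ceiling of 31 — with default weights 0.3/0.4/0.3 so
that all strata appear in a 34-well campaign. Whenever at least six
wells are drawn, every positively weighted stratum is guaranteed at
least one well.

Each frame contains a Poisson number of cell-like objects with
expectation

$$ \lambda(\text{myf5}, d) = \Big(\beta_0 + \beta_d f(d) +
   \beta_{md} f(d)\,\text{myf5}\Big) \cdot \frac{HW}{512^2}, \qquad
   f(d) = \frac{d - 14}{38 - 14} \in [0, 1], $$

with defaults $\beta_0 = 60$, $\beta_d = 90$, $\beta_{md} = 9$ per
$512^2$ frame: density grows with day, and at later days efficient
wells are visibly denser — the qualitative phenotype the features are
designed to exploit. Objects are anti-aliased dark ellipses with a
bright phase-halo rim (the standard appearance of adherent cells in
low-magnification phase contrast); their aspect ratio grows from round
at day 14 toward elongated at day 38, more so in efficient wells
(gains 2 with day and 1 with myf5/31). Median semi-minor axis is 4 px
(log-normal, $\sigma_{\log} = 0.25$), body contrast 45 ± 10 gray
levels, halo 30. A linear illumination field (amplitude 20 gray levels,
random direction) supplies the low-frequency background, and Gaussian
camera noise (SD 2) is added before 8-bit quantization. These levels
were chosen once to mimic what a fixed-exposure 4x phase-contrast
image of a differentiating culture looks like: a smooth bright-ish
background dominated by illumination structure, cells contributing the
mid/high-frequency content, and read noise small relative to both.

Determinism is strict: every image derives its own sub-seed from the
plate seed and its (well, day, position) coordinates, so any subset of
the plate can be re-rendered bit-identically and the caller's RNG
stream is never touched.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: optical point-spread functions and
defocus, confluency-dependent contact topology (objects are placed
independently and may overlap), debris and edge artifacts,
batch-to-batch imaging drift, and any biological correlation structure
beyond the density/elongation link. Performance numbers on synthetic
plates characterize the pipeline's mechanics, not expected performance
on real cultures.

## Classification

Images inherit the binary label of their well: Task 1 is positive when
MYF5+% < 10 (defective wells, to be excluded), Task 2 when > 20
(high-quality wells, to be retained); both inequalities are strict, so
boundary scores are negative.

The 100 shell features are reduced before classification: constant
columns are removed (the mask is stored and re-applied verbatim to
unseen rows), features are centered, the first 10 principal axes are
fitted, and one PLS-DA discriminant axis is fitted on the PC scores
against the labels. With two classes and one component, PLS-DA has the
closed form $w \propto S^\top(y - \bar y)$ on the centered score matrix
$S$ — the direction maximizing covariance between projected scores and
labels; the tests verify this variationally against random directions.
The design concatenates the 10 PC scores with the single discriminant
score (11 columns). The description of the original design — "a linear
combination of" the PCA and PLS components — is read as column
concatenation; an actual weighted collapse into one score is neither
specified anywhere nor implemented.

A random forest (100 trees, unlimited depth, $\lfloor\sqrt{p}\rfloor$
variables per split, fixed seed; all exposed) maps the design to
positive-class scores in $[0, 1]$; binary decisions use a configurable
threshold, default 0.5, with the tie at exactly the threshold going to
the positive class. These are conventional defaults; the package's
performance claims are property-based (signal recovered, null at
chance), not tied to specific hyperparameter values.

Two leakage decisions are deliberately conservative: the
reduction (mask, centers, axes) is refitted inside every training fold
rather than once globally, and centering-only (no unit-variance
scaling) is the default because shell features already share a
normalized scale; `scale = TRUE` is available.

## Evaluation protocol

Cross-validation is grouped **by well**: the distinct wells are
shuffled and split into 4 folds whose sizes differ by at most one (34
wells give 9/9/8/8), and all images of a well share its fold — the
classifier is never tested on images of a well it trained on. The
4-fold pass is repeated 50 times (defaults) with fresh partitions; each
repeat contributes the mean of its fold AUCs ("average AUC"), and the
distribution of these averages is the per-day summary. A fold whose
held-out images are single-class has no defined AUC; it is skipped with
a warning and excluded from that repeat's mean — with small strata this
is expected behavior, not an error.

AUC is computed through the Mann–Whitney identity (midranks, ties
half-weighted) and is tested against brute-force pairwise concordance
and an independent library implementation. Day distributions are
compared with all pairwise two-sided Mann–Whitney tests
(exact enumeration when both samples have at most 10 observations and
no ties; otherwise the normal approximation with continuity and tie
correction), Benjamini–Hochberg adjusted across pairs; a day is flagged
best when its median beats all others and all its pairwise q-values
clear the significance level.

**A calibration caveat, found and characterized during development:**
the day comparison treats the repeated-CV averages as independent
samples, but repeats of one day re-use the same images — only the
partition changes. Tiny finite-sample differences between two days'
datasets are therefore flagged far more often than the nominal level
even when the generative process is class-identical (about 30% of null
plates at q < 0.05 in simulations across plate sizes). The comparison
is useful for *ranking* days; its q-values overstate evidence and
should not be read as calibrated error rates. Relatedly, the textbook
step-up FDR adjustment is not idempotent in general (re-adjusting an
adjusted vector can change it), so no such property is claimed.

### Filter metrics

Used as a production filter, the classifier is summarized by confusion
counts and three derived quantities. For an exclusion filter (Task 1)
the flagged images are removed; *impurity* is the proportion of true
defects before filtering versus among the retained pool, *Impurity
Change* is their ratio (below 1 = defects depleted; one minus it is the
defect-rate reduction), and the FPR is the fraction of non-defective
images wrongly flagged. For a retention filter (Task 2) the flagged
images are kept; Impurity Change above 1 measures enrichment of the
high-quality class, and the FNR is the fraction of truly high-quality
images wrongly discarded. All rates are reported at full precision;
rounding happens only at display time. Worked arithmetic on a 714-image
pool is frozen in the acceptance tests.

Significance of the composition change is a two-sided Fisher exact test
on the 2×2 table (positive/negative × before-pool/after-pool), with a
two-proportion test available; since the exact test behind the
originally reported p-values is not documented, reported p-values are
comparable in magnitude, not digit-matched. When predictions come from
the model rather than printed counts, the package pools **out-of-fold**
predictions from one seeded grouped k-fold pass — the only way to get
exactly one leakage-free prediction per image.

Box-plot-style summaries are emitted as tables (medians, quartiles) and
a text waffle summary; plotting is left to the caller.

## Numerical and degenerate-input conventions

* Shell assignment uses `ceiling(r / width - 1e-9)` so a radius that is
  mathematically on a shell boundary is not pushed upward by floating
  error (a bin at exactly $r = 0.26$ belongs to shell 52 of 100).
* Images smaller than 4×4, empty batches, single-class training labels,
  all-constant feature tables, fewer non-constant columns than
  requested components, and folds with fewer wells than folds all fail
  fast with specific messages.
* Training data of rank below 10 yields zero-variance principal axes;
  they are kept as all-zero design columns and counted, so the design
  width is stable.
* An empty retained pool reports impurity-after as undefined (`NA`)
  rather than dividing by zero.
* Pixel values are clamped to $[0, 255]$ after noise addition, so
  extreme contrast/noise settings cannot leave the 8-bit range.

## Problem sizes used by the test and acceptance suites

The suites run on desk-scale versions of the full design, chosen so the
whole loop stays in the minutes range: 64–128 px frames for unit tests;
the performance properties use a 34-well, single-day (day 38), 5-position
plate at 256² — 170 images — with a bimodal outcome mixture (weights
0.5/0/0.5) for the clear-separation case and a severed class link
(density and elongation coefficients on myf5 set to 0) for the null
case, with 10 CV repeats. The full 5,712-image design arithmetic is
exercised by generating the complete default plate at 128².
Well-to-outcome separability at the default mixture is intrinsically
limited by wells adjacent to the 10%/20% thresholds; the
clear-separation condition removes the middle stratum precisely to
isolate pipeline performance from that irreducible ambiguity.

## Known limitations

* Synthetic realism is deliberately limited (see the generator section);
  absolute AUC values on synthetic plates do not transfer to real data.
* Day-comparison q-values are anticonservative under the null
  (pseudo-replication), as discussed above.
* The classifier predicts binary task membership only; regression of
  the continuous efficiency score and probability calibration are out
  of scope.
* Features are global per image; spatial heterogeneity within a frame
  (e.g. colony edges) is integrated away.
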