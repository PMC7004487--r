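---
title: "Quantification methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gustaquant)
```

# What this package quantifies

Studies that compare taste-bud composition and innervation between mouse
genotypes (for example wild type against a knockout lacking Type II taste
cells) rest on a small set of recurring measurements:

* **Innervation density** of a taste bud: the fraction of the bud ROI's
  voxels positive for a nerve-fiber marker such as P2X3, after the image
  stack has been conditioned and binarized.
* **Two-channel co-occupancy**: the fraction of P2X3-positive fiber volume
  that also carries a second label (for example GFP driven from the *Htr3a*
  promoter), `F = |GFP ∩ P2X3 ∩ ROI| / |P2X3 ∩ ROI|`.
* **Cell-profile counts** of marker-positive cells with a visible nucleus on
  sampled optical sections.
* **Ganglion-cell scoring**: classifying geniculate ganglion somata as
  positive or negative per channel from normalized mean intensities, with a
  threshold derived from a two-component Gaussian mixture.
* **Trace responses**: baseline-normalized integrated chorda tympani nerve
  responses and fura-2 ratio (340/380) peak responses.
* **ATP release**: luciferase plate readings calibrated against a linear
  standard curve and compared pairwise against artificial-saliva controls.

Raw recordings behind published figures of this kind are rarely deposited,
so the package ships a synthetic-data module that generates every input
with exact ground truth. All quantitative guarantees quoted below are
measured by the test suite and `scripts/acceptance.R` on those synthetic
conditions, not on real tissue.

# Image conditioning chain

The conditioning chain is fixed, in this order: rolling-ball background
subtraction (radius 50 px), 2D disk median filter (radius 2 px), Otsu
binarization on the stack histogram. `preprocess_stack()` composes the
three and records every parameter in the mask provenance.

**Rolling ball.** Implemented as a per-slice grey-scale morphological
opening with a *non-flat ball* structuring element,
`b(d) = sqrt(r^2 - |d|^2) - r`. The opening is a lower envelope of the
image, so the subtracted result is nonnegative and never exceeds the input.
The exact opening (rather than a sliding-paraboloid approximation) was
chosen because it is fully specifiable and testable against a brute-force
oracle; the compiled kernel is exact at any radius. Background subtraction
runs per z-slice, the conventional behaviour for stack processing.

**Median filter.** A true disk neighbourhood (`dx^2 + dy^2 <= r^2`, 13
pixels at r = 2) with half-sample symmetric reflection at the borders.

**Otsu on the stack histogram.** One threshold per channel, computed from
the histogram pooled over all z-slices — slice-order invariant by
construction. For 8-bit integer data with the default 256 bins the
histogram is the exact integer histogram and the returned threshold is a
grey value; foreground is the *strict* exceedance `intensity > T`. On
plateaus of the between-class variance the smallest maximizing threshold is
taken, making results bit-reproducible. A constant channel has no
threshold and raises an error rather than returning a degenerate mask.

**Known limitation.** Otsu assumes a two-class histogram. On a channel with
no true signal at all (for example the GFP channel of a reporter-negative
animal), the threshold lands inside the noise distribution and roughly half
the voxels are marked foreground. The overlap fraction of a truly
GFP-free bud measured through the full chain is therefore meaningless;
the simulator exposes this case (overlap 0) and it is verified only on
noiseless ground-truth masks.

# Volumetric quantification

Densities and overlap fractions are computed as voxel counts (units
cancel); volumes are additionally reported in µm³ using the anisotropic
voxel size. Per-section area/positive-count records are retained for
auditing but nothing downstream consumes them. An empty ROI or an empty
reference channel is an explicit flagged condition, never a silent zero.

"Middle, upper, and lower quadrant" planes for profile counting are read
minimally as the planes at 25/50/75% of each bud's z-extent with floor
rounding (`z = zmin + floor(q * (n - 1))`), configurable via the
`quantiles` argument. Profile detection — a stand-in for by-eye counting —
is 8-connected components of the binarized marker channel with area ≥ 20 px
containing at least one nucleus-positive pixel. Two merged somata count
once and a neighbouring nucleus can validate the wrong profile, so on
crowded buds the count errs by about one cell per sampled plane (the suite
measures a mean absolute error ≤ 1 against simulator truth at roughly six
marker-positive cells per bud). The detector is pluggable: precomputed
masks can be passed in.

# Ganglion-cell scoring

Stacks are split into consecutive 10 µm substacks (a trailing remainder of
at least half the thickness becomes its own substack, a thinner one merges
into the previous) and max-projected. Cell ROIs are inputs, as they are in
practice; mean intensities are measured per cell and channel.

**Normalization** is per image and channel: subtract the median of
non-ROI pixels (background), clip at zero, divide by the 99th percentile of
the background-subtracted in-ROI pixel values. The result is dimensionless,
approximately in [0, 1], and invariant to rescaling all pixel intensities
by a positive constant. The exact convention is a declared choice — the
field's "background subtracted and normalized for each image" is not more
specific — and the constants used are recorded in the output.

**Thresholding.** One- and two-component Gaussian mixtures are fitted by EM
(via `mclust`, whose hierarchical model-based initialization is
deterministic, so a fixed input gives a fixed fit) and the modality is
chosen by BIC. For a bimodal channel, each value is assigned to its
maximum-responsibility component and

> `T = median(lower-component values) + 2 * SD(lower-component values)`

taking "median/SD of the lower peak" as statistics of the assigned values;
the fitted component sigma is available via `use_fitted_sigma = TRUE` and
is substituted automatically when fewer than two values are assigned to the
lower component. For a unimodal channel the rule is extrapolated as
`mean + 2 SD` and flagged. Cells score positive on the *strict* exceedance
of `T`. Note the rule's intrinsic asymmetry: a threshold two SDs above the
lower peak leaves ~2.3% of genuinely negative cells above it, so scored
positive fractions run ~1–2 points above truth even with perfect fits; the
pooled misclassification measured by the suite is ~1.4%.

# Trace analysis

**Nerve.** For each stimulus, baseline `B` is the mean of the 10 s
immediately before onset, `S` the mean over the stimulus window, and the
response `R = (S - B)/B` — scale-free, so amplifier gain cancels. A
non-positive baseline or overlapping windows are errors. Responses can
optionally be re-expressed relative to a reference stimulus (conventionally
NH₄Cl) with `normalize_to_reference()`.

**Calcium.** Baseline is the mean of the first 10 s (configurable to 15 s)
of the ratio trace. A response is *visible* when the ratio exceeds
`B + 3·SD(baseline)` for at least two consecutive samples; requiring the
exceedance to be sustained keeps the expected maximum of a ~30-sample
window (which crosses 3 SD in a double-digit percentage of null traces)
from counting as a response, which is what a by-eye "visible" call means.
For visible responses the peak `P` is the raw window maximum; otherwise the
value 30 s after onset is used and flagged. Reported are `dR = P - B` and
the normalized value `dR / P` (the per-trace reading of the
baseline-subtracted-over-peak convention; normalizing across stimuli
instead is trivial downstream). Because the peak is a maximum, its mean
under noise carries a positive bias of order twice the effective noise SD
(about +0.018 ratio units at noise SD 0.01); this is a property of any
peak-picking convention, not of the implementation, and should be kept in
mind when comparing small responses.

# ATP calibration

The standard curve is ordinary least squares of RLU on known concentration
— linear, not log-log, since luciferase output is linear over the nM range
used. At least three distinct standard concentrations are required and the
slope must be positive. Inversion clips negative back-calculated
concentrations to zero with a flag and flags extrapolation beyond the
fitted range. Stimulated wells are paired with the artificial-saliva well
of the same preparation; per-condition comparisons use the paired t test,
and saliva-relative ratios are reported per trial.

# Statistical battery

`kruskal_wallis()` (tie-corrected H, χ² approximation), `dunn_test()`
(pairwise rank z statistics with the tie term, unadjusted by default —
matching how per-pair p values are conventionally reported — with Holm or
Bonferroni on request), `chi_square()` (Pearson, expected counts reported),
`paired_t()` (zero-variance nonzero-mean differences raise an error rather
than returning an infinity), and `two_way_anova()`. The two-way analysis
uses Type II sums of squares for fixed-effects layouts — appropriate for
the unbalanced per-bud designs this pipeline produces — and a split-plot
decomposition when a subject identifier is given (between-subject factor
tested against the subject stratum, within-subject effects against the
subject-by-factor stratum; sphericity is assumed and flagged). Post hoc,
levels of the first factor are compared within each level of the second by
t tests on the relevant error term with step-down Holm–Šidák adjustment,
`p_adj = 1 - (1 - p)^(m - i + 1)` cumulatively maximized. Every statistic
is pinned in the test suite to hand-computed oracles on small inputs and to
the reference implementations (`kruskal.test`, `chisq.test`, `t.test`,
`aov`, `car::Anova`), and the simulated null rejection rates of the
Kruskal–Wallis, χ², and paired t tests sit in [0.03, 0.07] at α = 0.05.

# The synthetic-data generators

The generators define the conditions under which every guarantee is
measured.

**Taste-bud stacks** (`generate_bud_stack()`): 0.2 × 0.2 × 1.0 µm voxels
and a 14-section stack, matching cryosection imaging at 1 µm axial spacing;
an ellipsoidal bud of 24 µm diameter (a compact fungiform-scale bud, kept
deliberately small so a full conditioning chain runs in seconds); elongate
cells (2 × 2 × 5 µm semi-axes) with 1.6 µm nuclei, Poisson counts per type
(defaults 14 Type II, 6 marker-positive Type III); fibers as random-walk
tubes of 0.7 µm radius — the apparent caliber of intragemmal fiber bundles
— grown until the in-bud fiber volume hits the target density *exactly*
(the last stamp is trimmed voxelwise, so stored truth equals
`round(density × bud volume) / bud volume`). The GFP mask is a subset of
whole P2X3 fibers plus one partial fiber, hitting the requested overlap
fraction with the same one-voxel exactness. Rendering applies a Gaussian
PSF (σ 0.15 µm lateral, 0.5 µm axial — textbook confocal widths), then
Poisson shot noise (gain 1) plus Gaussian read noise (SD 6 of 255), a
linear background ramp, and 8-bit quantization. What the simulator does
*not* model: optical sectioning artifacts beyond the Gaussian PSF,
bleaching, tissue autofluorescence structure, or axon-guidance biology of
real fiber arbors — so recovery results certify the measurement chain, not
performance on arbitrary tissue.

**Ganglion fields** (`generate_ganglion_field()`): non-overlapping 6 µm
somata in a 128 × 128 × 30 µm slab at 1 µm axial spacing; per-channel
intensities drawn from the two-component mixture N(0.2, 0.05²)/N(0.8,
0.05²) with positive fractions 0.95 (SNAP25), 0.85 (P2X3), 0.4 (GFP) — all
below one because every real channel has a dim population, and an
all-positive channel makes any histogram threshold an extrapolation.
`generate_ganglion_intensities()` exposes the value-level draw directly for
scoring tests at scale.

**Traces**: integrated nerve recordings at 10 Hz, baseline 2.0, exponential
rise/decay kinetics (τ 1.5 s / 4 s), 30 s stimulus / 40 s rinse schedule;
fura-2 ratio traces at 1 Hz (dual-excitation ratio imaging is slow),
baseline ratio 1.0, noise SD 0.01. Stored truth for recovery tests is
recomputed from the noiseless waveform with the same windowing the analysis
uses, so recovery is self-consistent whatever the kinetics.

**Plates**: RLU linear in concentration; the paired release study draws a
saliva level of 20 nM with lognormal (σ_log 0.3) per-measurement noise and
a stimulated level at a configurable fold change, read through the same
curve. With a 2× effect and 10 pairs the paired t test detects release in
well over 80% of replicates.

All generators take an explicit seed, restore the caller's RNG state, and
are bit-reproducible.

# Problem sizes and reproducibility

The test suite and the acceptance script run everything at the scales
quoted above: 50 random stacks for the Otsu oracle, three full
simulate-condition-quantify runs for density recovery (one per fiber
level), 24 buds for profile-count recovery, 20 × 500 cells for scoring
recovery, 100 replicates per trace Monte-Carlo, 500 replicates for ATP
power, and 1,000 replicates per null-calibration test — sizes chosen so the
whole suite completes in a few minutes on one core while keeping every
Monte-Carlo standard error well below the margins being asserted. The demo
pipeline (`run_pipeline()`) is byte-reproducible: the same configuration
and seed produce identical CSV/JSON outputs and checksums.

# Command-line use

The package's interface is its functions plus two entry points:
`run_pipeline()` consumes a YAML configuration (see
`inst/extdata/demo_config.yaml`) covering simulation, preprocessing,
quantification, and statistics with full default echo and rejection of
unknown keys, and `scripts/acceptance.R` reproduces the headline numbers
from a fresh seed. Format round trips (multi-page TIFF per channel plus a
JSON metadata/provenance sidecar, tidy CSV tables) cover the interchange
needs of the pipeline.
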