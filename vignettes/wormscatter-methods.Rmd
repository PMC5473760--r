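---
title: "Methods: dark-field scattering densitometry of C. elegans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dark-field scattering densitometry of C. elegans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormscatter)
```

## The measurement model

Under dark-field (oblique) illumination, only light scattered by the
specimen enters the objective. In *C. elegans* the dominant scatterers are
lipid-rich structures — intestinal lipid droplets, embryos, and in early
larvae the birefringent gut granules (lysosome-related organelles, LROs).
The package's core quantity is the *scattering density* of a worm:

$$ D \;=\; \frac{\sum_{p \in \text{contour}} I_p}{|\text{contour}|} \qquad [\text{a.u.}/\text{px}] $$

the summed in-contour pixel intensity divided by the contour area. It is a
*relative* fat proxy: intensities are arbitrary detector units, so $D$ is
only comparable between images that share a common illumination reference.
Three assumptions underlie the pipeline:

1. **Scattering is proportional to illumination.** A session-wide lighting
   change multiplies every pixel by a constant, so a single scalar per
   session can undo it.
2. **The contour contains the signal of interest.** Everything inside the
   worm outline — intestine, embryos, head — contributes; nothing is
   background-subtracted by default (a `background` argument exists but
   defaults to off, since the method sums raw, lighting-corrected
   intensities).
3. **Validation is at cohort level.** Scattering and Oil Red O (ORO)
   staining cannot be measured on the same worm (staining requires
   fixation), so the validation regresses cohort means on cohort means,
   with disjoint worm sets per cohort.

### Illumination regulation and correction

A stable scattering phantom is imaged at the start of each session. The
mean intensity in an annulus around a scratch mark (the registration
landmark; the annulus excludes it because the scratch is not
representative scatter) is the session's illumination readout. Two uses:

- `check_lighting()` — an advisory check that the session mean is within a
  fractional tolerance (default 10%, boundary inclusive) of a fixed
  target. It warns rather than blocks, because residual differences are
  corrected in software anyway.
- `correction_factor()` / `apply_correction()` — every experimental frame
  is multiplied by `reference mean / session mean`, putting all sessions
  on the common reference scale. The correction is exactly multiplicative
  and unclipped; the factor is recorded in the image metadata and a second
  application is a guarded error (silent idempotence would hide pipeline
  bugs; silent re-application would bias every downstream density).

The guarantee this buys — and the property the tests enforce end to end —
is *session invariance*: if the scene and the phantom are both scaled by
any $k > 0$, corrected densities are unchanged to floating-point
precision.

The annulus geometry is configurable (defaults: inner 5 px, outer 25 px)
because the physical protocol does not pin down an ROI shape; one phantom
frame per session (not per image) is assumed, matching how such phantoms
are used in practice.

### Segmentation

Worm bodies are segmented by a grayscale threshold chosen *per condition*:
strain brightness varies (feeding-defective mutants are darker), so no
single automatic threshold is trustworthy. `suggest_threshold()` offers an
Otsu starting point but is never applied silently. Conventions, fixed for
reproducibility:

- pixels **strictly above** the threshold are foreground (a pixel equal to
  the threshold is background);
- connected components under **8-connectivity**;
- components below `min_area_px` are discarded;
- interior holes are filled, because worm interiors (notably the head)
  can scatter weakly and the density must integrate the whole body;
- masks are returned sorted by area (ties broken by the smaller row-major
  top-left pixel), labelled `worm_1`, `worm_2`, ... deterministically.

At high magnification the outline is drawn by hand instead
(`manual_mask()`), excluding head and cuticle. Rasterization is by
pixel-center membership under the even-odd fill rule with 0-based
`(row, col)` vertices — stated once and used everywhere, to avoid the
dialect ambiguity between raster libraries. Self-intersecting outlines are
rejected.

Worm length (for larval staging) is the longest geodesic path along the
Zhang–Suen skeleton of the mask, diagonal steps weighted $\sqrt 2$, times
the pixel size. Thinning erodes a few pixels at the body tips, so lengths
carry a 1–3 px endpoint tolerance; on capsule-shaped test bodies the
measurement lands within 5% of the generating curve's arc length. No
installed R package provides thinning, so the Zhang–Suen pass is
implemented here directly; the longest path is computed on the skeleton's
8-neighbour graph with igraph.

### ORO pseudodark field

ORO absorbs strongly near 510 nm, so stained regions are *dark* in a
510 nm bright-field frame. Inverting on the native integer scale,
$p \mapsto 2^{\text{bit}} - 1 - p$, turns absorption into a bright signal
so the identical sum/area densitometry applies. Inversion and
multiplicative correction do not commute, so the pipeline order is fixed —
**invert, then correct, then measure** — and enforced through the modality
and `corrected` flags: inverting an already-corrected frame is an error.

### Colocalization (dark field vs Nile Red)

To ask *what* scatters, each channel is high-pass filtered (unsharp-mask
style: image minus Gaussian blur) to isolate puncta and edges, the pixels
strictly above the 80th percentile of in-mask filtered intensity are
selected in each channel, and the Sørenson–Dice coefficient
$QS = 2|A\cap B|/(|A|+|B|)$ measures their overlap. Choices that matter:

- The physical protocol does not specify the filter; a Gaussian high-pass
  (default $\sigma = 2$ px at 63×) is the simplest operator that produces
  puncta and edges. QS magnitudes depend on the filter, so QS values are
  comparable only at matched parameters.
- The blur is renormalized over in-mask pixels
  ($\mathrm{blur} = K*(I\,m) / K*m$), so the dark background outside a
  manual outline cannot bleed across the boundary and masquerade as edge
  signal.
- Percentile by linear interpolation, selection strictly above it: with
  continuous values the selected fraction is 20% to within one pixel; an
  all-ties channel selects nothing.
- $QS(\varnothing,\varnothing) = 1$ (vacuous agreement) and
  $QS(\varnothing, A) = 0$ — documented because unstained controls can
  produce near-empty selections.
- Because selection is rank-based, QS is invariant to any strictly
  monotone intensity transform of a channel.

Two independent 20%-selections overlap at $QS = 2 f^2 / 2f = f = 0.2$ in
expectation — the analytic "no colocalization" null the calibration tests
target. Coincident puncta in both channels drive QS toward 1 (kernel and
rim effects keep it slightly below).

### Cohort statistics

`anova_bonferroni()` runs a one-way ANOVA across all groups, then pairwise
two-sample t tests of each condition against the reference strain only
(matching how strain panels are reported against an N2 reference), with
the Bonferroni multiplier equal to the number of pairwise tests performed
and the adjusted p capped at 1. The pairwise tests are unpooled (Welch) by
default — strain variances differ visibly in real panels — with a pooled
option; an all-pairs mode sits behind a flag. Degenerate input (all
observations identical) takes the no-effect path $F = 0, p = 1$ rather
than erroring. With two groups the ANOVA reduces exactly to the pooled
t test ($F = t^2$), which the tests assert to $10^{-9}$.

`validation_fit()` is unweighted OLS of cohort-mean ORO density on
cohort-mean scattering density (the protocol plots SEM ellipses but
describes no weighting; errors-in-variables modelling is out of scope),
reporting slope, intercept, $r^2$ and the slope-zero p-value.

`paired_change()` exploits that dark-field imaging is non-destructive: the
same worm is measured before and after an intervention (e.g. 18 h
fasting). A delta of exactly 0 is *not* a decrease; unmatched worm ids are
excluded with a warning.

### Time courses

Different worms are culled at each timepoint (no per-worm tracking), so a
series is a per-timepoint cohort of densities. Trajectories are divided by
the mean density at a baseline timepoint (so its mean is exactly 1). Small
larvae are imaged through a high-magnification objective and older worms
through a lower one; one shared timepoint imaged through both anchors the
merge: the second series is multiplied by
$k = \text{mean}_a(t_s)/\text{mean}_b(t_s)$, both shared cohorts are
retained, and the high-magnification series is the reference scale by
default (it covers the early baseline). Normalize-then-stitch and
stitch-then-normalize agree to float tolerance.

Larval transitions are read off the mean-length curve: the first upward
crossing of each length cutoff, located by linear interpolation after
3-point median smoothing (to tolerate cohort noise). Cutoffs are
user-supplied — there are no authoritative stage/length constants, and any
defaults shown in examples are placeholders, not biology.

## The synthetic-data generator

`render_scene()` draws what the measurement model needs and nothing more:

- a **body** as a sinusoidal centerline swept with a disk (a capsule),
  with analytically known centerline arc length and realized area;
- **lipid droplets** as disks whose 1 px rim is brighter than the interior
  (the rim-bright appearance of droplets under dark field), disjoint
  interiors by default;
- **puncta** (LRO-like) as small bright disks, optionally co-placed or
  independently placed in a fluorescence channel
  (`render_fluorescence()`) to emulate perfect colocalization or its
  absence;
- **camera noise** as Gaussian shot noise with variance proportional to
  signal plus additive read noise — the minimal model that makes SNR a
  controllable parameter;
- a multiplicative radial **vignette**, applied last;
- a **phantom** (`render_phantom()`) as a flat noisy field with a dark
  scratch — a synthetic stand-in for a physical scattering target.

Everything is deterministic given the mandatory seed, and the ground truth
(body mask, droplet/puncta positions, realized noiseless density, arc
length) suffices to predict every pipeline output in closed form in the
noiseless limit; the tests exploit exactly that.

When a target density is requested (`droplet_density_target`), the droplet
count is derived from the realized body area and the exact expected
per-droplet pixel sum (computed on the pixel grid by quadrature over the
radius range), with stochastic rounding so the *expected* density equals
the target even though one droplet is a coarse quantum on a small body.

`generate_validation_study()` emulates the split-cohort validation design
at its published shape: 23 conditions spanning a 3-fold latent-fat range,
15 worms per condition per modality (the reported per-cohort medians are
19 dark-field and 15 ORO worms), per-worm measurement
$g\,\mu_c(1+\varepsilon)$ with $\varepsilon \sim N(0, \text{cv})$ and
cv = 0.10 by default, and *disjoint* worm draws for the two modalities.
`generate_fasting_cohort()` uses 55 worms with a uniform 10–40% density
loss over 2% measurement noise. `generate_timecourse()` renders full
scenes for synchronized cohorts between 4 and 50 h, switching from the
fine to the coarse objective at the 31 h shared timepoint, with an
objective throughput mismatch (gain 0.55) that the stitching must absorb.

What the generator does **not** emulate — and what passing tests therefore
do not certify on real data: optical blur and diffraction, realistic worm
posture (coiling, touching worms), anatomy beyond a homogeneous capsule
(no head/intestine structure, no embryos), Mie scattering of droplets
(rim-bright disks are a phenomenological stand-in), spatially varying
illumination beyond a radial vignette, and stage drift or registration
error between channels. Real-data thresholds and QS magnitudes must be
established per study; the synthetic results validate the *computations*,
not any biological constant.

## Numerical conventions and degenerate inputs

- Coordinates: 0-based `(row, col)`, row-major, pixel centers; stated once
  in `worm_image()` and used everywhere.
- Intensities stay on the native integer scale; no implicit [0,1]
  rescaling. Ingest enforces $p \le 2^{\text{bit}}-1$; corrected values
  may exceed it (and then refuse lossless TIFF export).
- Percentiles: linear interpolation (R type 7); threshold comparisons are
  strict (`>`).
- Empty results are not errors where emptiness is informative: a
  threshold above the image maximum yields an empty mask list; a cutoff
  never crossed yields an `"absent"` transition.
- Division-by-zero paths are explicit: SEM needs $n \ge 2$; the slope of a
  constant-x fit is an error while constant-y returns slope 0, $r^2 = 0$;
  zero-variance correlation returns a flagged undefined result.
- Seeds are mandatory arguments of every generator; there is no hidden
  global RNG state (`withr::with_seed` scopes all draws).

## Problem sizes used by the test suite

The suite and `scripts/acceptance.R` run at sizes chosen to make the
stochastic checks sharp while keeping a full run in tens of seconds:
100 random 64×64 rasters for the densitometry oracle; 1000 trials for
percentile exactness; 50 scenes for segmentation recovery (observed IoU
≥ 0.999 against truth at 8:1 body/background contrast); 100 studies of
23 × 15 worms for the validation fit (observed r² ≈ 0.98 at cv = 0.10,
slope recovery within 1%); 10 + 100 scenes for colocalization calibration
(coincident QS ≈ 0.93, independent-placement mean QS ≈ 0.21 against the
0.2 analytic null); 1000 null simulations for the family-wise error rate
(observed ≈ 0.04 at nominal 0.05); 9-timepoint, 6-worm-per-point
two-objective time courses (trajectory correlation ≥ 0.999 with the
programmed curve, a ×2 step recovered within 3%, transitions within 1 h);
and 55-worm fasting cohorts. The published experiments used 10–16 worms
per timepoint; the generator's default `worms_per_point = 12` matches
that, and tests pass 6 explicitly for speed.

## Known limitations

- Relative units only: no absolute triglyceride calibration; densities
  are comparable only within one phantom reference, and cross-project
  comparison is explicitly unsupported.
- One scalar correction per session: no per-pixel flat-field model.
- Threshold segmentation cannot separate touching worms and assumes
  immobilized, non-overlapping animals.
- QS depends on the high-pass parameters; only matched-parameter
  comparisons are meaningful.
- The CLI takes its configuration from flags only; batch inputs are
  manifest CSVs rather than a config file.
- Skeleton length is biased low by endpoint erosion (and high by boundary
  fuzz on noisy masks — open the mask first, as `measure_timecourse()`
  does); transitions inherit a fraction of an hour of uncertainty from
  this.
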