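---
title: "Methods: quantifying a labeled retinal ganglion cell population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying a labeled retinal ganglion cell population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgckit)
```

# Scope

`rgckit` implements the quantitative pipeline used to characterize a
genetically labeled retinal ganglion cell (RGC) population from four
kinds of evidence:

1. **Spatial statistics** on the mosaic of labeled somata in a whole
   mount (nearest-neighbor distances, a regularity index, the density
   recovery profile).
2. **Section straightening**: mapping a curved cross-section of the
   inner plexiform layer (IPL) onto a rectangular depth frame with a
   bilinearly blended Coons patch, to extract stratification profiles.
3. **Morphometry** of dye-filled, traced cells (SWC): total neurite
   length, branch points, dendritic stratification depth, and a
   four-way subtype call.
4. **Spike-train physiology**: firing adaptation, flash-response class
   (ON / OFF / ON-OFF), spot-size tuning, and direction tuning with a
   direction-selectivity index (DSI).

Every input class can be generated synthetically with known ground
truth, so each stage is validated by parameter recovery rather than by
eyeballing plots.

# Mosaic statistics

## Nearest-neighbor distances and the regularity index

For each cell, `compute_nnd()` finds the Euclidean distance to its
closest neighbor. The regularity index is the mean nearest-neighbor
distance divided by a dispersion measure. This package's default
denominator is the **standard error of the mean** (the convention used
for this dataset); the mosaic literature more commonly divides by the
**standard deviation**. The two differ by a factor of $\sqrt{n}$:

$$\mathrm{RI}_{sem} = \frac{\overline{NND}}{SD/\sqrt{n}}
  = \mathrm{RI}_{sd}\,\sqrt{n}.$$

Because $\mathrm{RI}_{sem}$ grows with the number of cells sampled, it
is **not comparable across samples of different size**; the result
object therefore always records which denominator produced it, and both
modes are exposed (`denominator_mode = "sem"` or `"sd"`). No assumption
is made about which convention produced any published figure.

A perfect lattice has zero NND dispersion; rather than returning an
overflow-scale number driven by float rounding, dispersion below
$10^{-12}$ of the mean is reported as an explicit infinite-RI flag.

## Density recovery profile (DRP)

`density_recovery_profile()` counts, around each reference cell, the
neighbors in concentric annuli $[r, r+\partial r)$ and divides by the
annulus area:

$$\rho(r) = \frac{N(r+\partial r)}{A(r+\partial r)} \quad
  [\text{cells/mm}^2].$$

A random (Poisson) mosaic gives a flat profile at the global density;
a regular mosaic shows an exclusion zone — a depressed profile near
$r = 0$. Defaults are $\partial r = 10$ µm and $r_{max} = 300$ µm
(configurable; comparable to the radial range over which retinal DRPs
are usually plotted).

**Edge correction.** The default `"buffer"` policy admits as reference
points only cells at least $r_{max}$ from every window edge, so every
annulus lies fully inside the window and the estimator is unbiased; the
uncorrected `"none"` policy is available for small windows, at the cost
of underestimating outer annuli. No published edge-handling rule was
available to mirror, so the conservative option is the default.

`fit_drp_curve()` adds a least-squares polynomial (order 7 by default)
of mean density on annulus midpoint and a 99% confidence band obtained
by bootstrap resampling of reference cells (1,000 seeded resamples by
default). A percentile bootstrap was chosen because the CI construction
behind shaded bands of this kind is conventionally unstated; resampling
reference cells respects the fact that annulus counts from one
reference cell are correlated.

# Section straightening

## Boundary detection

Cross-sections are oriented with the ganglion cell layer (GCL) toward
row 1. The nuclear channel (DAPI-like) is thresholded with Otsu's
method, then each column is walked for its first and last nuclear band
(≥ 3 px thick); the band edges facing the IPL become the GCL/IPL and
IPL/INL boundary curves, smoothed with a 1-D Gaussian (σ = 5 px
default). Columns where either band is missing are linearly
interpolated when they are ≤ 20% of the domain; beyond that the section
is **discarded with an error**, mirroring the practice of dropping
sections that cannot be straightened rather than guessing.

## The Coons patch

With boundary curves $c_0(s)$ (top, GCL/IPL) and $c_1(s)$ (bottom,
IPL/INL) and lateral edges $d_0(t), d_1(t)$, the bilinearly blended
Coons patch is

$$S(s,t) = (1-t)\,c_0(s) + t\,c_1(s) + (1-s)\,d_0(t) + s\,d_1(t)
         - B(s,t),$$

where $B$ is the bilinear interpolant of the four corners. Only the two
horizontal boundaries are detectable from the nuclear stain, so the
lateral edges are taken as the straight segments joining the curve
endpoints — in that case the lateral terms cancel $B$ exactly and the
patch degenerates to vertical interpolation between the detected
curves. The full four-boundary formula is implemented nonetheless, so
curved lateral edges could be supplied. Intensities are resampled
bilinearly, identically for every channel; samples outside the raster
are zero-filled (never extrapolated) and counted.

The output grid has row 1 at **0% depth (GCL border)** and the last row
at **100% (INL border)**; `depth_profile()` reduces a channel to mean
intensity per depth row, normalized to peak 1.

## Depth conventions and the S1–S5 scheme

The whole package uses the same axis: 0% at the GCL border, 100% at the
INL border. The five conventional strata are equal quintiles. S1 — the
OFF stratum — is the one adjacent to the inner nuclear layer, and S5
the ON stratum adjacent to the GCL, so on this axis:

| stratum | depth range | polarity |
|---------|-------------|----------|
| S5      | 0–20%       | ON       |
| S4      | 20–40%      | ON       |
| S3      | 40–60%      | —        |
| S2      | 60–80%      | OFF      |
| S1      | 80–100%     | OFF      |

This orientation is what makes a cell with dendritic peaks at ~30% and
~70% depth "bistratified in S2 and S4", i.e. co-stratifying with the ON
and OFF cholinergic bands. Stratum edges are a config key
(`default_layer_scheme()`), since equal quintiles are a convention, not
a measurement.

# Morphometry

SWC trees are validated on read (unique ids, one root, all nodes
reachable — which excludes cycles and orphans). Total neurite length is
the sum of parent–child segment lengths with soma segments always
excluded and axon (type 2) segments excluded by default, because the
analysis concerns dendritic stratification. Branch points are non-soma
nodes with ≥ 2 children.

`stratification_distribution()` apportions each dendritic segment's
length linearly across the depth bins it traverses (default bin 2%), so
the unnormalized profile mass equals the total dendritic length exactly
— a conservation law the tests check to $10^{-6}$ relative. Nodes
within $[-10, 110]$% depth are tolerated (clamped, with a warning);
beyond that the frame is presumed wrong and the call errors.

`classify_subtype()` finds profile peaks by topographic prominence
(default 0.2 on the peak-normalized profile), partitions dendritic mass
at the minima between peaks, drops peaks carrying < 15% of the mass,
and maps the survivors to strata. Exactly {S2, S4} → bistratified;
a single peak in S4, S5, or S1 → the corresponding monostratified call;
anything else → `unclassified`. The prominence and mass-fraction
defaults were chosen once so that generator fixtures with 5%-SD slabs
at the canonical depths classify correctly; both are exposed as
arguments, since no published bistratification criterion exists to
adopt.

# Spike-train physiology

## Firing adaptation

The adaptation index compares the first and last inter-spike intervals
(ISI) of a train. The **literal** variant is

$$a = 1 - \frac{T_{last}}{T_{initial}},$$

which is 0 for a perfectly regular train and *negative* when firing
decays (the last interval is then the longest). Because verbal
descriptions of this quantity usually intend decaying firing to score
*positive*, a second variant `decay_positive` computes
$1 - T_{initial}/T_{last}$. The two agree at 0 for regular trains and
are algebraically linked by $a_{lit} = 1 - 1/(1 - a_{decay})$; the
variant used is recorded on every result, and neither is asserted to be
the "right" reading of the ambiguity.

A numerical note: with a decimal ISI such as 100 ms, cumulative spike
times round at the $10^{-16}$ level, so the index of a perfectly
regular train computes to ~2×10⁻¹⁶ rather than bitwise 0; with a
binary-representable ISI (e.g. 125 ms) it is exactly 0. The test suite
asserts both.

## Flash classification

Flash trials carry `baseline` (1 s), `stim_on` (2 s), and `stim_off`
(2 s) epochs. The ON (OFF) index is the z-scored elevation of the mean
rate in the 300 ms window after the light-ON (light-OFF) edge, relative
to the across-trial distribution of baseline rates; the call is ON,
OFF, ON-OFF, or unresponsive depending on which indices exceed
`z_thresh` (default 3 — no published criterion exists, and 3 SDs is the
usual conservative choice). A completely silent baseline has zero SD;
the classifier then substitutes the Poisson SD of the baseline-rate
estimate (with a half-spike floor) and flags the fallback. The 300 ms
transient window matches the generator's ON-OFF edge transients, whose
duration is itself a modeling choice: transient edge responses are
visible in recordings of this kind but their duration is not quantified,
so 300 ms is a stated convention, not a fit.

## Direction tuning

Trials at 8 directions (45° apart, 2 s moving-grating sweeps) are
reduced to mean spike counts $n_d$. The default DSI is the normalized
vector sum

$$\mathrm{DSI} = \frac{\left|\sum_d n_d e^{i\theta_d}\right|}
  {\sum_d n_d},$$

standard in the direction-selective ganglion cell literature, 0 for
uniform tuning and 1 when all spikes fall in one direction; the
preferred direction is the argument of the vector sum. A
`(pref − null)/(pref + null)` variant is available behind
`dsi_mode = "pref_null"`. No DSI cut-off for calling a cell "direction
selective" is hard-coded, because none is established. Directions are
kept in the retina's reference frame; any flip to the animal's visual
perspective is presentation-layer only and never applied to stored
data.

# The synthetic world

The generators state a world in which every downstream claim is
checkable; their defaults are fixed once and are not tuned to tests.

- **Mosaics.** Poisson patterns at 100 cells/mm² in a 2×2 mm window are
  the randomness null. Regular mosaics are hard-core (dart-throwing)
  patterns with dmin = 50 µm — rejection sampling guarantees the
  exclusion distance exactly and fails loudly (naming the achieved
  density) when the packing is infeasible, which a thinning scheme
  would hide. Jittered hexagonal lattices provide a high-regularity
  reference for RI ordering tests.
- **Spike trains.** Geometric ISI progressions pin the adaptation
  ground truth: the literal index is $1-\rho$ for ISI ratio $\rho$, by
  construction.
- **Direction trials.** Counts are Poisson with a von Mises mean
  profile (peak-normalized), the standard smooth single-peaked circular
  tuning form, consistent with single-lobed polar plots; the generative
  form is a choice, not a claim about real cells.
- **Flash trials.** Piecewise-constant-rate Poisson spiking at
  40 spikes/s evoked over a 2 spikes/s baseline; spot diameter scales
  the evoked rate by a Gaussian-in-log-diameter profile peaking at
  300 µm with a 0.25 floor. No published spot-size tuning function
  exists for this population, so the profile is a free generator
  parameter recorded in the ground truth — recovery tests check the
  argmax, not the shape.
- **Morphologies.** Binary-branching arbors whose nodes scatter around
  one or two stratification planes with 5%-depth Gaussian slabs, soma
  in the GCL, IPL thickness 50 µm (a typical adult mouse value).
- **Sections.** Sinusoidally curved layers of constant IPL thickness,
  nuclear bands flanking the IPL, Gaussian marker bands at known
  depths, additive Gaussian noise. Constant thickness means boundary
  curves cannot cross by construction; amplitudes that would push a
  layer off the raster are rejected.

**What a green test does not establish.** The synthetic world is
idealized: real mosaics have soft (not hard) exclusion zones and
density gradients; real sections have uneven staining, varying IPL
thickness, and tissue tears; real spike trains are non-Poisson and
adapt continuously rather than geometrically. Recovery of planted
parameters demonstrates that the estimators are correctly implemented
and approximately unbiased under their assumptions — not that those
assumptions hold in tissue.

# Numerical choices and degenerate inputs

- Nearest-neighbor search is exact (full distance matrix); patterns at
  the scale of this analysis (≤ a few thousand cells) do not warrant a
  spatial index.
- DRP annuli are half-open $[r, r+\partial r)$; a neighbor exactly at
  an annulus edge belongs to the outer annulus.
- Patterns with n < 2, empty spot/flash windows, all-zero channels,
  blank nuclear stains, zero-dispersion NND sets, and all-zero
  direction counts each produce a documented explicit result (error or
  flag), never a silent NaN.
- Out-of-raster samples during straightening are zero-filled and
  counted (`attr(x, "oob_count")`), never extrapolated.
- All generators take a mandatory seed and restore the caller's RNG
  state; the pipeline derives stage seeds from one master seed, so a
  full run is byte-reproducible.

# Known limitations

- The SEM-based regularity index is faithfully implemented but is an
  unusual convention; cross-study comparisons should use `"sd"` mode.
- The Coons patch with straight lateral edges cannot correct shear
  along the layer, only curvature across it.
- The long-format spike CSV cannot represent a trial with zero spikes;
  analyses rebuilt from disk see only spiking trials.
- Subtype classification assumes the four-type scheme it was built
  for; cells stratifying in S3, or with three or more peaks, are
  `unclassified` by design.
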