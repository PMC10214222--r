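---
title: "Methods: inverse design and quantification of microstructured niches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverse design and quantification of microstructured niches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichefab)
```

This vignette documents the models the package implements, the tunable
parameters and their defaults, the numerical choices made where the design
was genuinely open, and what the synthetic-data tests do and do not
demonstrate about real data.

## The fabrication state-space

Flow-lithographic niche printing has, after fixing laser power (100% PWM)
and scan velocity, two free fabrication variables: the **unified
monomer–photoinitiator index** `peg_pi` (dimensionless, numerically equal
to the monomer concentration in % w/v, with the photoinitiator
concentration slaved to it along an ellipse — see below) and the **focus
offset** `focus_z` (mm). Calibration prints pair these with measured
Young's modulus (kPa), linewidth (µm) and bound-conjugate fluorescence
(a.u.). A `state_space` holds such records and answers property queries by
Nadaraya–Watson smoothing:

$$\hat E(x, z) = \frac{\sum_i \tau_i E_i}{\sum_i \tau_i},\qquad
\tau_i = \frac{1}{0.1\cdot 2\pi}\exp\!\left(-\tfrac12\left[
\left(\tfrac{\Delta x_i}{0.1}\right)^2 +
\left(\tfrac{\Delta z_i}{0.1}\right)^2\right]\right)$$

with $\Delta x_i = (x_i - x)/40$ and $\Delta z_i = (z_i - z)/6$. The
constants 40 and 6 are the normalization ranges of the two axes and 0.1 is
the kernel bandwidth in normalized units; together they give the kernel a
standard deviation of 4 index units and 0.6 mm. The $1/(0.1\cdot2\pi)$
prefactor cancels in the ratio and is retained in `kernel_weights()` only
for fidelity to the weighting expression. Interpolated values are convex
combinations of the records, hence always bounded by the record extrema.

Two kernel readings are provided because the weighting expression admits a
degenerate transcription in which the two normalized differences are summed
before squaring. The default `product_gaussian` is the standard 2-D
Gaussian; `literal_summed` implements the summed variant for comparison.
The summed form is not a metric kernel (opposite-sign offsets cancel), which
is why it is not the default.

For the bound-conjugate channel the calibration has a third axis, the
conjugate concentration. The same 2-D kernel is used, restricted by
nearest-neighbour matching to the closest tabulated conjugate level. This
treats the conjugate axis as categorical, which matches how such tables are
acquired (a few discrete loadings) and avoids inventing a third bandwidth
the data cannot support.

## Inverse design

`solve_fabrication()` minimizes the relative squared mismatch

$$\left(\frac{E_{des}-\hat E(x,z)}{E_{des}}\right)^2 +
  \left(\frac{W_{des}-\hat W(x,z)}{W_{des}}\right)^2$$

with a multistart Nelder–Mead simplex (8 Latin-hypercube starts over the
record bounding box, objective tolerance 1e-10, seeded and therefore
deterministic). The relative scaling makes kilopascals and micrometres
commensurate. Ties between equally good minima break toward the smallest
`|focus_z|`, then the smallest `peg_pi`.

The search runs in logistically transformed coordinates so that iterates
remain inside the calibration bounding box. Outside the box the kernel
smoother merely extrapolates its edge records — the surface flattens and
carries no information — and an unconstrained simplex can wander into that
plateau or beyond the domain of the ellipse split. Confining the search to
the data hull makes the solver return the best *supported* setting.

A consequence of kernel smoothing worth knowing: near the edges of the
calibration box the one-sided kernel biases the surface inward by up to
10–20% of the local value, so targets at the extreme corners of the
envelope (for example the very softest modulus jointly with a wide
linewidth) are approached best-effort rather than matched exactly. The
solver reports the achieved properties (`achieved_E`, `achieved_W`) and the
residual objective, so such cases are visible rather than silent. Targets
in the interior of the calibration hull are recovered within 5% (this is
the round-trip property the acceptance checks quantify).

The envelope guard (E ∈ [2, 20] kPa, W ∈ [40, 300] µm, conjugates ≤ 4 mM)
reflects the range over which this class of material has been
characterized; `validate_design()` additionally annotates conjugate
loadings in (4, 8] mM, which have been printed experimentally but lie
beyond the interpolated envelope.

### The monomer–initiator ellipse

The unified index is split by `split_peg_pi()`: the monomer concentration
equals the index, and the photoinitiator concentration is a real root of

$$\left(\frac{peg_{pi}-50}{40}\right)^2 +
  \left(\frac{PI-0.5}{0.35}\right)^2 = 1 .$$

Both roots are positive over the domain [10, 90], so "the positive real
solution" underdetermines the branch. The default is the **upper** branch,
$PI = 0.5 + 0.35\sqrt{1-((peg_{pi}-50)/40)^2}$, so that the initiator rises
with the index over the mid-range — consistent with stiffer prints needing
both more monomer and more initiator; the lower branch is selectable
(`branch = "lower"`). At the apices (index 10 or 90) the branches coincide
at PI = 0.5 and the residual is exactly zero.

The scan velocity is emitted as `100` with an explicit unit tag defaulting
to `mm min^-1`; the unit is configurable because reported values for this
class of printer vary between mm and µm per minute, and the plan format
should not silently commit to either.

## Print-plan compilation

`compile_plan()` solves one fabrication setting per *unique* region target
(identical targets share a solve, and hence a resist batch, exactly),
rasterizes rectangles with a serpentine fill pitched by the achieved
linewidth, and groups segments by resist composition. Raster rows overshoot
the rectangle edges by half a linewidth (`edge_overshoot`), because a
stadium-shaped filament footprint otherwise leaves uncovered corner
lunettes of area $(1-\pi/4)(W/2)^2$ per corner — with 250 µm filaments that
alone would violate 99% coverage of small regions. Batches are ordered
stiff-to-soft (descending monomer index), mirroring serial resist exchange
from the densest resist down; the number of exchanges is the number of
distinct compositions minus one, which is optimal for the contiguity
objective. Coverage is audited by `plan_coverage()` on a rasterized grid
(default 5 µm) against each region's geometry.

## Force spectroscopy

Approach curves relate piezo displacement $z$ (µm) to force $F$ (nN)
at a cantilever of stiffness $k$ (N/m). Post-contact, a conical indenter of
half-angle $\theta$ into an incompressible gel follows the Sneddon law

$$F = \frac{2}{\pi}\tan\theta\,\frac{E}{1-\nu^2}\,\delta^2,$$

with the indentation corrected for cantilever compliance,
$\delta = (z - z_0) - F/k$. Units are chosen so no constants appear:
1 kPa = 1 nN/µm². Defaults: $\theta = 18°$ (the conical equivalent of the
pyramidal tips typically used for soft gels) and $\nu = 0.5$
(incompressible hydrogel; configurable, since the value is rarely measured).

**Finite thickness.** A gel of thickness $h$ bonded to rigid glass appears
stiffer than it is. `becc_factor()` applies the four-term bonded-cone
bottom-effect series in $\chi = \delta\tan\theta/h$:

$$F = F_{Sneddon}\,[1 + 0.721\chi + 0.650\chi^2 + 0.491\chi^3 + 0.225\chi^4].$$

The same series is used in simulation and fitting, so the package's
correction-consistency checks (naive fits overestimate on 10 µm gels; the
corrected fit recovers truth; both agree within 1% once
$h \ge 100\times$ the maximal indentation) hold independent of the series'
third decimal. The leading term coincides with the classical first-order
bonded-cone result at $\nu = 0.5$.

**Contact point.** `detect_contact_point()` minimizes the residual of a
piecewise model — flat baseline before $z_0$, Sneddon-shaped growth in the
compliance-corrected indentation after — over a coarse grid of every 5th
sample, refined by golden-section search between the bracketing grid
points; ties resolve to the smaller $z_0$. Including the compliance term in
the detection model matters: without it the best-fit contact point of a
soft-gel curve shifts by many sample spacings, because the raw
force-displacement ramp is visibly sub-quadratic. `fit_modulus()` additionally
refines $z_0$ jointly with $E$ (the modulus enters linearly given $z_0$, so
the refinement is a cheap 1-D minimization), and labels fits
`rejected_fit` when the relative residual exceeds 5%.

**Slip rejection.** Slipping samples produce step discontinuities. The
detector in `qc_discontinuity()` measures, at every increment, an inner
difference of 5-sample running medians spanning the increment minus 5/19 of
an outer median difference with the same midpoint. For any locally
quadratic force trend the two differences cancel *exactly* (both evaluate
the same linear functional of a quadratic), so the smooth indentation ramp
and its curvature contribute nothing; a step discontinuity survives at
14/19 of its size. The threshold is `jump_sigma` (default 6) times the MAD
of the statistic over the curve; the MAD is immune to the isolated jump
itself, and a floor of 15% of the 99th-percentile raw increment keeps
near-noise-free curves — where the running median occasionally swaps
adjacent samples of a steep ramp, glitching by one increment — and the
slope kink at the contact point below threshold. Two simpler detectors were evaluated and discarded: raw
trend-corrected increments carry about twice the per-sample noise standard
deviation, and an explicit running-median slope estimate fluctuates slowly
enough to generate rare multi-sigma excursions — both produced occasional
false rejections of clean curves at the default settings. The shipped
checks exercise the paired median-difference statistic on 100 clean and
100 slipped curves (2 nN jumps, 0.05 nN noise) and on noise-free curves
at every stiffness level.

**Acquisition defaults** mirror common soft-gel practice: 0.5 µm/s
approach, termination at 10 nN, 0.05 N/m cantilever, 100 Hz sampling
(5 nm/sample), 0.05 nN force noise in simulation.

## Image quantification

Arrays are `(z, y, x)`; the niche frame is µm, origin lower-left, y up —
identical to the print-plan frame, so measured cells can be related to
printed regions directly.

**Segmentation stand-in.** Real pipelines segment nuclei with a trained
star-convex network; any such label image is accepted by the measurement
functions. The built-in `segment_nuclei_simple()` is a deterministic
classical fallback (Gaussian blur, Otsu threshold, distance-transform
watershed). For 3-D stacks it segments the maximum-intensity projection and
propagates labels through the thresholded volume — a monolayer assumption
appropriate for cells cultured *on* a niche surface, and explicitly not for
thick multi-layer tissue.

**N:C ratio.** Per cell: mean marker intensity over the nuclear voxels
divided by the mean over that cell's share of the non-nuclear cytoplasm.
Multi-cell fields are partitioned by nearest nuclear centroid (distances in
µm, respecting voxel anisotropy); cells with an empty cytoplasm share are
dropped and counted in the `n_dropped` attribute. The ratio is invariant to
any positive rescaling of the channel, so it is robust to illumination
gain but not to nonuniform background — background correction is the
caller's responsibility.

**fat:cyto.** Lipid voxels (Otsu within the cytoplasm by default, fixed
threshold overridable) over total cytoplasm voxels, per field of view.

**Alizarin score.** mean(R)/[mean(R)+mean(G)+mean(B)] over a region of
interest (logical mask or polygon; point-in-polygon via `mgcv::in.out`).
Achromatic regions score exactly 1/3, saturated red 1.

**Expression maps.** Per-replicate, per-channel intensities are rescaled to
[0, 1] between their 1st and 99th percentiles (min–max selectable); the
percentile default keeps single hot pixels from compressing the dynamic
range of a whole replicate. Cells are mapped into the common niche frame by
each replicate's affine transform, pooled, and binned into a mean surface;
cells landing outside the niche bounding box are excluded and counted, so
cell-count conservation is auditable. Per-region violin-style summaries are
computed when region annotations are supplied.

**Dose–response.** `fit_sigmoid()` fits the 4PL
$y = bottom + (top-bottom)\,d^{hill}/(d^{hill}+ec_{50}^{hill})$ by bounded
Levenberg–Marquardt with data-driven starts; EC50 is constrained to
[0.01, 100]× the positive dose range, the Hill slope to [0.1, 10].
Constant responses return a flagged degenerate `bottom == top` fit rather
than an error, because ladder experiments legitimately produce flat
channels.

## The synthetic generators

The generators define the conditions under which the package validates
itself; their defaults are fixed and not tuned per test.

- **Calibration** (`gen_calibration`): modulus
  $E = 2.6\,(x/10)^{0.92}e^{-0.02 z}$, linewidth
  $W = 45 + 35 z + 0.45 (x-10)$ over the default grid
  $x \in [10, 90]$ (step 5), $z \in [0, 6]$ mm (step 0.5) — monotone in the
  index, linewidth linear in defocus, both independent of conjugate
  loading, spanning E ≈ 2.3–19.6 kPa and W ≈ 45–291 µm inside the
  characterized envelope. Multiplicative noise, default CV 5% (a realistic
  replicate-to-replicate spread for AFM-verified prints). These functional
  forms are an *emulation* with the right monotone structure, not a
  reproduction of any measured surface; recovery results transfer to real
  tables only insofar as those are equally smooth and monotone.
- **Force curves** (`gen_force_curves`): contact points drawn uniformly in
  1.5–2.5 µm, per-curve seeds, optional slip events placed inside the
  indentation ramp; 0.05 nN noise default.
- **Image volumes** (`gen_niche_image`): a monolayer of non-overlapping
  ellipsoidal nuclei (default semi-axes 2×5×5 voxels) with cytoplasm shells
  (3×9×9), marker channels realizing prescribed N:C ratios, optional linear
  marker gradients along x, lipid droplets packed to an *exact* volume
  fraction (the realized fraction is returned as truth), and Poisson shot
  noise plus 2 ADU read noise. What these scenes do **not** emulate:
  optical blur and the axial PSF, intensity bleed-through between channels,
  segmentation errors of real nuclei, and dense multi-layer growth. Passing
  recovery tests therefore demonstrates the correctness of the measurement
  arithmetic and partitioning, not robustness to real microscopy artefacts.
- **Dose–response** (`gen_dose_response`): 4PL truth (default bottom 1,
  top 3, EC50 2 mM, Hill 2) over doses 0–8 mM, Gaussian noise 0.05.

## Problem sizes and determinism

The shipped checks run at the sizes the methods are meant for: 100
inverse-design round trips on a 221-record table, a 1000-point ellipse
sweep, 50 curves per stiffness level (2.5/7.5/20 kPa) for AFM recovery, 100
clean plus 100 slipped curves for QC rates, 25 cells per N:C level at four
levels, three lipid fractions, and 50 seeded dose–response datasets. Every
stochastic step takes an explicit integer seed; repeated runs are
bit-identical, and changing only the seed changes noise realizations, never
the structure of the data.

## Known limitations

- The kernel interpolant is only as good as the calibration grid; edge
  bias (above) means envelope-extreme targets are matched best-effort.
- Print plans are single-layer; multi-layer lattice geometries are
  representable as designs but no z-stacking logic is provided.
- The bottom-effect series assumes a bonded sample and a conical tip; very
  shallow indentations of very thin gels (χ > ~0.5) leave its validated
  range.
- The segmentation stand-in is intentionally simple; for crowded or
  three-dimensional tissue, supply label images from a dedicated tool.
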