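---
title: "Quantifying smoothing-induced signal mixing between STN and SN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying smoothing-induced signal mixing between STN and SN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subcortmix)
```

## The problem

The subthalamic nucleus (STN) is a basal-ganglia nucleus of roughly 120 mm^3
— a few voxels at typical BOLD fMRI resolutions — sitting directly
dorso-latero-anterior to the much larger substantia nigra (SN). Their
centres of mass lie only about 6.4 mm (left) and 6.7 mm (right) apart.
Gaussian spatial smoothing, a standard fMRI preprocessing step with kernels
of 4-12 mm FWHM, therefore mixes the signals of the two nuclei and of the
surrounding tissue, making it hard to attribute an activation to either
structure. `subcortmix` quantifies that mixing and, separately, summarises
how far STN/SN activation coordinates reported in the literature lie from
probabilistic-atlas centres of mass.

## The mixture model

Every voxel of a nucleus mask is assumed to carry unit signal. After
smoothing with an isotropic Gaussian of standard deviation
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$, the signal observed at a point
$p$ contains, from each nucleus $X$, the mass

$$\mathrm{mass}_X(p) = \sum_{v \in X} \exp\left(-\sum_{d}
  \frac{(v_d - p_d)^2}{2\sigma_d^2}\right),$$

the sum running over the voxel centres of the mask. Dividing by the total
kernel mass over the full voxel lattice (so that a unit signal everywhere
would give exactly 1) turns the masses into fractions; the remainder
$1 - f_{STN} - f_{SN}$ is attributed to tissue outside both nuclei. The
evaluation point is each nucleus' *centre voxel* — the grid voxel nearest
its binary centre of mass — emulating a region-of-interest analysis placed
at the best possible location. A zero-FWHM kernel is treated as a delta, so
without smoothing the centre voxel contains only its own nucleus' signal,
exactly.

Numerical choices worth stating:

* **Kernel sampling.** The Gaussian is evaluated at voxel centres, matching
  the sum-of-exponentials definition above, not integrated over voxel
  volumes (a voxel-integrated variant would differ at coarse grids; at
  0.5 mm it is negligible).
* **Normalisation.** The normalising constant is the *converged* lattice sum
  (terms to 9 sigma, below double precision), independent of the grid
  extent, so mixtures do not depend on how much empty space surrounds the
  masks. The kernel truncation (default 6 sigma) limits only which mask
  voxels and convolution taps are visited; results at truncation 4 vs 6
  agree to better than 1e-4.
* **Degenerate inputs.** Empty masks, mismatched grids and points outside
  the grid are errors; FWHM 0 is the identity, not an error.
* **Oracle.** For a spherical mask evaluated at its centre the fraction has
  the closed form $P = \mathrm{erf}(z/\sqrt 2) - \sqrt{2/\pi}\,z\,e^{-z^2/2}$
  with $z = r/\sigma$ (the chi distribution with 3 degrees of freedom),
  implemented independently as `sphereFraction()` and used in the tests to
  validate the voxel-sum path to 0.01.

The related acquisition-grid bound `discreteVoxelLeakage()` asks a different
question: on a coarse EPI grid (say 3.4 x 4 x 4 mm), how much of a voxel's
smoothed value originated *outside that voxel*? The discrete kernel sampled
at acquisition-voxel centres is normalised to sum to one and the answer is
one minus the central weight — separable, exact, and well under 0.2% for a
2 mm kernel on such a grid, which is why tiny kernels on coarse grids are
effectively no-ops.

## The synthetic anatomy

The simulation needs cohorts of paired STN/SN masks. The generator emulates
the study conditions of a 30-subject, two-rater, 0.5 mm isotropic 7T
segmentation cohort with rotated-ellipsoid phantoms:

* **STN**: mean conjunct volume 119.88 mm^3 (the weighted literature
  average), semi-axis ratio 1.3 : 1.05 : 1 with the short axis along the
  STN-to-SN separation direction; per-subject volumes N(119.88, 14) mm^3.
* **SN**: 550 mm^3 (no literature consensus value is pinned here; this sits
  in the 7T segmentation literature range), ratio 3 : 1.5 : 1, its long axis oblique
  antero-posterior and its medium axis tilted 49 degrees off the contact
  axis so the SN's broad face lies directly ventro-medial to the STN
  without intersecting it.
* **Separations**: centre-to-centre 6.4 mm (left) and 6.7 mm (right) along
  the unit vector (0.30, -0.40, -0.86) (medial, posterior, ventral),
  mirrored for the right hemisphere.
* **Jitter**: per-axis centre jitter SD 0.3 mm and orientation jitter SD 3
  degrees, emulating residual inter-subject variability after linear
  registration to MNI space.
* **Conjunct-rater emulation**: with probability 0.5 a subject's mask is
  eroded by one voxel (6-connectivity), standing in for the conservative
  intersection of two raters; volumes are calibrated *post*-erosion, so
  every realized mask volume is within a few per cent of its drawn target.
* **Disjointness**: STN and SN masks may never share a voxel. If jitter
  makes them touch, the SN is nudged apart along the separation axis in
  0.25 mm steps (at most ten), which preserves the configured separations
  to within ~0.2 mm at the cohort level.
* **Determinism**: one integer seed; each subject uses a substream at a
  fixed offset, so enlarging the cohort never changes earlier subjects.

A probabilistic atlas is the voxelwise fraction of subjects whose mask
contains the voxel, exactly as a real multi-subject atlas is assembled, and
reference centres of mass for the meta-analysis are computed from these
maps (probability-weighted by default; a threshold option gives binary
centres instead — published atlases do not always state which convention
was used, so both are provided).

### What the phantom does and does not capture

The ellipsoid cohort reproduces the sizes, separations, orientations and
population variability of the real nuclei, and the resulting mixture curves
at the STN centre voxel match the reported values closely at FWHM 8 mm
(about 75% from outside both nuclei, 10% from the SN, 15% from the STN) and
for the elsewhere/STN split at FWHM 4 mm (about 34% vs the reported 30%
outside, 63% vs 60% from the STN). One reported quantity is *not*
attainable with this geometry: the 10% SN contribution at FWHM 4 mm. In
real anatomy the SN's dorsolateral surface hugs the STN's ventral face over
a broad curved interface, so substantial SN tissue sits within 2-3 mm of the
STN centre. Two disjoint ellipsoids whose centres are held 6.4 mm apart can
bring at most a narrow cap of SN that close: the SN share at FWHM 4 tops
out near 5% under contact (and about 3% under realistic jitter). We report
this as a known limitation rather than distorting the anatomy (e.g.
non-ellipsoidal shells) to force it; shapes beyond rotated ellipsoids are
deliberately out of scope. Passing tests on the synthetic cohort therefore
validate the mixture *machinery* everywhere, and the mixture *magnitudes*
at the 8 mm kernel; conclusions at small kernels about SN-specific
contamination are conservative lower bounds.

The phantom also ignores MR-specific effects by design: no EPI distortion,
no registration error beyond rigid jitter, no BOLD time-series or
hemodynamics — signal is a unit-strength spatial indicator.

## The coordinate meta-analysis

The packaged table transcribes a literature overview of 52 BOLD fMRI
studies reporting STN or SN activation coordinates (122 rows; one row per
reported coordinate, study-level fields repeated; unspecified entries kept
as missing; all coordinates already in MNI space — those originally in
Talairach space were converted by the source with the Lancaster transform,
whose pooled matrix ships with the package for users with raw Talairach
coordinates). Deviations are focus minus reference centre of mass, signed
per axis (positive x right, y anterior, z superior) plus the per-focus
Euclidean distance, summarised as mean (sample SD, n-1) per structure label
and hemisphere. STN foci are referenced to the STN centre of mass; SN,
SN/VTA and SN/STN foci to the SN. Hemispheres are assigned by the sign of
x with x = 0 grouped right, which reproduces the published left-hemisphere
group sizes exactly (SN 12, SN/VTA 17, STN 20). The published
right-hemisphere group sizes (SN 18, SN/VTA 17, STN 17 from 14 studies)
cannot be reconstructed from the published study table itself, which yields
15, 21 and 24 from 10, 12 and 12 studies; the package reports what the
table supports and flags the discrepancy here rather than matching either
set of numbers by construction. The same applies to two summary statistics:
the source reports 47 of 52 studies with a voxel resolution, while its own
table supports 48 (only four studies leave a dimension unspecified), and
the kernel/voxel aggregation rule (averaging within studies reporting
several values, excluding unspecified ones) is the simplest reading that
reproduces the printed median of 6 mm, the 16-study count for the 8 mm
mode, and the 34 mm^3 mean voxel volume.

## Problem sizes and runtime

The default pipeline — 30 subjects x 2 hemispheres, 0.5 mm grids of roughly
130^3 voxels per hemisphere, eleven kernel sizes — runs in about a minute on
a single core; the two-kernel acceptance run takes ~20 s. Unit tests use
2-8-subject cohorts with the same anatomy defaults. Gaussian smoothing of
full fields is separable and implemented as banded matrix products per axis;
mixture evaluation sums only over mask voxels and is exact to the stated
truncation.

## A worked example

```{r example, eval = FALSE}
cfg <- cohortConfig()            # the defaults described above
cohort <- generateCohort(cfg)
curves <- simulateCohort(cohort, fwhms = c(0, 4, 8))
subset(curves@summary, destination == "STN" & fwhm_mm == 8)
#   fwhm_mm destination    source mean_fraction sd_fraction  n
#         8         STN elsewhere        0.7551      0.0179 60
#         8         STN        SN        0.0899      0.0146 60
#         8         STN       STN        0.1550      0.0153 60

discreteVoxelLeakage(c(3.4, 4, 4), 2)
# 0.000723  — a 2 mm kernel on a 3.4 x 4 x 4 mm grid leaks < 0.1%

foci <- loadFoci()
kernelSummary(foci)$median       # 6 (mm)
deviationStats(foci, atlasComTable(cohort))
```

## Known limitations

* Rotated ellipsoids cannot reproduce the broad curved STN/SN interface;
  the SN share of the STN-centre signal at small kernels is underestimated
  (see above).
* The overlap-repair rule censors close-proximity jitter, biasing realized
  centre separations upward by ~0.1-0.2 mm.
* The centre voxel is the voxel nearest the binary centre of mass; for the
  near-convex phantoms this is unambiguous, but for strongly non-convex
  real masks the fallback (nearest in-mask voxel) is a convention.
* Real-data deviations (e.g. the ~5 mm mean distances of reported STN foci
  from atlas centres) require the published probabilistic masks, which are
  downloadable but not shipped; `readVolume()` + `deviationStats()`
  recompute them when the files are supplied.
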