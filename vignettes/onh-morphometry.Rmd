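---
title: "Quantifying optic nerve head morphology from segmented OCT geometry"
author: "onhmorph contributors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying optic nerve head morphology from segmented OCT geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onhmorph)
```

## The measurement problem

The optic nerve head (ONH) is the weakest point of the corneoscleral shell:
intraocular pressure (IOP) pushes on it from the front and retrobulbar
cerebrospinal fluid pressure from behind, and their difference across the
lamina cribrosa (the translaminar pressure difference) deforms the
neuroretinal rim on time scales from minutes to hours. Modern OCT devices
acquire radial B-scans through the ONH plus circumpapillary circles, and the
clinically used structural read-outs are geometric quantities defined on the
*segmented* layer boundaries, not on pixels. `onhmorph` starts exactly
there: its inputs are layer polylines, manually marked Bruch's membrane
opening (BMO) and anterior lamina cribrosa surface (ALCS) points in physical
micrometres, plus per-session physiology, and its outputs are the standard
ONH parameters and the cohort statistics used in diurnal studies.

## Coordinate conventions

A radial acquisition is 24 B-scan diameters spaced 7.5 degrees apart,
sharing a rotation centre (`s = 0`). Each B-scan plane is vertical; a sample
at lateral position $s$ and axial position $z$ on the scan at angle
$\theta$ maps to $(x, y, z) = (s\cos\theta, s\sin\theta, z)$. The axial
axis points toward the vitreous, so anterior displacement is positive --
this is why BMO height and lamina depth of healthy eyes are negative
numbers. Transverse scaling (corneal-curvature correction) is assumed to
have been applied by whatever produced the segmentations; the package only
carries units. Eye laterality is stored but never used to mirror
coordinates.

## The structural parameters

**Minimum rim width (BMO-MRW).** For each of the 48 marked BMO points (2
per B-scan) the Euclidean distance, in the B-scan plane, to the nearest
point of the linearly interpolated internal limiting membrane (ILM),
searching only the ILM arc between the two BMO points of that B-scan.
Restricting the search to the inter-BMO arc prevents spurious minima on the
peripheral retina. Equidistant minima resolve to the foot point with
smaller $|s|$ so output is deterministic. The global value is the
arithmetic mean of the 48 point values. We compute MRW per B-scan plane
rather than as a full 3-D search: the marks exist per plane, and on
phantoms the difference is far below the 0.5 um oracle tolerance at 7.5
degree spacing.

**BMO area.** A least-squares plane is fit through the 48 BMO points
(SVD), the points are projected into it, and a direct least-squares conic
fit constrained to an ellipse (Fitzgibbon's method in the numerically
stable Halir-Flusser partitioned form) gives in-plane semi-axes $a, b$;
area is $\pi a b$. On exact elliptical samples the fit recovers $a$, $b$
and the area to better than $10^{-6}$ relative; on a 48-point circle of
radius 800 um with 5 um coordinate noise the axes agree with a nonlinear
orthogonal-residual fit to a fraction of a micrometre.

**BMO height.** Per B-scan, Bruch's membrane (BM) is interpolated at
$s = \pm 2000$ um and the chord through those points is the 4-mm reference
line; BMO height is the signed perpendicular distance of each BMO point
from that chord (anterior positive), averaged over all 48 points. We use a
per-B-scan chord, not a fitted 3-D plane, matching how the reference is
drawn on individual radial scans.

**Lamina depth (BMO-ALCSD).** Mean signed perpendicular distance from the
traced ALCS to the chord joining the two BMO points, using only samples
whose perpendicular foot falls in the central 50% of the chord (25%-75% of
its length) -- peripheral laminar curvature is thereby excluded. A B-scan
without an ALCS trace, or with fewer than 3 samples in the window, yields a
missing value rather than an error, since the lamina is typically visible
in only a majority of B-scans; the session value averages the B-scans that
have one.

**Total retinal thickness (TRT) map and annuli.** TRT is the axial ILM-BM
distance. A polar map (default 1 degree x 10 um) is built by linear
interpolation in radius along each of the 48 half-lines and
circumferentially between adjacent half-line angles. Annular means are then
taken over eccentricity bands 0-250, 250-500, 500-1000 and 1000-1500 um,
where eccentricity is measured *outward from the BMO ellipse boundary*
along rays from the ellipse centre -- so "BMO to 250 um" starts at the rim
margin. Cells are area-weighted ($\propto r$); an annulus with more than
25% of its area unmapped is invalidated with a warning. With a mean BMO
area of 2.04 mm^2 (equivalent diameter ~1600 um) the four standard circles
sit at eccentricities of about 550, 950, 1300 and 1650 um from the margin,
which is what `circle_eccentricity()` computes.

**Circumpapillary means.** On each circular scan the per-sample axial
thicknesses (RNFL = ILM minus RNFL posterior boundary; TRT = ILM minus BM;
choroid = BM minus choroid/sclera interface) are averaged with trapezoidal
angular-gap weights over the valid samples; masked samples contribute
neither value nor weight, and a scan with more than 25% masked is rejected
outright. Thickness is axial rather than normal-to-BM -- the convention of
the clinical devices; at circumpapillary eccentricities the difference is
well below the layer SDs (an open point we resolve and flag here).

## Pressures and sheath diameter

IOP is the mean of a rebound-tonometry triplet. Mean arterial pressure is
$\mathrm{MAP} = (2\,\mathrm{DBP} + \mathrm{SBP})/3$ and mean ocular
perfusion pressure applies a hydrostatic correction for the vertical
distance between the brachial cuff and the eye:

$$\mathrm{MOPP} = \mathrm{MAP} - 0.77\,\frac{\text{mmHg}}{\text{cm}}\cdot d_{\text{cuff-eye}} - \mathrm{IOP}.$$

The sign convention ($d > 0$ when the eye is above the cuff) is the
package's choice; it is the one under which head-down tilt -- where the eye
drops below the cuff -- *raises* MOPP even while MAP falls, the behaviour
reported in diurnal tilt experiments. Optic nerve sheath diameter is read
off an ultrasound trace: the point 3 mm along the nerve axis (arc length,
not straight-line depth -- a deliberate choice, flagged as such) behind the
globe is located, the perpendicular to the local tangent is erected, and
the distance between its intersections with the two sheath boundaries is
returned. The measurement is exactly invariant under rigid motions of the
whole trace.

## Repeatability and diurnal statistics

With duplicate scans per subject, the within-subject standard deviation is
$S_w = \sqrt{\sum_i d_i^2 / 2n}$ (equivalent to the root mean square of a
one-way within-subject ANOVA), repeatability is $2.77\,S_w$ -- the expected
bound on the difference between two repeated measures -- and
$\mathrm{CV} = 100\,S_w/|\bar x|$. The absolute value in the denominator is
the package's decision for signed parameters whose mean sits near zero
(BMO height): their CV is large and should be read as such, not as a
failure of the measurement.

Change-from-baseline tables subtract each subject's 7 a.m. seated value;
subjects without a baseline are excluded and logged, mirroring the listwise
handling of incomplete blood-pressure panels in practice. Session effects
are tested with one-way repeated-measures ANOVA followed by two-sided
Dunnett many-to-one comparisons of every later session against baseline, on
raw values with the baseline as reference level (change tables are for
reporting; the contrast of raw values is identical because subtracting a
per-subject constant leaves the within-subject sums of squares unchanged).
No correction is applied *across* parameters -- deliberately, matching the
study designs this package serves.

**Dunnett probabilities without external packages.** For a balanced design
the contrast statistics are equicorrelated with $\rho = 1/2$ and share the
error variance, so

$$P\!\left(\max_i |T_i| \le q\right) \;=\; \mathbb{E}_{S}\,\mathbb{E}_{Z_0}
\prod_{i=1}^{k}\Big[\Phi\big(z_0 + q\sqrt{2}\,s\big) - \Phi\big(z_0 - q\sqrt{2}\,s\big)\Big],$$

with $Z_0 \sim N(0,1)$ and $S^2 \sim \chi^2_\nu/\nu$. The package
evaluates this by Gauss-Hermite (48 nodes, $z_0$) times Gauss-Legendre (48
nodes, probability transform of $S$) quadrature. Accuracy: ~$6\times
10^{-6}$ against the exact $t$ distribution at $k=1$ and within Monte-Carlo
error of a $2\times10^5$-draw simulation of the joint null at $k \in \{4,
6\}$. This deterministic route replaces a Monte-Carlo fallback; there is no
seed sensitivity in reported p-values.

Under a 1000-replicate null simulation ($n = 30$, 7 sessions, noise at the
BMO-MRW within-subject SD) the family-wise type-I error of the procedure
falls within three Monte-Carlo standard errors of the nominal 0.05, and an
injected -10 um step at every post-baseline session ($\sigma = 4.4$ um) is
detected at every contrast in >=95% of replicates -- both checked in
`tests/testthat/test-acceptance.R`, which is where every number quoted in
this vignette is computed.

## What the synthetic generators emulate -- and what they do not

**Phantoms** (`phantom_spec()` / `make_phantom()`) are fully analytic
eyes: an elliptical BMO (defaults $a = 900$, $b = 720$ um, area 2.036 mm^2)
on a plane sunk 102 um below the peripheral BM plane, a cosine BM taper
completing within the 4-mm reference chord, a rim/cup ILM whose thickness
at the margin is `rim_h` (default 403 um, so TRT250 lands near 395 um with
the default -0.065 um/um radial slope), a flat or quadratically bowed
lamina 440 um below the BMO plane, and linear RNFL/choroid eccentricity
profiles anchored to healthy circumpapillary means. Defaults were set from
the healthy-baseline ranges and then frozen. Ground truth is computed by
dense evaluation of the analytic surfaces (0.1 um lateral resampling for
rim distances; 2-D quadrature for annuli) -- never through the measurement
pipeline -- so phantoms are genuine oracles. The closed-form special case
`cup_depth = 0` (flat inner shelf) makes MRW equal `rim_h` exactly and is
used for exactness tests; note the rim radius must lie on the lateral
sampling grid for the shelf case to be exact to machine precision, because
a clipped ILM endpoint otherwise interpolates across the BM-taper kink
(about 4e-3 um at a 25 um grid).

Phantoms add independent Gaussian axial noise (default 2 um, a realistic
segmentation jitter) to every sampled coordinate. They do **not** emulate
vessel shadows, segmentation bias near the rim, registration error between
B-scans (the radial lines are assumed exactly concentric), or transverse
scaling error. A green oracle test therefore establishes that the
*geometry code* is correct to its stated tolerances, not that the pipeline
is robust to all failure modes of real segmentations.

**Cohorts** (`cohort_sim_spec()` / `simulate_cohort()`) draw per-subject
baselines from the healthy-population means and SDs, within-subject noise
at the Table-of-repeatability $S_w$ values (IOP 1.0 mmHg and ONSD 0.15 mm
are the package's own choices -- repeatability tables for those are not
published), and inject the reported diurnal structure: rim width declining
linearly from 7 a.m. to 3 p.m. then plateauing (total -13.56 um in females,
-5.55 in males), TRT250/TRT500 ramps, a mid-day choroidal trough, a
late-day blood-pressure rise, and -- in the tilt arm -- IOP and sheath
diameter steps (+4.37 mmHg decaying to +2.5; +0.43 mm sustained), an
anterior BMO drift, suppressed rim thinning, and a seated endpoint session.
The trajectory *shapes* are the package's parameterisation of a
qualitatively described pattern; every effect size, SD and shape is a
config field so none of this is hard-coded. Measurement noise is
independent across sessions -- within-day autocorrelation of segmentation
error is unknown and deliberately not invented. MOPP and MAP are not drawn
directly: SBP/DBP, the tonometry triplet and the cuff-to-eye distance are
simulated and the pressure formulas derive the rest, so the simulator
exercises the same code path as real session tables.

## Numerical choices

* JSON writers use 17 significant digits so write/read is bit-for-bit.
* The ellipse fit rescales coordinates to mean radius 1 before the conic
  solve (conditioning); the plane basis is the deterministic projection of
  the global x-axis, so orientations are reproducible.
* TRT map grid defaults 1 degree x 10 um; annuli sample eccentricity at
  5 um midpoints; linear profiles are integrated exactly by construction,
  and smooth phantoms stay within 1 um of 2-D quadrature.
* MRW ties (exactly equidistant ILM points) break toward smaller $|s|$.
* Degenerate inputs fail loudly with classed conditions
  (`onh_coverage_error`, `onh_fit_error`, `onh_degenerate_error`, ...):
  zero within-subject variance refuses to emit p-values, collinear
  regressors refuse to fit, a BM not spanning 4 mm refuses a BMO height.
* All simulation is driven by explicit integer seeds; the pipeline derives
  per-stage seeds from the master seed and re-running a config is
  byte-identical.

## Limitations

Sectoral (non-global) parameters, minimum rim *area*, lamina curvature
indices beyond ALCSD, conversion of sheath diameter to cerebrospinal fluid
pressure, and translaminar pressure difference as a number are all out of
scope. The statistics layer implements the specific design it was built
for -- balanced two-hourly sessions against a 7 a.m. baseline with
duplicate-scan repeatability -- and the $S_w$ formula is the duplicate-pair
special case, not the general $k$-replicate estimator. Real `.vol` parsing
and any pixel-level segmentation are explicitly not goals: the package
begins where segmentation ends.
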