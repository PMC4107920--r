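---
title: "Serial synchrotron crystallography with ssxtools: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial synchrotron crystallography with ssxtools: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssxtools)
```

# The experiment this package models

Serial synchrotron crystallography (SSX) determines a macromolecular
structure from many short still exposures of individual microcrystals in
random orientations, instead of a rotation series on one large crystal.
In the capillary-flow variant implemented here, a slurry of micron-scale
crystals is pushed through a thin capillary across a microfocus beam
while the detector free-runs at a fixed frame rate. A crystal's exposure
time -- and hence its dose -- is set by the time it takes to transit the
focus. Most frames are blank; frames containing diffraction are found by
peak searching, indexed one at a time against the known unit cell,
integrated at predicted spot positions, and merged by plain (Monte
Carlo) averaging over all measurements of each unique reflection. With
enough patterns, the stochastic per-snapshot factors -- crystal size,
transit time, partiality, orientation -- integrate out.

`ssxtools` implements that whole chain twice over: once as closed-form
beamline arithmetic and a processing pipeline, and once as a synthetic
frame generator with known ground truth, so that every processing stage
can be validated quantitatively without the multi-terabyte raw frame
archive of a real beamtime.

# Beamline and microfluidics arithmetic

The `physics` layer is deliberately closed-form. Conversions use
$\lambda = hc/E$ with $hc = 12398.42$ eV·Å (9800 eV gives 1.265 Å,
commonly quoted rounded to 1.27 Å). Capillary flow is modelled as
Newtonian laminar (Poiseuille) flow: mean velocity $\bar v = Q/\pi R^2$,
profile $v(r) = 2\bar v (1 - r^2/R^2)$. For the default 2.5 µl/min in a
100 µm capillary, $\bar v = 5.3$ mm/s and the centerline moves at twice
the mean. Note that the exact parabolic value 10 µm from the wall is
$0.72 \times$ centerline (3.8 mm/s at the default flow); a commonly
quoted "3 mm/s" is a rounding of this quantity at $\bar v = 5$ mm/s
(3.6 mm/s exactly). The package always reports the exact value.

The Reynolds number $\rho \bar v D / \mu$ depends on the slurry
viscosity, which is a configuration input: a dense PEG-containing
crystal suspension is far more viscous than water, and the default of
46 mPa·s places the flow deep in the laminar regime (Re ≈ 0.01). The
flow of a real slurry is additionally perturbed by the crystals
themselves; the package does not model that turbulence explicitly but
represents its effect as transit-time jitter in the simulator (below).

The absorbed dose uses a thin-sample, monochromatic mass-energy-
absorption model: fluence $\times$ photon energy $\times \mu_{en}/\rho$,
with a small shipped table of water coefficients (5--20 keV,
interpolated log-log). This is a deliberate simplification of a full
dose program -- no photoelectron escape, no explicit atomic composition
-- adequate for the order-of-magnitude budgeting the method needs
(about 0.1 MGy per 3 ms transit at the default beam, versus tolerable
room-temperature doses of a few hundred kGy).

# The synthetic frame generator

`simulateDataset()` renders photon-count frames with a ground-truth
sidecar. Its components, and what each emulates:

* **Crystal arrivals.** The number of crystals in a frame is Poisson
  with configurable mean (default 0.3, which puts about a quarter of
  frames in the hit class); `crystals_per_frame = 1` forces exactly one
  crystal for parameter-recovery studies. Orientations are i.i.d.
  uniform over rotations (Shoemake quaternion sampling).
* **True intensities.** Per-ASU amplitudes are drawn once per dataset
  from an acentric Wilson distribution: $|F|^2 \sim$ Exp with shell mean
  $\propto \exp(-B s^2/2)$, $s = 1/d$, default $B = 44.1$ Å². Centric
  zones are not given their separate distribution; for the merging and
  recovery statistics exercised here the distinction is immaterial, and
  the Wilson-plot fit it feeds is linear either way.
* **Partiality.** A still exposure records only part of a reflection.
  The generator uses the standard stills approximation: a Gaussian
  rocking profile in excitation error $\zeta$ (distance of the
  reciprocal node from the Ewald sphere), with effective width the
  quadrature sum of mosaicity (default 0.05°), beam divergence (1 mrad)
  and bandwidth ($10^{-4}$) terms. Reflections within $\pm 3$ widths are
  rendered with partiality $\exp(-\zeta^2/2\sigma^2)$.
* **Exposure spread.** Spot intensities scale with transit time, drawn
  from the Poiseuille-profile-induced distribution over the usable
  capillary cross-section (10 µm wall margin) and truncated to 1--3 ms
  -- the truncation standing in for the turbulence the laminar model
  omits. A lognormal size factor (sd 0.25) models crystal-volume
  scatter.
* **Rolling.** A configurable fraction of crystals (default 10%,
  chosen as "occasional") rotates about the beam axis during exposure,
  smearing spots into constant-radius arcs of 5°.
* **Background and noise.** Flat 0.5 photons/px plus a water ring
  centered at 3.5 Å pseudo-resolution (amplitude 2 photons/px, width
  0.04 Å⁻¹ in $|q|$), all Poisson-sampled. No published per-pixel
  background exists for this geometry, so these levels are declared,
  not fitted; they put the background-subtraction error of a
  high-resolution spot at about ±7 photons.
* **Point-spread.** Spots are 2D Gaussians of 1 px sigma. Real hybrid
  pixel detectors are sharper; a wider PSF is the conservative choice
  for testing centroiding and integration tail losses.

**The simulation detector.** The default panel is 600×600 pixels of
0.7 mm at 300 mm -- the same angular range (2.1 Å at the center edge at
1.265 Å) as the full-size 2463×2527 panel, at a pixel count tractable
for repeated simulation. The full-size geometry is available as
`pilatus6M()` and is used for the closed-form geometry checks. The
intensity scale default (5000 photons per unit Wilson intensity at full
partiality and reference transit) was chosen once so that a typical
single-crystal frame yields tens of detected peaks above the 25-count
threshold -- the "strong pattern" regime the 15/200 selection band
targets -- and so that a fully-recorded reflection at 2.1 Å carries a
few tens of photons, the scale reported for real high-resolution spots.

What the generator does *not* emulate: absorption and polarization
factors, detector module gaps and point-spread tails, non-isomorphism
between crystals, twinning, and the long-tailed background of real
capillary scatter. Pipeline statistics on simulated data therefore
bound what the code can do on ideal data; they do not certify
performance on any particular real dataset.

# Processing chain

**Peak finding** is a gradient search: pixels at or above the threshold
are walked uphill to their local maximum; a connected region is grown
while counts exceed the local background plus $k\sigma$ (default
$k = 2$); the centroid is the background-subtracted count-weighted
mean. The local background is the median of a surrounding square ring
(half-width 7 px). The 25-count threshold is applied to the
*background-subtracted* maximum -- a decision, since either convention
is defensible; with the sub-photon flat background of the simulator the
two differ by at most a few counts. Frames are classed blank
($n \le 15$ peaks), hit ($15 < n < 200$) or multi ($n \ge 200$), with
strict inequalities.

**Indexing** assumes the cell is known (the usual SSX situation) and
searches orientations only. A quasi-uniform quaternion grid
(super-Fibonacci spiral, default 1.5° step) is reduced by the 422
orientation degeneracy to one representative per point-group orbit
(~130k orientations), scored by counting scattering vectors within
0.45 reciprocal-spacings of a lattice node -- a single BLAS
multiplication per frame. The 30 best candidates are polished by
iterating nearest-node assignment with a shrinking tolerance and
re-solving the rotation in closed form (SVD/Kabsch). Success requires
at least half the peaks (and at least 6) within the assignment
tolerance (0.8 × half the minimum node spacing) *and* an rms residual
below half that tolerance after refinement. The residual gate is what
separates true lattices (residuals dominated by sub-pixel centroid
error, far below tolerance) from the best random orientation of a
non-lattice peak set (residuals uniform up to the tolerance radius,
rms ≈ 0.77 × tolerance); without it, maximizing over 10^5 orientations
occasionally "indexes" noise. Any symmetry-equivalent orientation is
accepted; downstream ASU mapping makes the results invariant.

**Cell refinement** alternates two closed-form steps: linear least
squares for $a^*, c^*$ under the tetragonal constraint at fixed
orientation, and Kabsch re-refinement of the orientation at the fixed
cell. Peaks sit on the Ewald sphere while nodes sit slightly off it, so
even noiseless data refine to a small nonzero residual (the excitation
error scale, ~10⁻⁴ Å⁻¹); exact node positions refine to numerical zero.
Ill-conditioned systems (fewer than six assigned peaks) keep the prior
cell.

**Integration** predicts *all* reflections inside the acceptance window
out to the detector corner -- including those with no detected peak,
deliberately merging weak signal at high angle -- and integrates a
13-pixel disc ($r = 2$, center-of-pixel rule) minus the per-pixel
background estimated from a 4--8 px annulus. The annulus statistic is
the median (robust to a neighboring spot in the annulus; the mean is a
config option). Sigma is Poisson-propagated:
$\sqrt{\Sigma_{disc} + n_{disc}^2 \mathrm{var}(annulus)/n_{annulus}}$.
Discs that leave the panel, or annuli more than half masked, are
flagged invalid and excluded. Overlapping predicted discs are both
retained -- Monte Carlo averaging, not deconvolution, is the error
model. Integration is at predicted centers without re-centering on the
observed peak. About 14% of each spot's photons fall outside $r = 2$
for the 1 px PSF; this constant tail loss cancels in all ratio
statistics and in the Wilson slope.

**Merging** is a plain unweighted mean per ASU reflection -- no
per-frame scaling -- with sigma the standard error of the mean from the
measurement scatter. This is the Monte Carlo scheme: convergence is
$\propto 1/\sqrt{n}$ in the number of patterns, which the convergence
analysis verifies by resampling pattern subsets. Negative merged
intensities are retained.

**Quality metrics.** Frames (never individual measurements) are
assigned at random to two halves, so CC½ compares genuinely independent
merges. $R_{split} = 2^{-1/2} \sum|I_1 - I_2| / \frac12\sum(I_1+I_2)$
includes the conventional $1/\sqrt2$ factor extrapolating half-set
disagreement to the full set. CC* $= \sqrt{2CC/(1+CC)}$; for negative
CC½ in $(-1/3, 0)$ the signed extension $-\sqrt{-2CC/(1+CC)}$ keeps the
transform monotone (a negative CC* simply flags an inconsistent shell),
and at or below $-1/3$ it is undefined. Shells are ten equal volumes of
reciprocal space; overall values are computed over all common
reflections, not averaged over shells. Completeness divides observed
unique reflections by a brute-force enumeration of non-absent ASU
reflections in the same range. The Wilson B is the slope of
$\ln\langle I\rangle$ versus $s^2/2$ over 8 Å to the data edge,
excluding non-positive shell means.

# Numerical and interface conventions

Pixels are 0-based with images stored `image[slow + 1, fast + 1]`;
positions are in mm from the beam center; the beam runs along +z.
Scattering vectors use $|q| = 2\sin\theta/\lambda$ (so $d = 1/|q|$)
with full Ewald curvature everywhere -- no small-angle approximation.
The ASU representative under Laue group 4/mmm is the lexicographically
largest image over all 16 operations ($h \ge k \ge 0$, $l \ge 0$),
which makes the mapping idempotent by construction. All randomness is
seeded; the orientation grid is deterministic; a dataset simulated
twice with the same seed is bit-identical.

Frame stacks persist as a directory of per-frame TSV matrices with a
JSON geometry descriptor and TSV truth sidecars -- plain text, diffable,
and trivially adapted to other containers by reimplementing two reader
functions. Merged data are TSV `h k l d I sigma n` tables.

# Problem sizes

The test-suite and acceptance computations use the reduced detector and
these scales, chosen so that each check constrains what it should at
comfortable statistical margins: 200 rendered frames for cell-parameter
recovery (the published per-frame scatter of ±0.3 Å makes the mean over
~190 indexed frames precise to ~0.02 Å); 600--1200 measurement-level
patterns for merging statistics, Wilson-B recovery and the
$1/\sqrt n$ convergence law; 10--50 rendered frames for peak-finder
recall and false-positive rates.

# Known limitations

* Space group support is P4₃2₁2 (and its point/Laue groups) only; the
  symmetry machinery is table-driven and small, but other groups would
  need their operator sets and absence rules added.
* Indexing requires a known cell; there is no ab initio autoindexing
  and no multi-lattice deconvolution (multi-crystal frames are rejected
  by the 200-peak bound, as in the experiment).
* No per-reflection partiality correction or post-refinement: accuracy
  comes from redundancy alone, so quality degrades gracefully but
  slowly with pattern count.
* The dose model ignores composition and photoelectron escape; it is a
  budgeting tool, not a damage simulation.
* The simulator's background and PSF defaults are declared rather than
  fitted to any measured frames; absolute detection rates on real data
  will differ.
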