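---
title: "Methods: OMAG reconstruction, eigen-velocimetry and perfusion metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OMAG reconstruction, eigen-velocimetry and perfusion metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omagkit)
```

# The measurement problem

Optical microangiography contrasts moving scatterers (blood, or an
intralipid tracer in fixed ex-vivo hearts) against static tissue by
acquiring repeated complex A-lines at each lateral position. Two
protocols are built in as presets: `"omag"` (16 repeats at 250
positions, repeat spacing set by the 280 frames/s inter-frame interval)
gives high-contrast angiograms; `"omag-v"` (50 repeats at 200 positions
at 20,000 A-lines/s) supports quantitative velocimetry. Both cover a
1.5 x 1.5 mm^2 field at a 1340 nm center wavelength.

# Signal model and the phantom generator

Each voxel's repeat series is modeled as

$$ S(z, k, x) = A_s e^{i\phi_z} + \sum_{\mathrm{seg}} A_f
   e^{i(\phi_{0,z} + 2\pi f\, t_k)} + \varepsilon,\qquad
   f = \frac{2 n v_z}{\lambda_0},\ t_k = k/\mathrm{rate}, $$

with circular complex Gaussian noise $\varepsilon$, i.i.d. across voxels
and repeats (the shot-noise-limited OCT regime). The phases are random
per voxel but constant over repeats for the static term — a fixed
specimen has no slow-time dynamics — which is exactly what makes static
clutter a DC component in repeat time. Programmed velocities must stay
below the aliasing limit $\lambda_0\,\mathrm{rate}/(4n)$ (about 5 mm/s
for the velocimetry preset); the generator rejects faster segments
outright rather than silently wrapping them.

What the phantoms deliberately do **not** model: transverse-flow
decorrelation (the velocity calibration here is purely axial; an
optional amplitude-decorrelation mode exists but is off by default),
sample-arm optics, speckle statistics of whole blood, and motion — the
study design this emulates uses diastolically arrested fixed hearts
precisely to remove motion. Passing tests therefore demonstrate
correctness of the computation chain, not robustness to in-vivo motion
artifacts.

The intralipid refractive index is not a standardized constant; the
default is n = 1.35, configurable everywhere the Doppler slope is used.

# OMAG reconstruction

`omag_flow()` uses the magnitude of complex differences of adjacent
repeats. A constant phasor cancels exactly, so the static-tissue
contract (`flow == 0` for noiseless clutter) holds to machine precision,
and a phasor rotating at frequency $f$ leaves $2A|\sin(\pi f \Delta t)|$
per pair. This is also why the angiography preset runs at the
inter-frame rate: at 20 kHz a capillary-speed scatterer barely rotates
between repeats, while at 280 Hz it decorrelates fully.

Binarization of flow images defaults to Otsu, but Otsu assumes a
bimodal histogram; a flow image with sparse vessels is nearly unimodal
(almost all pixels are noise), and with several vessel brightness
levels Otsu tends to threshold *between vessels* rather than between
vessels and noise. The pipeline therefore thresholds at
`k * median(flow)` (k = 3 by default): the median of the flow image is a
robust estimate of the differential-noise floor precisely because
vessels are sparse. Both routes are exposed.

Vessel diameters are taken per connected component as
`2 * max(distance transform) - 1` pixels. The `-1` corrects the
half-pixel overshoot at each boundary of center-to-center distances; it
makes a rendered 15-pixel bar measure exactly 15 pixels and a single
pixel measure one pixel. Connectivity is 8 in 2-D and 26 in 3-D by
default, configurable.

# Eigendecomposition velocimetry

Per lateral position and axial window (default 16 pixels — a compromise
between covariance conditioning and axial velocity resolution), the
repeat series are stacked into $C = \frac1Z \sum_z x_z x_z^H$. Its
eigenvalues conserve the mean per-depth signal energy; the leading
`n_clutter` components (default 1 — a fixed specimen has a single
dominant static component; an adaptive eigenvalue-threshold rule is
available) are labeled clutter, and the next component is the flow
candidate.

Two guards decide whether a window carries flow at all:

* the flow eigenvalue must exceed `noise_k` (default 3) times the noise
  floor, estimated as the mean of the trailing eigenvalues;
* the lag-one autocorrelation of the flow eigenvector must be coherent
  (normalized magnitude at least 0.7). A pure phasor has coherence 1; a
  broadband noise eigenvector of a 50-repeat ensemble has coherence
  around 0.15, so the gate cleanly rejects static windows — static
  phantoms produce exactly zero flow voxels.

One numerical subtlety matters. When clutter and flow powers are
comparable, the sample covariance of a finite window mixes their
eigenvectors (the coupling scales like $\sqrt{n_f}N/Z$ against the
eigenvalue gap), and the mixed-in DC pulls the lag-one phase toward
zero — in a phantom with equal powers this biased velocities by tens of
percent. Because the static signature of a fixed specimen is *known* to
be the constant vector, `velocity_map()` deflates the flow eigenvector
of its DC component before estimating frequency and projecting voxels.
This removes the leakage deterministically: the same phantom then
recovers programmed velocities to well under 1%, and a 100x static-power
sweep moves the recovered frequency by less than 0.1%. The standalone
`lag_one_frequency()` operation is untouched by this and computes the
plain lag-one estimate.

Frequencies within 5% of Nyquist are flagged as potentially aliased in
the output rather than silently reported.

Velocity is `v = slope * f` with the Doppler slope
$\lambda_0/(2n) \approx 4.96\times10^{-4}$ mm/s per Hz by default; an
empirically calibrated slope can be supplied instead. Perfusion rates
multiply per-vessel mean velocity by lumen cross-section; the volumetric
normalization divides by field-of-view area times a configured tissue
depth. The effective depth is not a universal constant, so
`perfusion_rate()` has no silent default and errors if it is missing;
the demo configuration uses 0.89 mm, the value consistent with a
2.25 mm^2 field of view linking a 24.5 uL/min field rate to a
12.3 mL/min/mL volumetric rate.

# Network hemodynamics

Vessel graphs are Hagen-Poiseuille resistor networks: conductance
$g = \pi r^4 / (8\mu L)$ in SI units, nodal pressures from Kirchhoff
balance with Dirichlet elimination of fixed-pressure nodes, flows in
uL/min, shear $\tau = 4\mu Q/(\pi r^3)$ in dyne/cm^2. Fluid is
Newtonian with configurable viscosity — 1 mPa s for culture medium
(default), 3.5 mPa s as a whole-blood preset; at these diameters a
non-Newtonian correction would be second-order against the r^4 law.

Grid generators mirror patterned microvessel geometries (3 x 3 culture
devices; 13 x 13 implant grids of 125 um lumens). The center-to-center
spacing is not a printed parameter; the default 500 um gives an open
lattice of the right overall footprint and is configurable. Sprouts are
added either as bridges between existing nodes (diameters uniform in
20-50 um, the sub-50 um range typical of angiogenic sprouts) or as
dead-end stubs, which carry zero steady flow — consistent with blood
entering such sprouts and stopping — but remain in the graph for
geometry and shear reporting. Bridging a resistor network can only
decrease its equivalent resistance (Rayleigh monotonicity); the test
suite verifies this by re-solving after every one of 100 random sprout
additions.

Degenerate inputs are rejected with named errors: non-positive
geometry, inlet/outlet in different components, and free components
with no pressure reference (a singular system) name the offending
nodes.

# Image quantification

Particle analysis labels connected components and removes areas
strictly below 20 um^2 (background speckle). Distance bins are half-open
`[lo, hi)` — the convention must be fixed somewhere, and half-open
intervals partition the line without double counting; a centroid at
exactly 300 um falls in the second bin. Distance is measured from the
particle centroid to the nearest wall pixel via Euclidean distance
transform (or analytically for a straight wall). Bin densities are
counts over the bin's own pixel area in mm^2, so densities weighted by
bin areas reconstruct the overall density exactly.

Lumen sizes are reported both as area (um^2) and equivalent-circle
diameter (um), since either convention appears in practice.

Bead tracking detects per-frame centroids and links them by nearest
neighbor within a displacement gate; a link with two equally close
candidates is ambiguous and terminates the track rather than guessing.
On non-crossing constant-velocity movies the tracker is exact (27 um
steps at 0.27 s intervals give exactly 100 um/s).

# Expression screen

The screen implements only the formula-level rules: CPM; the
keep-filter (strictly more than 1 CPM in at least 2 samples); the
differential gate (linear |FC| strictly above 1.5 **and** BH-adjusted
FDR strictly below threshold — Methods-style 0.01 is the default, the
relaxed 0.05 used in headline gene counts is a preset, and neither is
asserted as canonical since sources quote both); upper-tail
hypergeometric overlap; and gene-centered, unscaled PCA of
log2(CPM + 1). Dispersion-modeled GLM fitting is out of scope — p
values and fold changes may come from any per-gene engine. Two are
provided for synthetic cohorts: a plain two-sample t (pooled variance
by default, because Welch's degrees of freedom collapse to ~2 at
n = 3/group and destroy power even for 4-fold effects) and the limma
moderated t, the field's standard at this sample size.

The count generator plants 4-fold shifts in 100 of 2000 genes among
3-vs-3 cohorts. Its dispersion default (0.02, biological CV ~14%)
describes replicate engineered constructs from a single cell batch
rather than independent donors; at donor-level dispersion (0.1+) no
two-sample test at n = 3 can reach 90% recovery of 4-fold effects —
a power fact worth remembering when reading such designs. DE genes are
planted only where baseline expression makes a call meaningful
(mean >= 50 counts).

# Group summaries and fold reporting

Cohort metrics are summarized as mean ± SEM with two-sided Welch t
tests per group pair (Welch is appropriate here: group variances of
in-vivo metrics differ substantially), without multiple-testing
correction across metrics. Fold ratios carry an explicit rounding rule
(`none`, `nearest_int`, `one_decimal`) so that a headline "6-fold" is a
reproducible presentation of 33.8/5.3 rather than an implicit rounding.

# Problem sizes and determinism

The demo pipeline and the test suite run phantoms of 32-64 depth
pixels, 20-32 positions and 32-50 repeats, with 2-4 samples per cohort
— sizes chosen so a full end-to-end run is a desk-scale computation
while every estimator still operates in its intended regime (the
covariance windows remain 16 pixels, the repeat counts match the
presets where the contract depends on them). All generators take
explicit seeds and save/restore RNG state, so identical configurations
are bit-identical, which the pipeline verifies by hashing its own
outputs into the run manifest.

# Known limitations

* Velocimetry measures the axial velocity component only; vessels
  nearly parallel to the surface are underestimated by the projection
  angle. The linear calibration absorbs a constant angle, not a
  distribution of angles.
* The clutter model is rank-1 DC (fixed specimens). Slowly drifting
  clutter (live imaging) would need a higher-order slow-time basis.
* Diameter estimation from en-face masks reports the medial-axis width;
  for strongly elliptical cross-sections this is the minor axis.
* The Poiseuille solver is steady-state and rigid-walled: no
  pulsatility, compliance, or hematocrit-dependent viscosity.
* The expression module does not reproduce any specific deposited
  dataset; it validates the stated rules on synthetic truth.
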