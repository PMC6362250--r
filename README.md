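# omagkit

Quantitative analysis of microvascular perfusion from OCT-based optical
microangiography (OMAG), for studies that ask whether an engineered
vascular graft on the heart actually carries flow: how dense the perfused
network is, how fast blood moves through its small arterioles, and how
much volume it delivers per minute — plus the supporting in-vitro
quantifications (Poiseuille network hemodynamics of sprouted microvessel
grids, fluorescence lumen/platelet/TUNEL particle analysis, bead-tracking
velocimetry) and the formula-level rules of a bulk RNA-seq screen.

Because raw imaging data from such studies are rarely reusable, every
input has a synthetic generator with exact ground truth, so the entire
chain is testable end to end on phantoms.

## The core computations

**OMAG flow contrast.** Repeated complex A-lines `S(z, k, x)` at each
lateral position are differenced across adjacent repeats:

    flow(z, x) = (1/(N-1)) * sum_k | S(z, k+1, x) - S(z, k, x) |

Static tissue is a constant phasor in slow time and cancels exactly; a
scatterer moving with axial velocity `v` rotates at the Doppler rate
`f = 2 n v / lambda0` and leaves `2A |sin(pi f dt)|` per pair. Vessel
area density is the percentage of a binarized en-face projection
occupied by flow pixels.

**Eigendecomposition velocimetry (OMAG-V).** The repeat series of the
depth samples in an axial window are stacked into the sample covariance
`C = (1/Z) * sum_z x_z x_z^H`. Its leading eigencomponents split into
static-tissue clutter and flow; the mean Doppler frequency of the flow
component comes from the lag-one autocorrelation of its eigenvector,

    r = sum_k e(k+1) conj(e(k)),   f = arg(r) * rate / (2 pi),

and velocity follows the linear calibration `v = (lambda0 / 2n) * f`.
Per-vessel velocities, diameters gated to the small-arteriole band
(20-40 um), and perfusion rates `Q = sum_i v_i * pi (d_i/2)^2` (uL/min,
normalized to mL/min per mL tissue) complete the chain.

**Network hemodynamics.** Microvessel graphs (e.g. a 13 x 13 patterned
grid of 125 um lumens) are solved as Hagen-Poiseuille resistor networks,
`g = pi r^4 / (8 mu L)`, with Kirchhoff balance at interior nodes and
wall shear `tau = 4 mu Q / (pi r^3)`. Adding bridging angiogenic sprouts
can only lower the inlet-to-outlet resistance (Rayleigh monotonicity),
which the solver verifies by re-solving.

**Image quantification.** Connected-component particle analysis with a
20 um^2 background exclusion, lumen density/size binned by distance from
the vessel wall ([0-300), [300-600), [600-900) um), signal-area
fractions, marker colocalization, and nearest-neighbor bead tracking.

**Expression screen.** CPM, the keep-filter (> 1 CPM in >= 2 samples),
the differential gate (|FC| > 1.5 and Benjamini-Hochberg FDR below
threshold), upper-tail hypergeometric pathway overlap, and gene-centered
PCA of log2 CPM.

## Worked example

A two-vessel OMAG-V phantom (50 repeats at 20,000 A-lines/s, 1340 nm):
a ~21 um vessel at 0.7 mm/s and a ~63 um vessel at 2 mm/s in static
clutter with complex noise.

```r
library(omagkit)

spec <- phantom_spec(
  preset = "omag-v", n_positions = 24, depth_px = 64,
  noise_sigma = 0.05, static_amplitude = 1, seed = 17,
  flow_segments = list(
    list(positions = c(3, 10),  depths = c(10, 13), velocity_mm_s = 0.7, amplitude = 1),
    list(positions = c(14, 22), depths = c(40, 48), velocity_mm_s = 2,   amplitude = 1)))
ph <- make_flow_phantom(spec)

fv   <- omag_flow(ph$ensemble)
mask <- binarize(fv$flow, "fixed", threshold = 3 * median(fv$flow))
vessel_area_density(mask)
#> [1] 7.4                # percent of the field carrying flow

diam <- estimate_vessel_diameters(mask, pixel_um = 7)
diam
#>   label area_px area_um2 diameter_um
#> 1     1      32     1568          21
#> 2     2      81     3969          63

vf <- velocity_map(ph$ensemble)
gated_velocity_stats(vf, attr(diam, "labels"), diam, gate = c(20, 40))$mean_mm_s
#> [1] 0.700              # only the 21 um vessel is in the gate

vt <- vessel_velocity_table(vf, attr(diam, "labels"), diam)
perfusion_rate(vt$diameter_um, vt$velocity_mm_s,
               fov_mm2 = 2.25, tissue_depth_mm = 0.89)
#> $q_fov_ul_min           [1] 0.3885
#> $q_volumetric_ml_min_ml [1] 0.1940
```

The gated mean recovers the programmed 0.7 mm/s, the diameters land
within one axial pixel (7 um) of the rendered widths, and the perfusion
rate is the exact unit arithmetic over the recovered vessel table.

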