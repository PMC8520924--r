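---
title: "Models and methods behind lymphchip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lymphchip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphchip)
```

`lymphchip` models a macrofluidic lymphangiogenesis chip: a COL1 hydrogel
in a central ECM channel, lymphatic endothelium cultured on its walls, a
growth-factor gradient across the gel, and a slow interstitial flow driven
by a hydrostatic head between medium reservoirs. This vignette documents
the physical models, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Device configuration

Geometry defaults are the fabricated dimensions: ECM channel 2 × 1 mm,
medium channels 4 × 1.2 mm, 4-mm medium and 1-mm ECM reservoir punches.
The channel length along the flow axis is not a fabricated cross-section
dimension; we default it to 10 mm, keep it configurable, and echo it in
the metadata of every quantity that depends on it (`head_decay`,
`run_pipeline` report). All internal units are SI; the YAML/JSON config
accepts `mm`/`um`/`kDa` suffixes and converts on load, and a save/load
round trip preserves every field exactly.

The two Darcy permeabilities are the measured values for this device:
COL1 hydrogel 1.04 × 10⁻¹³ m², lymphatic endothelium 2.46 × 10⁻¹⁶ m².
Where a solute diffusivity is needed and unknown, `stokes_einstein_diffusivity()`
provides `kT/(6πμR_h)` with a dextran-calibrated radius–mass relation
(`R_h = 0.488·MW^0.437` nm); the default gel diffusivity for the 40-kDa
tracer is 6.5 × 10⁻¹¹ m²/s, chosen so that `Pe = vL/D` with the measured
velocity endpoints (0.49 and 0.09 μm/s) and the 2-mm gel path reproduces
both ends of the reported Péclet range (15 and 3).

## Capillary filling stability

During gel loading the precursor must stay pinned at the step edge of the
ECM channel. We model the pinned meniscus with the rectangular-channel
Young–Laplace burst pressure,
\[
\Delta P_{burst} = -2\sigma\left(\frac{\cos\theta^*_h}{h} +
\frac{\cos\theta^*_w}{w}\right),\qquad
\theta^* = \min(\theta + \beta,\,180^\circ),
\]
with \(\beta\) the Gibbs edge-expansion angle of the step. This is a
modelling choice: it is the standard capillary burst-valve form, adopted
because the exact interfacial-energy expression used for the original
design is not published with the main text. The driving side is the
rectangular-duct Poiseuille drop with the first-order aspect-ratio
correction \(12\mu LQ/(wh^3(1-0.63h/w))\), valid for \(w \ge h\).

Contact angles after the hydrophobic surface treatment are unpublished;
defaults (120° walls, 60° edge expansion, σ = 0.072 N/m) give a burst
pressure of 216 Pa for the 2 × 1 mm channel, orders of magnitude above the
filling drop across the 0.1–100 μl/s loading range — filling is stable
regardless of loading rate, which is the design property the step edge
exists to provide. The precursor viscosity defaults to 0.01 Pa·s
(configurable; collagen precursors are weakly shear-thinning, which we do
not model). The critical loading rate is located by bisection on the
margin to relative tolerance 10⁻⁶ when a sign change is in range, and from
the closed-form linear crossing otherwise.

## Interstitial flow

The gel and the endothelial monolayer form a series Darcy path:
\(R = \sum_i L_i/K_i\) and \(v = \rho g \Delta h / (\mu R)\). The monolayer
thickness is not printed for this device; we use 10 μm, a typical
endothelial monolayer thickness, and pair it with a 3-mm initial head —
with the measured permeabilities this reproduces the reported initial
velocity of 0.49 μm/s exactly (to the two printed decimals).

The head relaxes as the reservoirs exchange volume. We integrate the two
reservoir levels as separate states of the linear ODE with classical
fixed-step RK4 (`deSolve`, dt default 60 s), which keeps the volume
exchanged between the reservoirs identical on both sides to rounding
(≤10⁻¹⁰ relative) and matches the closed form
\(\Delta h(t)=\Delta h_0 e^{-t/\tau}\) to better than 10⁻⁸ relative over
24 h. The geometric time constant
\(\tau = \mu R/(\rho g A_{int}(1/A_1+1/A_2))\) depends on the unprinted
channel length through the interface area, so `head_decay()` reports τ in
its attributes and `calibrate_tau()` instead fits τ to a measured velocity
pair — with the (0.49, 0.09) μm/s endpoints over 24 h,
τ = 24 h / ln(0.49/0.09) ≈ 5.1 × 10⁴ s, and the integrated state then
reproduces both endpoints by construction. The Péclet length scale
defaults to the ECM channel width (2 mm), the tracer's traverse distance.

## Solute transport

The gradient solver is a cell-centred 1-D finite-volume discretisation
across the gel, x = 0 at the factor-channel/gel interface, velocity
positive toward the stimulated channel. The endothelial monolayer enters
as an interface conductance \(P_m\) (m/s) in series with the half-cell
diffusive resistances of its neighbouring faces, rather than as resolved
10-μm cells — this avoids a 200:1 cell-size contrast and matches how thin
membranes are normally treated in compartment transport models.

Face fluxes use the Patankar exponential weighting
\(A(|P|) = |P|/(e^{|P|}-1)\) of the diffusive conductance plus upwinded
convection. We default to this scheme rather than plain first-order upwind
because it is equally monotone (the discrete maximum principle holds for
all source-free runs), reduces to upwind at high cell-Péclet, and is
*exact* at the nodes for steady uniform-coefficient advection–diffusion —
so steady profiles agree with the closed form
\(c(x) = (e^{Pe\,x/L}-e^{Pe})/(1-e^{Pe})\) to rounding at any resolution,
where upwind's O(dx) numerical diffusion would leave ~0.7% error at
Pe = 15 on a 400-cell grid. `"upwind"` and `"central"` remain available
and are cross-checked in the tests (upwind converges at first order, as
expected). Time stepping is backward Euler by default (unconditionally
stable; the constant system matrix is LU-factored once per step size);
the explicit mode is retained for cross-checks and refuses steps beyond
its stability limit. Snapshots default to every 3 h, the interval at which
the dextran gradients were monitored. Boundaries are fixed-concentration
reservoirs by default, matching daily medium refresh; closed boundaries
are available and conserve mass to ≤10⁻¹⁰ relative.

Two phenomenological regimes matter. At rest, the two-layer series
solution gives the fraction of the concentration drop across the
monolayer, \((1/P_m)/(L/D + 1/P_m)\) ≈ 0.76 at the defaults — the profile
is linear in the gel with a steep decrease over the endothelium. Under
flow at Pe ≈ 15 the gel profile flattens (mid-gel concentration > 0.99 of
the source) with the whole drop pushed to the downstream boundary layer.
For a solute secreted *inside* the gel (the CCL21 situation),
`secretion_under_flow()` reports the steady fraction of solute mass found
upstream of the source: 0.5 at rest by symmetry, decreasing monotonically
with Pe but remaining positive — molecules do spread against the flow at
these Péclet numbers, just asymmetrically.

## Morphometry

Masks are labeled 8-connected (via the pixel adjacency graph; 4-connected
labeling would split diagonal sprout necks). Per object we report
pixel-count area, perimeter, circularity \(4\pi A/P^2\) clamped at 1, and
aspect ratio/orientation from the eigen-decomposition of the second
central moments (with the +1/12 pixel-footprint correction); orientation
is axial, in degrees CCW from +x, wrapped to [−90, 90).

The perimeter estimator is the one genuinely open choice. Raw chain-code
length (1 per rook step, √2 per diagonal) overestimates smooth outlines by
~5%, biasing circularity of a digital disk to ~0.90; corner-corrected
weights fix the disk but bias the square. We instead trace the boundary
pixel centres and smooth the closed polygon with a centred moving average
(window 5) before summing segment lengths: a radius-100 disk then measures
circularity 1.005 and a 200-px square 0.80, both within the tolerances we
test. The window is fixed; it rounds true corners of very small objects,
which is why the minimum object area defaults to 20 px.

Orientation statistics treat cell orientations as axial data: angles are
doubled before computing the circular mean and resultant length, and the
mean is halved back. Sprout quantification splits gel-side foreground into
interface-connected sprouts (distance = maximum perpendicular extent from
the interface; both per-sprout values and the image maximum are reported,
since either convention appears in practice) and disconnected objects,
which are counted as single-cell migration events and excluded from
distances.

## Assays

Comparative Ct: technical replicates are averaged within sample × gene,
\(\Delta Ct = Ct_{target} - Ct_{housekeeping}\) per sample, group means
are differenced against the control group, and \(fold = 2^{-\Delta\Delta Ct}\)
with amplification efficiency fixed at 2 (no efficiency correction).
Biological replicates are aggregated at the ΔCt level (mean); per-sample
folds are attached for error bars. The control fold is identically 1.

The 4PL curve \(y = d + (a-d)/(1+(x/c)^b)\) is fit by Levenberg–Marquardt
with multi-start: heuristic initials (asymptotes from the response
extremes, c from the mid-response concentration) plus seeded log-normal
jitter restarts, keeping the lowest residual sum of squares. The inverse
\(x = c((a-d)/(y-d)-1)^{1/b}\) refuses responses at or beyond the
asymptotes. Inverse∘forward is identity to 10⁻⁸ relative on the fitted
range.

## Synthetic data: what it does and does not show

Every generator is a pure function of (parameters, seed) — same inputs,
bit-identical outputs — and returns a ground-truth manifest the tests
consume. Cell masks are rasterised ellipses with uniform aspect ratios,
von Mises axial orientations (Best–Fisher sampling, implemented here), and
optional boundary-pixel flip noise, which mimics segmentation jitter
without breaking connectivity; objects are laid out on a jittered
non-overlapping tile grid. Sprout fields are interface-connected fingers
with controlled horizontal extents and von-Mises-biased directions
(clamped to ±20° so lanes stay disjoint) plus disconnected blobs for
single-cell migration. Intensity series render a transport solution as
constant-transverse images with additive Gaussian noise at 3-h sampling.

These emulate the *geometry* of the measured data, not its microscopy:
no point-spread function, no photobleaching, no intensity heterogeneity
within cells, no gel fibre texture, and no segmentation step (the pipeline
starts from masks, as the original quantification started from stained
images). Passing tests therefore demonstrate that the quantification
stack is correct on its own terms — shape recovery, distance recovery,
fold/parameter recovery under the stated noise — not that segmentation of
real micrographs would be error-free.

Problem sizes used in the test suite (400-cell steady grids, 60–200-cell
transient grids, 200-object recovery sets, 50-seed and 200-seed noise
simulations) are chosen as the smallest sizes at which the asymptotic
behaviour under test is clearly expressed.

## Known limitations

- The transport model is 1-D; lateral spreading near channel junctions
  and the 3-D sprout geometry are outside its scope, as is any gel
  remodelling or cellular uptake kinetics.
- The head-decay model treats the two reservoir sets as ideal cylinders
  and ignores evaporation and the daily medium refresh; the calibrated-τ
  mode exists precisely because the geometric τ is not identifiable from
  published dimensions.
- Contact angles, precursor viscosity, monolayer thickness and the
  original simulation's diffusivity table are not published; all are
  configurable with documented defaults.
- The 4PL fit assumes homoscedastic noise; no 1/y² weighting is applied.
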