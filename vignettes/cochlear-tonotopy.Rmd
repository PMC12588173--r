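---
title: "Methods: 3D cochlear tonotopic mapping with cochleomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D cochlear tonotopic mapping with cochleomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochleomap)
```

## The problem

The cochlea encodes frequency by place: high frequencies at the base of the
basilar membrane (BM), low frequencies at the apex. Anatomical tonotopic maps
are built from traced 3D centerlines of the BM (carrying the organ of Corti,
OC) and of the spiral ganglion (SG, the neuron cell bodies), usually
segmented slice-by-slice from high-resolution CT of a temporal bone. Three
coordinates matter for each traced position: its curvilinear (arc-length)
position along the structure, its angular insertion depth about the
mid-modiolar axis (0 degrees at the round-window center), and its
characteristic frequency. `cochleomap` computes all three, links the OC and
SG maps through individually traced peripheral dendrites, and summarizes the
result as frequency tables, semitone rate-of-change profiles, octave bands,
and innervation-density morphometry.

## Frequency model

Position is mapped to frequency with the Greenwood function

$$F(x) = A\,(10^{a x} - k),$$

where $x \in [0, 1]$ is the *proportional distance from the apex*
($x = (L - s)/L$ for arc position $s$ from the base along a structure of
total length $L$). The convention puts the map's minimum $A(1-k)$ at the
apex and its maximum $A(10^a - k)$ at the base, matching the physiological
base-to-apex descent. Defaults are the standard human constants
$A = 165.4$ Hz, $a = 2.1$, $k = 0.88$, giving a 19.8 Hz apex and a
20,677 Hz base. These constants are not free in practice: with the turn
lengths of the reference specimen (21.38, 8.37 and 4.35 mm of a 34.10 mm
BM) they place the turn ends at 859, 161 and 20 Hz after integer rounding,
which is exactly what the acceptance suite checks.

`fit_greenwood()` estimates $(A, a, k)$ from observed $(x, f)$ samples by
nonlinear least squares **in log10-frequency**. Cochlear frequencies span
three decades, so linear-frequency residuals would let the basal kilohertz
range dominate; log-space residuals weight a given frequency *ratio* (i.e.
a semitone error) equally everywhere. Fitting uses Levenberg–Marquardt with
box constraints ($A > 0$, $a > 0$, $0 \le k < 1$) and requires at least
four distinct $x$ values; non-convergence is an error, not a silent result.

## Geometry

**Arc length** is the piecewise-linear chord sum of the ordered landmark
polyline. This matches how lengths are measured from manually placed
landmarks; no spline is fitted, so the measure is deterministic and its
resolution is controlled entirely by the sampling density (for a coiled
path, chord shortening falls with the squared angular step between
samples). `resample_centerline()` provides uniform arc-length resampling
(endpoints preserved) when traced landmarks are uneven.

**Mid-modiolar axis.** The axis is not traceable directly; it is estimated
from the coiled BM centerline. Initialization uses the mean cross product
of successive coarse chords — the direction about which the polyline turns.
(The principal directions of the point cloud are deliberately *not* used:
for a cochlea the axial rise over ~3 turns is smaller than the coil
diameter, so no principal component lies near the axis.) The axis (2
direction + 2 in-plane position parameters) is then refined by minimizing
the residual sum of squares of **log point-to-axis radial distance about a
low-order polynomial trend** in sample index (degree = one per turn, capped
at 5; Nelder–Mead followed by BFGS, relative tolerance 1e-8, 200 iterations
each). The polynomial absorbs the smooth base-to-apex radial taper of the
spiral, while a mis-aligned axis induces a once-per-turn radial ripple that
the polynomial cannot follow — so the objective measures coaxiality, not
circularity, and does not require the radius profile to be constant or even
exponential. A simpler "deviation from a running median" detrend was
rejected: the running median of a monotone taper is the identity, which
makes that objective identically zero over a wide set of visibly wrong
axes. Degenerate inputs fail loudly: collinear points (second singular
value below 1e-6 of the first) are not identifiable, and a round-window
landmark within 1e-6 mm of the axis leaves the zero ray undefined. Ties in
axis orientation are broken toward the net base-to-apex displacement.

**Angular depth.** Each point is projected into the plane orthogonal to the
axis; its angle from the zero ray (through the round-window center) is
signed by handedness (+1 for a left ear, the default; −1 for a right ear)
and unwrapped cumulatively — each raw step is taken modulo 360 in
[0, 360) — so the profile is monotone non-decreasing and can exceed 360.
The first point's raw angle is taken in [−180, 180). The unwrap assumes no
local reversal of 180 degrees or more between consecutive samples; for
noisy traces this is guaranteed by measuring angles at stations at least
~0.5 mm apart (`resample_centerline()`), where forward progress dominates
tracing jitter. A point lying exactly on the axis has no defined angle and
is reported as an error with its index, never skipped.

## Dendrite transfer and derived profiles

`transfer_to_sg()` carries the OC frequency at each dendrite's BM
attachment (linear interpolation of the OC map in log-frequency) to the
dendrite's SG attachment (nearest SG centerline point). Records are sorted
by SG arc position; dendrites landing on the same SG position are averaged
geometrically (log-frequency mean), which is linear on the semitone scale.
Dendrite endpoints must lie within a configurable 0.2 mm of their
centerlines; violations name the offending trace. The SG arc coordinate is
taken along the single SG centerline polyline continued through the central
modiolar space, treating the SG as one curve — how positions past the
Rosenthal's-canal/central-modiolus junction should be parameterized is not
standardized, and this single-curve convention is the package's choice.

`rate_of_change()` reports $12\,|\mathrm{d}\log_2 f / \mathrm{d}p|$
(semitones per mm or per degree). The log2-frequency series is smoothed
with a moving average (default window 30 degrees or 1 mm — roughly the
inter-landmark spacing at which tracing noise, not anatomy, dominates) and
differentiated with central differences; near the ends, where the window is
one-sided, the derivative is taken against the window's centroid position,
which keeps the estimate exact for exponential (constant-rate) maps.
`octave_bands()` places boundaries at $\mathrm{ref}\cdot 2^n$ and
interpolates their positions monotonically in log2-frequency; adjacent-band
semitone spans sum to the map's total span by construction.

`semitone_difference()` is $|12 \log_2(f_1/f_2)|$. Reported tables use the
field's printed precisions: integer Hz, one-decimal semitones, integer
percent, with half-up rounding (guarded against floating-point
representation error in products like $110 \times 4.35$).

## Morphometry

The innervation-density arithmetic is deliberately elementary and exact:

- `estimate_neurons_cylinder()`: soma of diameter $d$ packed into a
  cylinder $L \times D$ gives
  $\lfloor \phi \cdot \pi (D/2)^2 L / (\tfrac{4}{3}\pi (d/2)^3) \rfloor$
  with packing fraction $\phi \in (0, 1]$. The count is floored because a
  capacity cannot be exceeded. The default $\phi = 1$ is a pure volume
  ratio — no packing correction is assumed, and the result (8508 for the
  default 22 µm / 1.51 mm / 200 µm dimensions) is surfaced next to the
  axon-scaling estimate rather than hidden, since random sphere packing
  would reduce it by a third and no correction can be cited.
- `scale_axon_count()`: linear density extrapolation,
  round(n · target/ref), half up.
- `estimate_ihc_count()`, `innervation_ratio()`, `apical_fraction()`:
  direct products and ratios at the printed precisions.

## The synthetic generator

`generate_cochlea(cochlea_spec())` builds a conical helix about the z axis
for the BM and an inner helix for the SG, with exponential radius decay
$r(\theta) = r_0 e^{-c\theta}$. The decay rate $c$ is solved by bisection
so the generated arc length matches the requested total to well within
0.1%; an unsatisfiable length/angle/radius combination is a generation
error. Dendrites connect equal-angle BM/SG points below the rotation onset
(650 degrees by default) and, beyond it, follow a linear clockwise angular
ramp that reaches the SG terminal angle (720 degrees) at the BM apex
(1040 degrees) — onset and direction are anatomically motivated; the linear
form is the simplest monotone choice. Optional isotropic Gaussian noise
(`noise_sd`, mm) models tracing jitter; identical seeds give bit-identical
output.

Default dimensions are the reference specimen's: BM 34.10 mm / 1040
degrees with turn lengths 21.38, 8.37, 4.35 mm; SG 14.73 mm / 720 degrees;
rotation onset 650 degrees. The base radius (4.2 mm) and pitch (2.0 mm per
turn) are plausible human dimensions but are *not* calibrated: only total
lengths and angular spans are enforced by the solver. In particular the
printed per-turn lengths are carried as metadata, not enforced — a smooth
monotone radius profile cannot reproduce all three printed turn lengths
simultaneously at plausible dimensions, so per-turn length targets are
evaluated arithmetically from the printed values rather than from synthetic
geometry. Consequently the generator emulates the *coordinate structure* of
a traced cochlea (lengths, angles, dendrite topology, noise), not its
detailed radial anatomy: passing tests demonstrate that the pipeline's
geometry, mapping, transfer, and reporting are correct on ground-truthed
inputs, not that any particular specimen's radius profile is realistic.
Real traced data also exhibit non-isotropic, spatially correlated tracing
error and unevenly spaced landmarks; the generator models neither beyond
`noise_sd` and uniform angular sampling.

## Problem sizes and tolerances

The default generator samples 2 points per degree (2081 BM points, 1441 SG
points, 80 dendrites), which keeps chord-sum length error near 1e-6
relative and runs the full pipeline in well under a second; axis refinement
internally thins to at most 800 stations, which leaves the fit's noiseless
axis-direction error around 1e-4 degrees — far inside the 0.5-degree
acceptance band. Greenwood forward/inverse round-trips are exact to 1e-12
relative; parameter recovery from noiseless samples is within 0.1%; with
multiplicative noise of 0.01 log10 units on 50 samples the median recovered
$A$ and $a$ over 100 replicates stay within 5%.

## Known limitations

- The mid-modiolar axis is assumed straight; a curved modiolar axis would
  bias apical angular depths.
- Angular unwrapping requires monotone forward progress at the measurement
  stations; extremely tortuous or very noisy traces must be resampled
  first.
- The SG arc coordinate through the central modiolus follows the
  single-curve convention described above.
- Frequency transfer assigns each dendrite a single OC frequency; branching
  dendrites or uncertain attachments are not modelled.
- Morphometry counts are density extrapolations: they inherit the
  assumption that the reference axon density persists over the target
  extent, and efferent fibers are not separated out.
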