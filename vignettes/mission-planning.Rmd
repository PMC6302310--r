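---
title: "Planning photogrammetric UAS mapping missions with uasplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning photogrammetric UAS mapping missions with uasplan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uasplan)
```

## The problem

High-resolution optical remote sensing from unmanned aerial systems (UAS) —
for example millimetre-scale imaging of field-phenotyping trials — fails far
more often from poor flight preparation than from poor hardware. A mapping
mission couples quantities that are usually reasoned about separately: the
ground sampling distance (GSD) fixes the flight height, the flight height
fixes the depth of field the lens must bridge, the shutter speed bounds the
flight speed through motion blur, the overlap requirements of
structure-from-motion processing fix the exposure grid and hence the
duration, and the ground-control-point (GCP) layout decides whether the
imagery can be georeferenced at all. `uasplan` models this chain end to end
for a nadir-looking digital frame camera with a thin lens over flat terrain,
and exports the result as a geo-referenced waypoint flight.

## Per-photo optics

For a sensor of physical size $S_{x'} \times S_{y'}$ with $S_a \times S_b$
recorded pixels (pixel aspect ratio one, enforced to 1%), the pixel pitch is
$S_\delta = S_{x'}/S_a$. The circle-of-confusion limit defaults to
$c = S_\delta$ — for image processing the sensible sharpness criterion is
the sensor's own resolving limit — and may only be tightened, never
loosened. From the focal length $f$ and aperture number $N$ follow

* hyperfocal distance $H = f^2/(Nc) + f$,
* diffraction spot $d = 2 \cdot 1.22\,\lambda N$ (flagged when $d > c$;
  $\lambda$ defaults to 550 nm, mid-visible),
* angle of view $\mathrm{AOV} = 2\arctan(S/2f)$ per axis,
* ground field of view $G = S\,h/f$ and $\mathrm{GSD} = S_\delta\,h/f$ at
  flight height $h$,
* depth of field $D_{N,F} = sH/(H \pm s)$ around a focus distance $s$.

For nadir photography the depth of field should expand equally before and
beyond the ground, $(D_N + D_F)/2 = h$. Substituting the depth-of-field
limits turns this criterion into a quadratic in $s$ whose admissible root is

$$ s = \frac{H\left(\sqrt{H^2 + 4h^2} - H\right)}{2h}. $$

A closed form sometimes quoted for this problem, $s = H\sqrt{h}/\sqrt{H+h}$,
does **not** satisfy the midpoint criterion (it is easy to check that its
depth-of-field midpoint overshoots $h$); `uasplan` therefore solves the
criterion exactly. The exact root always lies below $H$, so the far limit
stays finite. The test suite verifies the midpoint identity to $10^{-9}$
relative error over a thousand random camera/height combinations, along with
the harmonic-mean identity $2/s = 1/D_N + 1/D_F$ that any solution of the
depth-of-field equations must obey.

Exposure bookkeeping uses exposure values,
$\mathrm{EV} = \log_2(N^2/I_t) + \log_2(100/\mathrm{ISO})$, and its exact
ISO inverse $\mathrm{ISO} = 25\,N^2\,2^{2-\mathrm{EV}}/I_t$; exceeding the
sensor's tolerable ISO warns (the remedy is a slower shutter — and a slower
flight — or a wider aperture), it never errors.

All computation is in SI metres and seconds; millimetres, micrometres and
nanometres exist only in constructor arguments, and display rounding
(nearest millimetre for GSD, one decimal for metre distances, whole minutes
for durations) happens only in `print`/`format` methods, never inside a
computation.

## The mapping grid

The local frame puts the origin at one corner of the rectangular mapping
area $A_x \times A_y$, +y along the flight direction, +x across it, with
serpentine (boustrophedon) line ordering starting at the line nearest the
origin. End/side laps ($E_\%$, $S_\%$) become spacings
$E = G_E(1 - E_\%/100)$ and $S = G_S(1 - S_\%/100)$, where $G_E$/$G_S$ are
the footprint extents along/across flight per the camera orientation. So
that the requested overlap also holds at the area edges, the area is
extended by half a footprint in both dimensions and directions:

$$ E_n = \lceil (A_y + G_E)/E \rceil, \qquad
   S_n = \lceil (A_x + G_S)/S \rceil, \qquad I_n = E_n S_n. $$

Design choices a user should know:

* The station grid is **centred** on the area — the slack the ceiling
  introduces is split evenly between both ends of each line and both sides
  of the area.
* Spacings are **not** recomputed after the ceiling; the realised overlap is
  therefore always at least the requested one.
* The ceiling carries a $10^{-9}$ fuzz so an exactly divisible extent does
  not gain a spurious extra line from floating-point noise.
* The approximate path length used for both the minimum-speed bound and the
  flight duration is $S_n(A_y + G_E) + A_x + G_S$: all lines at their full
  extended length plus one across-track transit. Transit legs are assumed
  flown at cruise speed; autopilots that add turn-time buffers will run
  somewhat longer (the briefing says so).

The flight speed is the motion-blur-budgeted candidate
$F_v = \mathrm{GSD}\,(\delta/100)/I_t$ clamped into
$[F_{v,\min}, F_{v,\max}]$, where $F_{v,\min}$ comes from the maximum
flight duration and $F_{v,\max} = I_{f,\max} E$ from the fastest trigger
rate the camera sustains. An empty window, or a minimum speed that alone
violates the blur budget, is an error with a remediation hint — not a
silently degraded plan. Motion blur is reported as
$\delta = 100\,F_v I_t/\mathrm{GSD}$ percent of one pixel; the briefing
warns above 50%, a practical limit for plant/soil segmentation work.

## GCP layouts and recover frequency

Two arrangements are generated on the area: `squared`, an $n_x \times n_y$
grid on cell centres, and `crosswise`, a quincunx that keeps the same rows
but offsets every second row by half the column spacing with $n_x - 1$
markers, trading marker count against coverage. A GCP is counted in a photo
when it lies within the axis-aligned footprint rectangle around the station,
**boundaries inclusive** — a marker exactly on a footprint seam is visible
in both adjacent photos, matching physical visibility. The recover-frequency
histogram $\nu_{GCP}(k)$ is the fraction of photos seeing exactly $k$
markers; it is computed on the planned, deterministic stations (positioning
noise enters the viewing-geometry prediction instead) and sums to one by
construction.

Automatic placement is a deterministic exhaustive search over both patterns
and $n_x, n_y \in 1..12$: feasible layouts reach the target fraction of
photos with at least one marker; among them the search minimises marker
count, then prefers the larger achieved fraction, then squared over
crosswise, then smaller $n_x$. At mission scale (hundreds of photos, tens of
markers) the search takes about a second; a bounded exhaustive search is
preferred over a heuristic optimiser because its result is reproducible and
its optimality within the bounds is checkable (the suite brute-forces it).

A caveat: predicted recover frequencies depend strongly on the exact
station-grid and marker-placement conventions. Realised recovery in a flown
mission — where the autopilot regenerates the grid and markers are staked
by hand — can differ by tens of percentage points in the individual
$\nu(k)$ classes even when the mean number of visible markers agrees, so
the target fraction should carry a margin.

## Viewing geometry

For plot-centred analyses (e.g. per-plot reflectance or canopy metrics) the
distribution of viewing angles matters. The positioning model is: flight
lines placed with a normal error (standard deviation $\sigma$) across the
flight direction; exposure positions along a line with a uniform error on
$(-\sigma/2, \sigma/2)$, reflecting an initial line-start error propagated
from exposure to exposure. The default $\sigma$ of 0.3 m is a realistic
satellite-navigation-plus-gimbal hold for a mid-size multirotor; it is a
spec parameter, not a fitted value.

For each sensor axis, pixel offsets from the sensor centre are binned
(`bin_px` pixels per bin, default 40, i.e. a 151 × 101 grid for a
6000 × 4000 px sensor — fine enough for 1° zenith bins, coarse enough to be
instant). The mass of a bin is the **integral** of the positioning density
over the bin's ground extent, computed from the distribution function. For
the normal axis this is indistinguishable from density × bin width; for the
uniform axis, whose support can span only two or three bins at default
settings, the integral form is what keeps the distribution normalised
(point-evaluated densities can over- or under-count by tens of percent at a
discontinuity). With $\sigma = 0$ each station–plot pair contributes a unit
mass to the bin containing its offset. The joint pixel distribution is the
outer product of the axis distributions, and its total mass is at most one —
mass falls outside the sensor whenever a plot is not visible from a station.

The zenith angle of a pixel at centred offset $(a, b)$ is
$\theta = \arctan\!\left(S_\delta \sqrt{a^2 + b^2}/f\right)$: zero at the
sensor centre (nadir) and half the diagonal angle of view at the corner.
(A form with offsets measured from the sensor edge would put nadir at the
edge pixel, which is physically wrong; the centred form reproduces half the
per-axis angle of view at the sensor edge exactly.) Summing the joint bin
masses into 1° bins yields the zenith-angle frequency distribution; for a
realistic mission it peaks well away from nadir — close-nadir views of any
given plot are rare, which is exactly why predicting the distribution ahead
of the flight is useful for multi-view or BRDF-sensitive analyses.

## Geography and exports

Three anchor points place the local plan on Earth: the take-off point
(reference altitude), one area corner (local origin), and a point defining
the flight-direction baseline. Conversion is a spherical tangent-plane
approximation at 111194.93 m per degree (mean-radius sphere); at
sub-kilometre field extents the error against a full ellipsoid model is
below a centimetre — far below UAS positioning noise — and the suite
cross-checks distances against an independent spherical geodesy
implementation. Latitudes above 85° are rejected rather than silently
degraded.

Waypoints keep the serpentine line endpoints unconditionally and insert
intermediate points along lines at a chosen leg length, the hook for
elevation-model-based terrain following in the consuming app (no elevation
model is read here). When a vendor waypoint cap binds (default 100, a common
autopilot limit), intermediates are thinned uniformly to the largest
admissible per-line spacing; endpoints are never dropped, and a cap below
twice the line count is an error. The waypoint CSV uses the widely-supported
column set `latitude,longitude,altitude(m),heading(deg),curvesize(m),rotationdir,gimbalmode,gimbalpitchangle`
with 7-decimal coordinates (≈1.1 cm quantisation) and a −90° nadir gimbal;
the KML export carries the area as a closed polygon and the path as a
line string for shape-import-based mission tools.

## A worked mission

The bundled demonstration mission maps a 40 × 35 m wheat trial at 3 mm GSD
with 92%/75% laps, a 5% motion-blur budget, a 1/16000 s shutter at ISO 2500
and f/5.6, and a 75% GCP recovery target:

```{r demo}
cfg <- suppressWarnings(load_mission_config(
  system.file("extdata", "missions", "mission_exp3.json", package = "uasplan")
))
briefing <- mission_briefing(cfg)
briefing
```

The 3 mm target puts the flight at 27.8 m; the blur budget caps the speed at
2.40 m/s, inside the duration/trigger window; the grid is 18 lines of 37
exposures (666 photos); and the ground-centred focus distance is 25.6 m with
a 20.0–35.6 m depth of field. Problem sizes throughout the examples and
tests (hundreds of photos, a 151 × 101 pixel-bin grid, ≤ 12 × 12 GCP search)
are the scales real field missions have; everything runs in seconds.

## Limitations

* Rectangular areas, thin lenses, flat terrain, nadir views only.
* No wind, turn-time, or multi-battery modelling; durations are lower
  bounds.
* GCP recovery is predicted on planned stations; realised per-$k$
  frequencies are convention-sensitive (see above).
* The viewing-geometry model treats the two axes as independent and ignores
  reflectance anisotropy; it predicts where plot centres land on the sensor,
  not how they look.
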