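# uasplan — photographic flight planning for UAS mapping missions

`uasplan` plans photogrammetric mapping missions for unmanned aerial systems
(UAS) carrying digital frame cameras — the kind of millimetre-GSD imaging
used in field phenotyping and close-range vegetation monitoring. Most
mission-planning tools treat the camera as a black box; this package puts
the photographic physics first and derives the mission from it:

* **Per-photo optics and exposure.** Pixel pitch and circle of confusion
  (`c = S_δ` by default), hyperfocal distance `H = f²/(Nc) + f`, diffraction
  limit `d = 2·1.22·λN`, angle and ground field of view, ground sampling
  distance `GSD = S_δ·h/f`, exposure value `EV = log₂(N²/I_t) +
  log₂(100/ISO)` and its exact ISO inverse. The focus distance is chosen so
  the depth of field expands equally before and beyond the ground,
  `(D_N + D_F)/2 = h`, solved exactly:
  `s = H(√(H² + 4h²) − H)/(2h)`.
* **Mapping grid and speed budget.** End/side laps become exposure/line
  spacings `E = G_E(1 − E_%/100)`, `S = G_S(1 − S_%/100)`; the area is
  extended by half a footprint so overlap holds at the edges
  (`E_n = ⌈(A_y+G_E)/E⌉`, `S_n = ⌈(A_x+G_S)/S⌉`); the flight speed is the
  motion-blur-budgeted candidate `F_v = GSD·(δ/100)/I_t` clamped into the
  window set by the maximum flight duration and the camera trigger rate.
* **Ground control points.** Squared and crosswise (quincunx) layouts, the
  recover-frequency histogram `ν_GCP(k)` (fraction of photos seeing exactly
  `k` markers, inclusive footprint window), and a deterministic exhaustive
  search for the smallest layout reaching a target fraction of photos with
  at least one marker.
* **Viewing geometry.** Per-pixel plot-centre recover frequencies under
  positioning noise (normal across lines, uniform along them) and the
  zenith-angle distribution `ν_θ(θ)` with
  `θ(a,b) = atan(S_δ√(a²+b²)/f)`.
* **Geo-referenced exports.** Three anchor points place the plan on Earth
  (spherical tangent plane, sub-centimetre at field scale); serpentine
  waypoints with terrain-following densification under a vendor waypoint
  cap; waypoint-CSV and KML export.

## A worked example

The bundled demonstration mission maps a 40 × 35 m wheat trial at 3 mm GSD
with 92 %/75 % laps, a 5 % motion-blur budget, 1/16000 s at ISO 2500 and
f/5.6, and a 75 % GCP-recovery target:

```r
library(uasplan)
cfg <- load_mission_config(
  system.file("extdata", "missions", "mission_exp3.json", package = "uasplan")
)
mission_briefing(cfg)
#> UAS MAPPING MISSION BRIEFING
#>
#> Photography
#>   flight height:        27.8 m
#>   GSD:                  3 mm (3.00 mm)
#>   ground field of view: 18.0 x 12.0 m
#>   hyperfocal distance:  91.1 m
#>   focus distance:       25.6 m (depth of field 20.0-35.6 m)
#>   ...
#> Flight plan
#>   exposures x lines:    37 x 18 = 666 photos
#>   flight speed:         2.40 m/s (window 1.12-2.88 m/s, motion-blur-limited)
#>   trigger interval:     0.60 s (1.67 photos/s)
#>   motion blur:          5%
#>   flight duration:      7 min (419 s)
#> ...
#>   >= 1 per image: 77%
```

Reading the numbers: the 3 mm GSD target fixes the flight height at 27.8 m;
at that height the 92 %/75 % overlaps need 18 serpentine lines of 37
exposures each; the 5 % blur budget at 1/16000 s caps the speed at 2.40 m/s,
which sits inside the feasible window, so the mission is blur-limited rather
than trigger- or duration-limited; and the automatically placed GCP layout
reaches the 75 % recovery target. Lower-level functions
(`ground_sampling_distance()`, `depth_of_field()`, `plan_mission()`,
`gcp_recover_frequency()`, `plot_center_pixel_frequency()`,
`build_waypoints()`, …) expose every step individually; see the vignette
`vignettes/mission-planning.Rmd` for the model and its design choices.

A thin command-line wrapper is installed at `inst/cli/uasplan`:

```sh
Rscript inst/cli/uasplan briefing --config mission.json --out briefing/
Rscript inst/cli/uasplan export --config mission.json --format csv --out flight/
```

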