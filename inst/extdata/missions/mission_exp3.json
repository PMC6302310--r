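{
  "camera": { "preset": "sony_a9_55mm", "aperture": 5.6 },
  "exposure": { "shutter_s": 6.25e-05, "iso": 2500 },
  "mission": {
    "area_width_m": 40,
    "area_depth_m": 35,
    "gsd_m": 0.003,
    "end_lap_pct": 92,
    "side_lap_pct": 75,
    "orientation": "wide_side_along_flight",
    "max_flight_duration_s": 900,
    "max_motion_blur_pct": 5,
    "positioning_sigma_m": 0.3
  },
  "gcp": { "target_at_least_one": 0.75 },
  "plots": { "n_x": 26, "n_y": 35 },
  "geo": {
    "start": { "lat": 47.44921, "lon": 8.68238 },
    "edge1": { "lat": 47.44944, "lon": 8.68181 },
    "dir": { "lat": 47.44998, "lon": 8.68192 }
  },
  "export": { "max_waypoints": 100, "max_leg_length_m": 20 }
}
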