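{
  "camera": { "preset": "sony_a9_55mm", "aperture": 8.0 },
  "exposure": { "shutter_s": 0.002, "iso": 320 },
  "mission": {
    "area_width_m": 40,
    "area_depth_m": 35,
    "flight_height_m": 46,
    "end_lap_pct": 85,
    "side_lap_pct": 70,
    "orientation": "wide_side_along_flight",
    "max_flight_duration_s": 900,
    "max_motion_blur_pct": 600
  },
  "report": { "heights_m": [46] }
}
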