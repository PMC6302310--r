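{
  "camera": { "preset": "sony_a9_55mm", "aperture": 6.7 },
  "exposure": { "shutter_s": 4e-04, "iso": 350 },
  "mission": {
    "area_width_m": 40,
    "area_depth_m": 35,
    "flight_height_m": 46,
    "end_lap_pct": 85,
    "side_lap_pct": 70,
    "orientation": "wide_side_along_flight",
    "max_flight_duration_s": 900,
    "max_motion_blur_pct": 8
  },
  "report": { "heights_m": [19, 28, 46, 93] }
}
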