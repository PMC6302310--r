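{
  "sensor_width_mm": 35.6,
  "sensor_height_mm": 23.8,
  "pixels_x": 6000,
  "pixels_y": 4000,
  "focal_length_mm": 55,
  "max_trigger_frequency_hz": 2.0,
  "max_iso": 4000
}
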