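{
  "title": "fourd end-to-end pipeline report",
  "required": {
    "seed": {},
    "image_shape": {},
    "n_calibration_fields": {},
    "start_radius": {},
    "smoothing": {},
    "pre": {
      "dominant_angle_deg": {},
      "mean_eccentricity": {},
      "circular_variance": {}
    },
    "post": {
      "dominant_angle_deg": {},
      "mean_eccentricity": {},
      "circular_variance": {}
    },
    "residual_moment": {},
    "no_significant_bias": {}
  }
}
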