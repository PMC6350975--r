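{
  "name": "schema_49",
  "comment": "0-based landmark indices per feature polygon, ordered around each contour. Layout: eyebrows 0-9, nose bridge 10-13, nose base 14-18, left eye 19-24, right eye 25-30, outer mouth 31-42, inner mouth 43-48.",
  "features": {
    "left_eye": [19, 20, 21, 22, 23, 24],
    "right_eye": [25, 26, 27, 28, 29, 30],
    "nose": [10, 14, 15, 16, 17, 18],
    "mouth": [31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42],
    "mouth_outer": [31, 32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42]
  }
}
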