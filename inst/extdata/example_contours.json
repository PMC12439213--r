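{
  "structure": "cord_demo",
  "slices": [
    {"z": 0, "polygons": [[[3.5, 3.5], [8.5, 3.5], [8.5, 8.5], [3.5, 8.5]]]},
    {"z": 2, "polygons": [[[3.5, 3.5], [8.5, 3.5], [8.5, 8.5], [3.5, 8.5]]]},
    {"z": 4, "polygons": [[[4.5, 4.5], [7.5, 4.5], [7.5, 7.5], [4.5, 7.5]]]}
  ]
}
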