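{
  "shapes": [
    {
      "label": "MT",
      "shape_type": "polygon",
      "points": [[32, 32], [96, 32], [96, 96], [32, 96]]
    },
    {
      "label": "JS",
      "shape_type": "polygon",
      "points": [[110, 20], [150, 28], [140, 70], [104, 60]]
    }
  ],
  "imageHeight": 176,
  "imageWidth": 176
}
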