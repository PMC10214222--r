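{
  "schema": "nichefab/design/v1",
  "name": "bmp4_half_square",
  "array_layout": {
    "rows": 3,
    "cols": 3,
    "pitch": 1500
  },
  "regions": [
    {
      "region_id": "bmp4_domain",
      "geometry": {
        "type": "rect",
        "origin": [0, 0],
        "width": 500,
        "height": 1000
      },
      "target": {
        "E_des": 8,
        "W_des": 200,
        "conjugates": {
          "RGD": 2,
          "BMP4": 0.015
        }
      }
    },
    {
      "region_id": "plain_domain",
      "geometry": {
        "type": "rect",
        "origin": [500, 0],
        "width": 500,
        "height": 1000
      },
      "target": {
        "E_des": 8,
        "W_des": 200,
        "conjugates": {
          "RGD": 2
        }
      }
    }
  ]
}
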