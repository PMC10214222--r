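{
  "schema": "nichefab/design/v1",
  "name": "mechano_gradient_square",
  "array_layout": {
    "rows": 3,
    "cols": 3,
    "pitch": 1500
  },
  "regions": [
    {
      "region_id": "strip_2.5_kPa",
      "geometry": {
        "type": "rect",
        "origin": [0, 0],
        "width": 200,
        "height": 1000
      },
      "target": {
        "E_des": 2.5,
        "W_des": 200,
        "conjugates": {
          "RGD": 2
        }
      }
    },
    {
      "region_id": "strip_5_kPa",
      "geometry": {
        "type": "rect",
        "origin": [200, 0],
        "width": 200,
        "height": 1000
      },
      "target": {
        "E_des": 5,
        "W_des": 200,
        "conjugates": {
          "RGD": 2
        }
      }
    },
    {
      "region_id": "strip_10_kPa",
      "geometry": {
        "type": "rect",
        "origin": [400, 0],
        "width": 200,
        "height": 1000
      },
      "target": {
        "E_des": 10,
        "W_des": 200,
        "conjugates": {
          "RGD": 2
        }
      }
    },
    {
      "region_id": "strip_15_kPa",
      "geometry": {
        "type": "rect",
        "origin": [600, 0],
        "width": 200,
        "height": 1000
      },
      "target": {
        "E_des": 15,
        "W_des": 200,
        "conjugates": {
          "RGD": 2
        }
      }
    },
    {
      "region_id": "strip_20_kPa",
      "geometry": {
        "type": "rect",
        "origin": [800, 0],
        "width": 200,
        "height": 1000
      },
      "target": {
        "E_des": 20,
        "W_des": 200,
        "conjugates": {
          "RGD": 2
        }
      }
    }
  ]
}
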