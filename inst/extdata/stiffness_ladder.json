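{
  "schema": "nichefab/design/v1",
  "name": "stiffness_ladder",
  "array_layout": {
    "rows": 2,
    "cols": 3,
    "pitch": 2200
  },
  "regions": [
    {
      "region_id": "stiffness_2.5_kPa",
      "geometry": {
        "type": "filament",
        "path": [
          [0, 150],
          [1500, 150]
        ],
        "linewidth": 250
      },
      "target": {
        "E_des": 2.5,
        "W_des": 250,
        "conjugates": {
          "RGD": 4
        }
      }
    },
    {
      "region_id": "stiffness_5_kPa",
      "geometry": {
        "type": "filament",
        "path": [
          [0, 450],
          [1500, 450]
        ],
        "linewidth": 250
      },
      "target": {
        "E_des": 5,
        "W_des": 250,
        "conjugates": {
          "RGD": 4
        }
      }
    },
    {
      "region_id": "stiffness_10_kPa",
      "geometry": {
        "type": "filament",
        "path": [
          [0, 750],
          [1500, 750]
        ],
        "linewidth": 250
      },
      "target": {
        "E_des": 10,
        "W_des": 250,
        "conjugates": {
          "RGD": 4
        }
      }
    },
    {
      "region_id": "stiffness_15_kPa",
      "geometry": {
        "type": "filament",
        "path": [
          [0, 1050],
          [1500, 1050]
        ],
        "linewidth": 250
      },
      "target": {
        "E_des": 15,
        "W_des": 250,
        "conjugates": {
          "RGD": 4
        }
      }
    },
    {
      "region_id": "stiffness_20_kPa",
      "geometry": {
        "type": "filament",
        "path": [
          [0, 1350],
          [1500, 1350]
        ],
        "linewidth": 250
      },
      "target": {
        "E_des": 20,
        "W_des": 250,
        "conjugates": {
          "RGD": 4
        }
      }
    }
  ]
}
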