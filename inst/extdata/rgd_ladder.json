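{
  "schema": "nichefab/design/v1",
  "name": "rgd_ladder",
  "array_layout": {
    "rows": 2,
    "cols": 3,
    "pitch": 2200
  },
  "regions": [
    {
      "region_id": "rgd_0_mM",
      "geometry": {
        "type": "filament",
        "path": [
          [0, 150],
          [1500, 150]
        ],
        "linewidth": 250
      },
      "target": {
        "E_des": 8,
        "W_des": 250,
        "conjugates": []
      }
    },
    {
      "region_id": "rgd_0.5_mM",
      "geometry": {
        "type": "filament",
        "path": [
          [0, 450],
          [1500, 450]
        ],
        "linewidth": 250
      },
      "target": {
        "E_des": 8,
        "W_des": 250,
        "conjugates": {
          "RGD": 0.5
        }
      }
    },
    {
      "region_id": "rgd_1_mM",
      "geometry": {
        "type": "filament",
        "path": [
          [0, 750],
          [1500, 750]
        ],
        "linewidth": 250
      },
      "target": {
        "E_des": 8,
        "W_des": 250,
        "conjugates": {
          "RGD": 1
        }
      }
    },
    {
      "region_id": "rgd_2_mM",
      "geometry": {
        "type": "filament",
        "path": [
          [0, 1050],
          [1500, 1050]
        ],
        "linewidth": 250
      },
      "target": {
        "E_des": 8,
        "W_des": 250,
        "conjugates": {
          "RGD": 2
        }
      }
    },
    {
      "region_id": "rgd_4_mM",
      "geometry": {
        "type": "filament",
        "path": [
          [0, 1350],
          [1500, 1350]
        ],
        "linewidth": 250
      },
      "target": {
        "E_des": 8,
        "W_des": 250,
        "conjugates": {
          "RGD": 4
        }
      }
    },
    {
      "region_id": "rgd_8_mM",
      "geometry": {
        "type": "filament",
        "path": [
          [0, 1650],
          [1500, 1650]
        ],
        "linewidth": 250
      },
      "target": {
        "E_des": 8,
        "W_des": 250,
        "conjugates": {
          "RGD": 8
        }
      }
    }
  ]
}
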