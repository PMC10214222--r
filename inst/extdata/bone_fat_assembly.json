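{
  "schema": "nichefab/design/v1",
  "name": "bone_fat_assembly",
  "array_layout": {
    "rows": 3,
    "cols": 4,
    "pitch": 1500
  },
  "regions": [
    {
      "region_id": "adipogenic_core",
      "geometry": {
        "type": "rect",
        "origin": [375, 375],
        "width": 250,
        "height": 250
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
      "region_id": "osteogenic_south",
      "geometry": {
        "type": "rect",
        "origin": [125, 125],
        "width": 750,
        "height": 250
      },
      "target": {
        "E_des": 8,
        "W_des": 250,
        "conjugates": {
          "RGD": 2,
          "BMP2": 0.008
        }
      }
    },
    {
      "region_id": "osteogenic_north",
      "geometry": {
        "type": "rect",
        "origin": [125, 625],
        "width": 750,
        "height": 250
      },
      "target": {
        "E_des": 8,
        "W_des": 250,
        "conjugates": {
          "RGD": 2,
          "BMP2": 0.008
        }
      }
    },
    {
      "region_id": "osteogenic_west",
      "geometry": {
        "type": "rect",
        "origin": [125, 375],
        "width": 250,
        "height": 250
      },
      "target": {
        "E_des": 8,
        "W_des": 250,
        "conjugates": {
          "RGD": 2,
          "BMP2": 0.008
        }
      }
    },
    {
      "region_id": "osteogenic_east",
      "geometry": {
        "type": "rect",
        "origin": [625, 375],
        "width": 250,
        "height": 250
      },
      "target": {
        "E_des": 8,
        "W_des": 250,
        "conjugates": {
          "RGD": 2,
          "BMP2": 0.008
        }
      }
    }
  ]
}
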