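{
  "criteria": [
    {
      "name": "C1",
      "type": "benefit",
      "weight": 0.4
    },
    {
      "name": "C2",
      "type": "benefit",
      "weight": 0.35
    },
    {
      "name": "C3",
      "type": "benefit",
      "weight": 0.25
    }
  ],
  "experts": [
    {
      "name": "E1",
      "reference_points": [
        [40, 48],
        [50, 55],
        [0.48, 0.58]
      ]
    },
    {
      "name": "E2",
      "reference_points": [
        [38, 46],
        [48, 54],
        [0.45, 0.54]
      ]
    },
    {
      "name": "E3",
      "reference_points": [
        [45, 50],
        [52, 56],
        [0.5, 0.6]
      ]
    },
    {
      "name": "E4",
      "reference_points": [
        [48, 52],
        [50, 54],
        [0.55, 0.62]
      ]
    }
  ],
  "alternatives": [
    {
      "name": "A1",
      "outcomes": [
        {
          "name": "succeed",
          "probability": 0.75,
          "values": [
            [60, 70],
            [80, 85],
            [0.75, 0.8]
          ]
        },
        {
          "name": "fail",
          "probability": 0.25,
          "values": [
            [30, 40],
            [40, 45],
            [0.35, 0.4]
          ]
        }
      ]
    },
    {
      "name": "A2",
      "outcomes": [
        {
          "name": "succeed",
          "probability": 0.8,
          "values": [
            [70, 75],
            [72, 80],
            [0.75, 0.85]
          ]
        },
        {
          "name": "fail",
          "probability": 0.2,
          "values": [
            [32, 42],
            [46, 48],
            [0.45, 0.5]
          ]
        }
      ]
    },
    {
      "name": "A3",
      "outcomes": [
        {
          "name": "succeed",
          "probability": 0.7,
          "values": [
            [82, 88],
            [75, 80],
            [0.8, 0.84]
          ]
        },
        {
          "name": "fail",
          "probability": 0.3,
          "values": [
            [36, 44],
            [35, 40],
            [0.48, 0.5]
          ]
        }
      ]
    }
  ],
  "cpt": {
    "alpha": 1,
    "beta": 1,
    "lambda": 2,
    "mu": 0.6
  },
  "options": {
    "probability_weighting": "neo_additive",
    "expert_weights": "similarity"
  }
}
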