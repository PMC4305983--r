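{
  "species": [
    {
      "id": "X1",
      "name": "X1",
      "kind": "dependent",
      "initial_value": 1
    },
    {
      "id": "X2",
      "name": "X2",
      "kind": "dependent",
      "initial_value": 1
    },
    {
      "id": "X3",
      "name": "X3",
      "kind": "dependent",
      "initial_value": 1
    },
    {
      "id": "X4",
      "name": "X4",
      "kind": "dependent",
      "initial_value": 1
    }
  ],
  "fluxes": [
    {
      "id": "vin",
      "substrates": [],
      "products": [
        [
          "X1",
          1
        ]
      ],
      "regulations": [
        {
          "effector": "X3",
          "sign": "inhibition"
        }
      ]
    },
    {
      "id": "v12",
      "substrates": [
        [
          "X1",
          1
        ]
      ],
      "products": [
        [
          "X2",
          1
        ]
      ],
      "regulations": []
    },
    {
      "id": "v14",
      "substrates": [
        [
          "X1",
          1
        ]
      ],
      "products": [
        [
          "X4",
          1
        ]
      ],
      "regulations": []
    },
    {
      "id": "v23",
      "substrates": [
        [
          "X2",
          1
        ]
      ],
      "products": [
        [
          "X3",
          1
        ]
      ],
      "regulations": []
    },
    {
      "id": "v3out",
      "substrates": [
        [
          "X3",
          1
        ]
      ],
      "products": [],
      "regulations": [
        {
          "effector": "X4",
          "sign": "activation"
        }
      ]
    },
    {
      "id": "v4out",
      "substrates": [
        [
          "X4",
          1
        ]
      ],
      "products": [],
      "regulations": []
    }
  ],
  "metadata": {
    "description": "branched pathway with end-product inhibition and activation"
  }
}
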