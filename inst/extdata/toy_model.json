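{
  "id": "contextflux_model",
  "metabolites": [
    {
      "id": "g6p"
    },
    {
      "id": "glc"
    },
    {
      "id": "pyr"
    }
  ],
  "reactions": [
    {
      "id": "EX_glc",
      "metabolites": {
        "glc": 1
      },
      "lower_bound": 0,
      "upper_bound": 5,
      "gene_reaction_rule": "",
      "subsystem": "Exchange",
      "objective_coefficient": 0
    },
    {
      "id": "HEX1",
      "metabolites": {
        "glc": -1,
        "g6p": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "hk1 or hk2",
      "subsystem": "Glycolysis",
      "objective_coefficient": 0
    },
    {
      "id": "PYK",
      "metabolites": {
        "g6p": -1,
        "pyr": 2
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "gene_reaction_rule": "(pyk1 and pyk2) or pyk3",
      "subsystem": "Glycolysis",
      "objective_coefficient": 0
    },
    {
      "id": "EX_pyr",
      "metabolites": {
        "pyr": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Exchange",
      "objective_coefficient": 0
    },
    {
      "id": "R_bio",
      "metabolites": {
        "pyr": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Biomass",
      "objective_coefficient": 1
    }
  ],
  "genes": [
    {
      "id": "hk1"
    },
    {
      "id": "hk2"
    },
    {
      "id": "pyk1"
    },
    {
      "id": "pyk2"
    },
    {
      "id": "pyk3"
    }
  ]
}
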