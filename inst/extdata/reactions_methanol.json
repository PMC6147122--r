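[
  {
    "name": "methanol_disproportionation_formate",
    "substrate": "methanol",
    "dG_total": -203.4,
    "reactants": [
      {"species": "methanol", "formula": "CH3OH", "charge": 0, "coef": 3}
    ],
    "products": [
      {"species": "formate", "formula": "HCOO", "charge": -1, "coef": 1},
      {"species": "proton", "formula": "H", "charge": 1, "coef": 1},
      {"species": "methane", "formula": "CH4", "charge": 0, "coef": 2},
      {"species": "water", "formula": "H2O", "charge": 0, "coef": 1}
    ]
  },
  {
    "name": "methanol_disproportionation_co2",
    "substrate": "methanol",
    "dG_total": -319.4,
    "reactants": [
      {"species": "methanol", "formula": "CH3OH", "charge": 0, "coef": 4}
    ],
    "products": [
      {"species": "carbon_dioxide", "formula": "CO2", "charge": 0, "coef": 1},
      {"species": "methane", "formula": "CH4", "charge": 0, "coef": 3},
      {"species": "water", "formula": "H2O", "charge": 0, "coef": 2}
    ]
  }
]
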