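[
  {
    "comment": "ligand C-terminal carboxylate near the photolabeled contact at consensus 725",
    "ligand": {"resno": 8, "elety": ["C", "O", "OXT"]},
    "receptor": {"consensus": 725},
    "max_distance": 5.0
  }
]
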