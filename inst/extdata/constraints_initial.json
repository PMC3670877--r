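[
  {
    "comment": "ligand C-terminal carboxylate near the basic residue at consensus 512",
    "ligand": {"resno": 8, "elety": ["C", "O", "OXT"]},
    "receptor": {"consensus": 512},
    "max_distance": 5.0
  },
  {
    "comment": "ligand residue-8 aromatic ring near the aromatic residue at consensus 621",
    "ligand": {"resno": 8, "elety": ["CG", "CD1", "CD2", "CE1", "CE2", "CZ"]},
    "receptor": {"consensus": 621},
    "max_distance": 6.0
  }
]
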