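[
  {
    "gene_id": "avian_EDCRP",
    "species": "chicken",
    "exons": [
      [0, 150],
      [800, 2200]
    ],
    "coding_exon_indices": 1,
    "locus_label": "EDC",
    "neighbors": {
      "upstream": ["EDWM", "PGLYRP3"],
      "downstream": ["LOR1", "LOR2"]
    },
    "strand": "+"
  },
  {
    "gene_id": "lizard_EDCRP",
    "species": "green anole lizard",
    "exons": [
      [0, 120],
      [700, 2100]
    ],
    "coding_exon_indices": 1,
    "locus_label": "EDC",
    "neighbors": {
      "upstream": ["EDWM", "PGLYRP3"],
      "downstream": ["LOR1", "LOR2"]
    },
    "strand": "+"
  },
  {
    "gene_id": "human_KRTAP",
    "species": "human",
    "exons": [
      [0, 600]
    ],
    "coding_exon_indices": 0,
    "locus_label": "type1_keratin_cluster",
    "neighbors": {
      "upstream": ["KRT31", "KRT33A"],
      "downstream": ["KRTAP1-3", "KRT34"]
    },
    "strand": "+"
  }
]
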