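[
  {
    "name": "Cyanidioschyzon merolae",
    "lineage": [["domain", "Eukaryotes"], ["phylum", "Rhodophyta"], ["genus", "Cyanidioschyzon"]],
    "carotenoids": ["CA00309", "FX0003"]
  },
  {
    "name": "Prochlorothrix hollandica PCC 9006",
    "lineage": [["domain", "Bacteria"], ["phylum", "Cyanobacteria"], ["genus", "Prochlorothrix"]],
    "carotenoids": ["CA00309", "FX0003"]
  },
  {
    "name": "Cyanophora paradoxa",
    "lineage": [["domain", "Eukaryotes"], ["phylum", "Glaucocystophyceae"], ["genus", "Cyanophora"]],
    "carotenoids": ["CA00309", "FX0003"]
  },
  {
    "name": "Glaucocystis nostochinearum",
    "lineage": [["domain", "Eukaryotes"], ["phylum", "Glaucocystophyceae"], ["genus", "Glaucocystis"]],
    "carotenoids": ["CA00309", "FX0003"]
  }
]
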