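[
  {"name": "phytoene", "domains": ["Archaea", "Bacteria", "Eukaryotes"]},
  {"name": "15-cis-phytofluene", "domains": ["Archaea", "Bacteria", "Eukaryotes"]},
  {"name": "all-trans-phytofluene", "domains": ["Archaea", "Bacteria", "Eukaryotes"]},
  {"name": "lycopene", "domains": ["Archaea", "Bacteria", "Eukaryotes"]},
  {"name": "beta-carotene", "domains": ["Archaea", "Bacteria", "Eukaryotes"]},
  {"name": "(13Z)-beta-carotene", "domains": ["Archaea", "Bacteria", "Eukaryotes"]},
  {"name": "alpha-carotene", "domains": ["Archaea", "Bacteria", "Eukaryotes"]},
  {"name": "prolycopene", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "3,4-dehydrolycopene", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "bisdehydrolycopene", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "zeta-carotene", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "asymmetric zeta-carotene", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "neurosporene", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "phillipsiaxanthin", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "spheroidenone", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "gamma-carotene", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "rubixanthin", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "1-hydroxy-1,2-dihydroneurosporene", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "torulene", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "(9Z)-beta-carotene", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "zeaxanthin", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "isozeaxanthin", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "beta-cryptoxanthin", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "isocryptoxanthin", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "echinenone", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "3'-hydroxyechinenone", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "canthaxanthin", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "adonirubin", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "mutatochrome", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "mutatoxanthin", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "epsilon-carotene", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "lutein", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "tethyatene", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "isorenieratene", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "renieratene", "domains": ["Bacteria", "Eukaryotes"]},
  {"name": "crocetindial", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "retinal", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "apo-8'-lycopenal", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "beta-apo-13-carotenone", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "beta-apo-14'-carotenal", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "beta-apo-10'-carotenal", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "apo-13-zeaxanthinone", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "apo-15-zeaxanthinal", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "apo-12'-zeaxanthinal", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "apo-10'-zeaxanthinal", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "beta-apo-8'-carotenal", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "beta-citraurin", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "beta-citraurinol", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "beta-ionone", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "4-oxo-beta-ionone", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "(3R)-3-hydroxy-beta-ionone", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true},
  {"name": "tectoionols A", "domains": ["Bacteria", "Eukaryotes"], "apocarotenoid": true}
]
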