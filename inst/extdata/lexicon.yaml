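# Versioned keyword lexicon for the carotenoid name grammar and the positional
# fingerprint dialect. New substituents (e.g. further acyloxy esters) are added
# here, not in code. Tokens marked `extrapolated: true` belong to modification
# categories for which no printed example token exists; their spelling is a
# package convention.
version: 1

# The 23 chemical modification categories, in descending order of occurrence.
categories:
  - hydroxylation
  - saturation
  - cyclization-of-end-groups
  - ketolation
  - desaturation
  - stereoisomer-RS
  - apo
  - epoxidation
  - esterification
  - cis-trans-isomerization
  - glycosidation
  - aldehyde-addition
  - alkoxylation
  - carbonylation
  - isoprene-polymerization
  - nor
  - complex-polymerization
  - olide
  - sulfation
  - seco
  - retro
  - cycloaddition
  - geranylgeranyl-polymerization

end_groups: [psi, beta, gamma, epsilon, phi, chi, kappa]

# Name substituent prefixes -> fingerprint token + category.
substituents:
  hydroxy:      {token: OH,             category: hydroxylation}
  oxo:          {token: "=O",           category: ketolation}
  methoxy:      {token: Methoxy,        category: alkoxylation}
  ethanoyloxy:  {token: Ethanoyloxy,    category: esterification}
  acetyloxy:    {token: Ethanoyloxy,    category: esterification}
  glucosyloxy:  {token: Glc,            category: glycosidation}
  sulfooxy:     {token: SO4,            category: sulfation}
  carboxy:      {token: COOH,           category: carbonylation}
  isoprenyl:    {token: isoprenyl,      category: isoprene-polymerization, extrapolated: true, carbons: 5}
  geranylgeranyl: {token: geranylgeranyl, category: geranylgeranyl-polymerization, extrapolated: true, carbons: 20}
  polymer:      {token: polymer,        category: complex-polymerization, extrapolated: true}

# Two-locant bridge / ring operations.
bridges:
  epoxy:    {token: Epoxy,    category: epoxidation}
  seco:     {token: seco,     category: seco}
  retro:    {token: retro,    category: retro}
  olide:    {token: olide,    category: olide}
  cycloadd: {token: cycloadd, category: cycloaddition, extrapolated: true}

# Skeletal operations (one locant each).
skeletal:
  apo: {token: apo, category: apo}
  nor: {token: nor, category: nor}

# Hydrogenation prefixes; locants come in adjacent pairs.
hydrogenation:
  hydro:   {token: "+H", category: saturation}
  dehydro: {token: "-H", category: desaturation}

# Principal characteristic-group suffixes.
suffixes:
  ol:       {token: OH,   category: hydroxylation}
  one:      {token: "=O", category: ketolation}
  al:       {token: al,   category: aldehyde-addition}
  oic acid: {token: COOH, category: carbonylation}
  olide:    {token: olide, category: olide, pair: true}

multiplicative: {di: 2, tri: 3, tetra: 4, penta: 5, hexa: 6, hepta: 7, octa: 8}
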