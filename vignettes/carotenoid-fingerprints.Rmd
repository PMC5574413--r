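---
title: "Positional carotenoid fingerprints: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional carotenoid fingerprints: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carofp)
```

## The model

Carotenoid semi-systematic names are compositional: a `carotene` stem
(a C40 polyene numbered 1–15 and 1′–15′ along the chain, with methyl carbons
16–20 and 16′–20′), two Greek end-group descriptors, and locanted
modification prefixes/suffixes. Because the grammar is closed, a name can be
rewritten loss-free into a *positional fingerprint*: a set of element tokens,
one per chemical modification, each carrying the position(s) of the modified
carbon(s). Fingerprint equality is exact token equality — `3-OH` and `3'-OH`
are different elements — which is what distinguishes these fingerprints from
hashed or bit-vector fingerprints and makes positional substructure queries
and precise similarity possible for this compound class.

The pipeline is `parse_name()` → `build_fingerprint()` →
`canonical_render()`, with `parse_fingerprint()` as the inverse of the
renderer. Every element maps to exactly one of 23 modification categories
(`modification_categories()`); the end-group pair is itself an element
(category *cyclization of end groups*).

### Canonical dialect

The literature prints the same fingerprint with varying typography
(`6′,7′–H` with Unicode primes and en-dash, `4 = O` with spaces). All
parsers accept these variants; all renderers emit one ASCII dialect:
`'` for the prime, `-H`/`+H`/`=O` unspaced, elements joined by `", "`.
Element order within a rendered fingerprint is fixed: stereo descriptors
(one combined `(…)` prefix for R/S centers, another for Z/E), then
desaturation, saturation, `-OH`, `-Methoxy`, acyloxy, `-Glc`, `-al`,
`-COOH`, `=O`, `-SO4`, `-Epoxy`, `nor`, `seco`, `retro`, `olide`, `apo`,
and the end-group token last; within a category, unprimed locants precede
primed ones, ascending. This order was chosen to be consistent with all
sixteen reference fingerprints shipped in `inst/extdata/entries.tsv` and is
a dialect choice of this package, not part of the nomenclature.

Two boundary conventions: mono-apocarotenoids keep the cleaved side as an
open end (`beta,-`), while diapocarotenoids carry no end-group element at
all (the reference diapocarotenoid row prints none). Stereo centers are
stored per-center (enabling granular similarity) and only combined at
render time.

### Keyword lexicon

The grammar keywords live in a versioned YAML table
(`inst/extdata/lexicon.yaml`): substituent prefixes (`hydroxy` → `OH`,
`methoxy`, `ethanoyloxy`, `oxo`, `glucosyloxy`, `sulfooxy`, …), bridge
operations (`epoxy`, `seco`, `retro`, `olide`), skeletal operations (`apo`,
`nor`), hydrogenation (`hydro`/`dehydro`, whose locants pair up two at a
time in listed order; odd counts are an error, never silently dropped), and
principal-group suffixes (`-ol`, `-one`, `-al`, `-oic acid`, `-olide`). New
esters or glycosides are added to the YAML without code changes. Four of
the 23 categories (isoprene, geranylgeranyl and complex polymerizations,
cycloaddition) have no printed token example anywhere in the reference
material; their lexicon tokens (`isoprenyl`, `geranylgeranyl`, `polymer`,
`cycloadd`) are marked `extrapolated` in the YAML and are a naming
convention of this package. Unknown tokens raise classed errors naming the
offending token, so lexicon gaps surface in tests instead of being skipped.

## Carbon accounting

`carbon_count()` counts *skeleton* carbons: 40 for the carotene stem, minus
the carbons cleaved off by each `apo` locant, minus one per `nor`, plus five
per isoprenyl attachment. The apo lookup follows the numbering scheme:
cleavage retains the named carbon and removes the chain beyond it together
with the methyls attached to removed chain carbons. A single apo with an
unprimed locant removes the entire primed half plus the unprimed chain
beyond the locant (so a 15-apo aldehyde retains C20, the retinal skeleton);
primed locants, and both locants of a diapo pair, remove toward the nearer
end (8′-apo → C30; 8,8′-diapo → C20). The table reproduces the known
stoichiometry of the C30 apocarotenal, retinal, the C35 apocarotenoic acid
and the C20 dialdehyde, and the test suite cross-checks it against every
fixture entry that carries a molecular formula.

Ester and glycoside carbons are deliberately *not* counted: the carbon
number used for classification is the skeleton count (fucoxanthin, formula
C42 with its acetate, is a C40 carotenoid). For the same reason the fixture
supplies formulas only where the formula carbon count equals the skeleton
count, keeping the formula-vs-lookup consistency invariant meaningful.

The C45/C50 classes arise from isoprenyl/geranylgeranyl attachment; since no
reference name for them is printed, the +5-carbon rule is an assumption
flagged here rather than a validated behaviour.

## Classification

`carbon_class()` maps exact skeleton counts to C30/C40/C45/C50. Skeletons
truncated below 40 by apo cleavage or nor elimination report as
`"C40-originated"`, matching how apocarotenoids are tallied in the
domain-of-life statistics; the one exception is a C30 skeleton with two apo
elements, which is the bacterial C30 diapocarotenoid pathway and keeps the
C30 class.

`classify_structural()` applies the 14 category membership rules
(any `-OH` → hydroxycarotenoid, `-Epoxy` → epoxycarotenoid, …, a 6,7 or
6′,7′ desaturation → allene, 7,8 or 7′,8′ → acetylene, exactly two `apo`
elements → diapocarotenoid) and reports every satisfied category plus a
single *primary* (most derived) one. The primary is the last satisfied
category in a fixed priority order. The reference table's own row order
would make its olide example (an allenic lactone carrying `6',7'-H`)
classify as an allene; since every reference example must classify to its
own row, the package's priority order places Olidecarotenoids after the
allene/acetylene marks — a lactone bridge on an allenic skeleton is treated
as the more derived feature. All fourteen reference rows classify to their
own categories under this order, which is asserted in the test suite.

## Function prediction

Six boolean rules, all decidable from the fingerprint and carbon count:

- *provitamin A*: a `beta` end group and no elements beyond end groups and
  stereo descriptors. The strict default treats skeletal hydrogenation
  (`±H`) as a modification, so a dihydro-β-carotene is excluded;
  `lenient_provitamin = TRUE` relaxes exactly that. Only β rings qualify —
  γ rings (partial activity in the literature) do not.
- *membrane stabilizer*: oxygen-bearing elements (`=O`, `-OH`, `-Methoxy`,
  `-Epoxy`, `-Glc`, `-al`, `-SO4`, `-COOH`, acyloxy) at both an unprimed
  and a primed locant — "oxygen on both ends" operationalized through the
  prime, not restricted to ring positions.
- *odorous* and *allelochemical*: carbon number strictly below 20 with any
  of `=O`, `-OH`, `-al`, `-Epoxy`. One shared rule sets both flags; they
  are carried separately for forward compatibility.
- *antiproliferative*: a 5,6- or 5,8-epoxide (either half) on a
  `beta,beta` skeleton.
- *reverse MDR*: the same epoxide with `beta,beta`, `beta,kappa` or
  `beta,epsilon` end groups — hence antiproliferative implies reverse MDR,
  a property asserted over synthetic fingerprints.

## Similarity

`weighted_tanimoto()` computes `W(Q ∩ E) / W(Q ∪ E)` with exact-element
intersection. Stereo elements participate by default (positional information
is the point of these fingerprints); `include_stereo = FALSE` drops them.
With uniform weights the score reduces to the classic set Tanimoto, which
the test suite verifies against an independent brute-force oracle
exhaustively over all subset pairs of a five-element universe.

The reference weighting principle — inversely proportional to category
occurrence, with frequent hydroxylation/saturation down-weighted — is
published, but the actual weight values are not. `compute_weights()`
therefore estimates `w_c = K / n_c` from whatever corpus it is given, with
`K` set so the rarest observed category weighs 1, unobserved categories
weighing 1, and the default exceptions clamping hydroxylation and
saturation to the minimum computed weight. Results are deterministic per
dataset and overridable via a JSON weight file (`read_weights()`). Ranked
search breaks score ties by ascending accession for reproducible output.

## Profiles and domain statistics

Organism profiles are plain accession sets with an ordered
`(rank, taxon)` lineage (no taxonomy service, no network); profile
similarity is the unweighted Tanimoto. `domain_shared_sets()` partitions
carotenoids by their annotated domain presence into the seven Venn regions
and derives pairwise shared totals. The packaged domain lists encode the
published presence annotations (seven carotenoids common to all three
domains; forty-five more shared by bacteria and eukaryotes, seventeen of
them apocarotenoids) rather than inferring presence from the full curated
organism database, which is not distributed. Isomer extraction compares
formulas and de-stereoized fingerprints; end-group elements are retained in
both comparisons so that α- and β-carotene are structural, not stereo,
isomers.

## The synthetic generator

`generate_synthetic()` draws random valid parses — an end-group pair from
the seven Greek descriptors (or mono-apo/diapo skeletons at realistic 4–12
positions), up to three R/S centers at the 3/5/6 ring positions, ring
substituents at positions 1–4 with non-colliding locants, hydrogenation
pairs along the chain, 5,6/5,8 epoxides, and occasional nor/olide marks —
then renders the canonical name and fingerprint. It emulates the
*grammatical* structure of real carotenoid names, not their chemistry: no
valence or conjugation model is enforced, so a passing round-trip suite
demonstrates parser/renderer correctness on the name grammar, not chemical
plausibility of every generated structure. Generation is deterministic per
seed and leaves the caller's RNG state untouched.

Problem sizes used by the shipped suites: 1000 seeded entries for the
round-trip identity checks (both name→parse and fingerprint→string
directions), 100 random pairs for similarity symmetry/bounds/self-identity,
and the exhaustive 32×32 subset grid for the uniform-weight oracle.

## Degenerate inputs and numerical choices

All scores are exact rational arithmetic in doubles; no tolerances are
involved anywhere. Empty fingerprint unions, empty profiles, unknown
accessions/organisms/taxa, locants outside 1–20, odd hydrogenation locant
counts and unknown keywords each raise a distinct classed condition
(`caro_*`), which the CLI maps to exit code 2 (usage errors exit 1). File
loads are atomic: every bad row is reported with its line number, and
nothing loads.

## Known limitations

- Only the carotenoid name grammar is supported — no general IUPAC organic
  nomenclature, no name→structure generation, no non-carotenoid terpenoids.
- Trivial-name stems (e.g. ionone-type apocarotenoid names) are not parsed;
  such entries enter via their fingerprint strings instead.
- The inverse-occurrence weights reproduce the published *principle*; the
  production database's exact weight values are unpublished, so ranked
  lists need not match the hosted search.
- Database-wide totals (full entry and organism counts) require the hosted
  dataset and are out of scope; all statistics here run on the packaged
  reference lists or user data.
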