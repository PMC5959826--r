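---
title: "From crystal structures to curated SMILES: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From crystal structures to curated SMILES: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cifsmiles)
```

# The problem

A CIF file describes a crystal: cell parameters, a space-group operator
list, and fractional coordinates for the atoms of one asymmetric unit.
Chemists, however, ask connectivity questions — "which entries contain a
coordinated pyridine?" — that require a molecular-graph representation.
Translating between the two views is not mechanical. The asymmetric unit
may be a fragment of the molecule (species sitting on symmetry elements),
several molecules, or a slab of an infinite framework; occupancies encode
disorder; hydrogens are often missing; and for organometallic, ionic and
polymeric species "chemical connectivity" is a matter of convention rather
than observation. `cifsmiles` implements one coherent set of conventions
end to end and writes the result as OpenSMILES strings.

# Pipeline

## Triage

Three flags route every entry (`triage()`):

* **Z′** = Z / (number of listed symmetry operators), kept as an exact
  rational. The operator count is taken verbatim from the file — centring
  translations must be listed, which matches how structures are deposited.
  Entries lacking `_cell_formula_units_Z` are rejected rather than guessed:
  a wrong Z silently corrupts the moiety multiplicities.
* **disorder**: any site occupancy strictly below one. Occupancies within
  10^-6 of 1 are treated as full — trailing-digit noise such as `0.9999999`
  occurs in deposited files.
* **cross-unit bonds**: any `_geom_bond_site_symmetry_2` code other than
  `"."`/`"1_555"`, indicating bonds leaving the asymmetric unit (a moiety on
  a symmetry element, or a polymer).

`Z′ = 1`, ordered, and no cross-unit bonds is the fast path: the asymmetric
unit *is* the molecule and symmetry reconstruction is skipped.

## Building the molecule

Otherwise the entry is expanded to *P*1 (`expand_to_p1()`): every operator
is applied to every site, placements that coincide within 0.2 Å are merged
(special positions; the tolerance is far below any bonding distance and far
above coordinate noise), and bonded clusters are grown across cell
boundaries so no perceived bond dangles. Growth is bounded at three cells
in any direction; a cluster that maps onto itself under a pure lattice
translation is polymeric, and the rank of the collected translations is its
dimensionality.

Disorder is resolved per assembly by keeping the group with the largest
occupancy sum (ties: lexicographically smallest group label, logged);
moieties with mean occupancy below 0.1 are dropped, mirroring how trace
components of mineral-like mixtures are usually ignored. Explicit hydrogen
atoms are folded into heavy-atom hydrogen counts. Two kinds of chemically
obvious missing hydrogens are then inferred: isolated oxygen atoms are read
as water, and an oxygen singly bonded to carbon at more than 1.38 Å with no
hydrogen becomes a hydroxyl unless a monoatomic counter-ion suggests an
alkoxide/carboxylate. The 1.38 Å threshold separates C–O single bonds
(≈1.43 Å) from carbonyls (≈1.22 Å).

Isomorphic moieties (decided on canonical SMILES of the connectivity graph)
are merged with multiplicities, divided by the greatest common divisor of
the non-solvent moieties; a whitelisted solvent left with a fractional
share (hemi- and sesquihydrates) is rounded up to one copy — the main
species is never duplicated. The solvent whitelist (water through toluene,
14 formulas) is configurable in spirit but deliberately conservative:
nothing more complex than a toluene moiety is ever treated as solvent.

Polymers: a 1-D chain is represented by two connected repeat units — the
unit plus its image under the recorded generating translation (smallest
norm when several exist, logged), with dangling continuation bonds dropped.
2-D/3-D covalent frameworks have no automatic SMILES and produce a
structured `unsupported` result. Extended *ionic* frameworks are different:
alkali and alkaline-earth cations are severed into bare cations (they keep
their bonds in finite moieties such as crown-ether complexes), metallic
crystals collapse to isolated atoms, and a framework of one metal plus
simple monoatomic anions is fully disconnected into ions. After severing,
monoatomic pieces are finite ions; a framework that *remains* both extended
and covalent after this step is reported unsupported.

## Bond perception and orders

Bonds come from the distance criterion d ≤ r(A) + r(B) + offset with a
bundled single-bond covalent radius table and a default offset of 0.40 Å,
chosen once so that standard bond lengths pass with margin while
second-neighbor contacts fail. Hydrogen bonds only to its single nearest
heavy neighbor. The CIF-listed bonds can replace or extend the perceived
set (`bond_source = "geom"`/`"merged"`); transition-metal pairs follow the
metal–metal windows (always bonded below 2.85 Å; with a bridging supporting
ligand never bonded above 3.0 Å; in between the authors' listed bonds
decide), and metal–metal bond orders are never guessed.

Kekulé orders are assigned by a maximum matching over atoms that have not
reached a standard valence. Two details do most of the convention work:

* metal bonds do not consume ligand valence during matching, and
* a penalty steers double bonds away from metal-bound atoms.

Together these yield the single-resonance-form convention for chelating
carboxylates and acetylacetonates, the bracket-free anionic nitrogen of
imidazolate complexes, and the η³-allyl form (one unbracketed terminal
carbon, internal double bond) without any dedicated rules. Dedicated rules
remain for terminal metal carbonyls/isocyanides (`C#[O]`, bridging `C=O`),
oxo groups (doubles on uncharged oxygens up to the element's highest oxo
valence), metallocene-type rings (every ring atom carbon and bonded to one
common metal: aromatic, bracketed, no Kekulé unsaturation) and all-carbon
3-connected cages of 60+ atoms (aromatic wholesale, substituted vertices
aliphatic). Matching ties are broken by content-based refinement ranks, so
the chosen resonance form does not depend on atom storage order. Leftover
unsaturation on a carbon bonded to exactly one metal raises that metal bond
(carbene-like); anything else is flagged for brackets and logged.

## Aromaticity

A ring of size 4–7 with no exocyclic double bonds is aromatic when every
atom can join the conjugated system (engaged in a double bond, a lone-pair
N/O/S, or a carbanion) and the π count obeys 4n+2 — each double-bond atom
contributes one electron, lone-pair heteroatoms and carbanions two. Rings
carrying exocyclic double bonds are aromatic iff at least one in-ring
single bond flanked by two in-ring double bonds survives. This single test
separates cyclopentadienone and 2-pyridone (aromatic) from quinones and
uracil (Kekulé), and was chosen over a pure π-count for exocyclic systems
because no additive electron bookkeeping reproduces all four verdicts at
once: the surviving-single-bond criterion is the operative rule, with
Hückel counting reserved for fully endocyclic systems.

## Writing, brackets and stereochemistry

Atoms are bracketed whenever the Kekulé bond-order sum plus hydrogens is
not a standard valence, the charge is non-zero, a parity is recorded, or
the element lies outside the organic subset. This is why a
pyridine-type nitrogen bound to a metal is `[n]` (sum 4) while the
imidazolate nitrogen is a bare `n` (sum 3), and why metallocene carbons are
`[cH]`.

Formal charges are assigned only where convention is unambiguous:
monoatomic ions by group, terminal atoms of oxo- and haloanions,
uncoordinated carboxylates/phenolates, ammonium/phosphonium. Coordination
compounds receive no charges at all, neither metal nor ligand.

Tetrahedral parities come from the sign of the signed volume spanned by the
four substituents (an implicit hydrogen is placed at the idealized fourth
vertex); substituent distinctness uses graph-refinement ranks, which
matches SMILES semantics rather than 3-D environments. Centres with
|volume| < 0.1 Å³ are refused with a warning — disordered or poorly refined
structures must not emit spurious marks. If the space group is Sohncke
(all rotation determinants +1) the asymmetric unit's configuration
represents the crystal and marks are kept. Otherwise the crystal is
racemic: a single mark is removed ("unspecified" re-read as "both
enantiomers"), a multi-centre moiety is written as both enantiomers (the
second obtained by swapping every `@`/`@@`), and a meso moiety — canonically
equal to its mirror image — is written once. The policy is idempotent: an
already-doubled pair is recognized and left alone.

## Canonicalization

Canonical ranks come from iterative refinement of content-based invariants
(element, charge, hydrogen count, aromatic flag, bracket status, degree,
bond-class multiset). Remaining ties are resolved by exploring candidate
desymmetrizations; branches whose refined partitions have identical
content signatures (including parity resolved against the rank order —
necessary so meso and chiral forms canonicalize differently) are visited
once, and the lexicographically smallest labeling wins. The exploration is
capped at 2000 labelings per moiety; beyond the cap a deterministic greedy
choice is used, which is exact whenever the remaining ties are automorphic
— the case for the symmetric cages where the cap could matter. Equality of
structures is always tested on canonical strings, never byte-wise against
any particular serialization.

## Curation and the alternative collection

Curation rules are structural rewrites dispatched per category (metal
carbonyls/isocyanides, perchlorate, nitrate/nitro, coordinated azide,
haloanion terminal charges, coordinated MeCN/DMSO/amide-O, imine single-bond
fixes, phosphane hydrogen removal, hydrogen-less water), applied in catalog
order with every change logged as (category, before, after); replaying the
log reproduces the output. Graph rewriting was preferred over the
historical text find/replace because string patterns are fragile to ring
numbering; a strict text mode remains for the rules where a literal
replacement is safe. A rule whose output fails to re-parse is rejected for
that record and logged. The interactive yes/no review of the original
workflow becomes accept-all plus a complete audit log; the dual
bond-source check (perceived vs merged) likewise becomes a review flag with
the perceived-only result carried forward — a documented default rather
than a human choice. The shipped rule catalog implements the named
families and is deliberately extensible; it does not claim completeness
against any historical script.

The haloanion recharge step rewrites moieties with exactly two element
types — a central B/P/S/As/Al/Bi/Sn/Si/Sb atom plus halogens — and negative
total charge, moving the whole charge onto the central atom with the most
halogen neighbors (ties: lowest canonical rank) and only committing when
the total charge is conserved. The rewrite preserves the input layout so
the transformation is readable record by record.

## Discrepancy classification

`classify_discrepancy()` compares two SMILES for one entry through a
cumulative chain of normalizations in increasing severity (directional
marks, heteroatom hydrogen/tautomer placement, chirality, racemate
doubling, nitro and related group conventions, charges, aromatic-vs-Kekulé
writing, bond orders, ionic representation, solvent-oxygen moieties); the
first level at which the sides agree names the category. Pairs that stay
different are classified structurally, most severe first: heavy-atom
composition, missing carbon, missing moieties, stoichiometry, moiety and
ring counts, connectivity. Hydrogen counts are excluded from the
composition test because hydrogen differences carry their own, least-severe
category. The boundary between "different representation of other groups"
and "different charge settings" is drawn by a motif list (nitro/nitrate,
N-oxide, diazo/azide) that is documented as extensible.

# The synthetic fixtures

Every test structure is generated in code (`build_fixture()`): idealized
geometries from standard bond lengths placed in generous cells, covering
aromatic edge cases, coordination and organometallic conventions,
carbonyls, boranes, metallocenes, ionic frameworks, disorder, special
positions, Z′ ≠ 1, 1-D/2-D polymers, Sohncke/racemic/meso stereochemistry
and haloanions. Generation asserts that every intended bond satisfies the
radius rule and every intended non-bond misses it by at least 0.3 Å (the
metal-to-apex contact of four-membered chelate rings is the documented
borderline exception). The fixtures emulate clean, ordered, fully refined
structures; they do not emulate coordinate noise, twinning, unresolvable
disorder, wrong author metadata or SQUEEZE-removed solvent. Passing tests
therefore demonstrate that the conventions are implemented as specified,
not that real deposited files never need human review — the review flags
and audit logs exist precisely because they do.

Problem sizes are chosen for a laptop-scale test run: molecules up to ~50
atoms, 20–100 random permutations per canonical-invariance check, 500
randomized haloanions, 100 random chiral moieties, and operator closure of
all 230 space-group types from a bundled generator table.

# Known limitations

* Double-bond (E/Z) configuration is neither perceived nor written;
  directional bond characters are accepted on input and read as single
  bonds.
* Stereo descriptors are tetrahedral only — no square-planar,
  trigonal-bipyramidal or octahedral marks.
* 2-D and 3-D covalent polymers are reported, not converted.
* Polycentric bonding (boranes, hapto ligands) is represented by plain
  two-centre bonds to every neighbor, with brackets and explicit hydrogens.
* The refinement-based canonicalizer is exact up to non-automorphic ties
  surviving refinement, which do not occur in chemically ordinary graphs;
  the branching cap is the safeguard for pathological symmetry.
* Formal-charge assignment is conservative by design; species whose charge
  placement is genuinely ambiguous are left uncharged.
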