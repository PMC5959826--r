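# cifsmiles

Chemical-connectivity SMILES from crystallographic CIF files.

Crystal-structure databases store unit cells, symmetry operators and atomic
coordinates — not the chemist's view of "which atoms are bonded to which".
`cifsmiles` derives that view: it reads CIF 1.1 files, rebuilds the finite
molecule a chemist would draw from the asymmetric unit (symmetry completion,
disorder resolution, duplicate-moiety reduction, missing-hydrogen inference,
1-D polymer fragments), perceives bonds from interatomic distances with the
conventions needed for organic, coordination, organometallic and ionic
species, and writes curated OpenSMILES strings suitable for substructure
search collections. It is aimed at crystallographic-database curators and at
chemists who want searchable connectivity for sets of CIF files.

## The procedure in brief

For every entry the pipeline computes three triage flags — Z′ = Z /
|general positions| (exact rational), a disorder flag (any site occupancy
< 1), and a cross-unit-bond flag (any `_geom_bond_site_symmetry_2` other than
`.`/`1_555`) — which decide whether the asymmetric unit can be used directly
or the structure must be expanded to *P*1 with bonded-cluster growth across
cell boundaries.

Bonds are perceived by the radius criterion *d*(A,B) ≤ *r*(A) + *r*(B) +
0.40 Å, optionally merged with the CIF-listed bonds; transition-metal pairs
follow the 2.85 Å / 3.0 Å metal–metal windows with the authors' listed bonds
deciding borderline cases. Kekulé orders are assigned by a constrained
maximum matching so organic-subset atoms reach a standard valence where
possible; convention rules give terminal metal carbonyls `C#[O]`, bridging
carbonyls ketone-like `C=O`, oxoanions single bonds to charged oxygens, and
metallocene rings lower-case bracketed carbons. Aromaticity follows Hückel's
4n+2 rule, with rings carrying exocyclic double bonds aromatic only when an
in-ring single bond flanked by two double bonds survives. Tetrahedral
stereocenters are read from the signed volume of their substituents; in a
non-Sohncke (racemic) space group a lone `@` mark is dropped and a
multi-center moiety is written as both enantiomers. A rule-based curation
step repairs crude strings (carbonyls, nitrate/perchlorate, coordinated
solvents, hydrogen-less water, ...), and a separate step can move haloanion
charges onto the central atom (`[P](F)(F)(F)(F)(F)[F-]` →
`[P-](F)(F)(F)(F)(F)F`) for cross-referencing with databases that prefer
that form. A discrepancy classifier compares two SMILES for the same entry
and reports the most severe difference in a 25-category severity order.

## Worked example

```r
library(cifsmiles)

fx <- build_fixture("ferrocene")          # synthetic CIF text
entry <- parse_cif(fx$cif)[[1]]
entry
#> <crystal_entry> ferrocene: 21 sites, 1 symops, 0 geom bonds, Z=1
triage(entry)
#> <entry_flags> Z'=1/1 (one), disordered=FALSE, cross_unit_bonds=FALSE [fast path]

res <- run_entry(entry)
res$smiles
#> [1] "[cH]12[Fe]3456789([cH]%10[cH]4[cH]5[cH]3[cH]9%10)[cH]1[cH]7[cH]8[cH]26"
```

The string is the canonical serialization of ferrocene under the
organometallic conventions: every ring carbon is aromatic (`c`) but
bracketed with its explicit hydrogen, because bonding to the metal puts it
outside a standard valence. Canonical equality is the intended comparison:

```r
canon_smiles(res$smiles) ==
  canon_smiles("[Fe]12345678([cH]9[cH]1[cH]2[cH]3[cH]49)[cH]1[cH]5[cH]6[cH]7[cH]81")
#> [1] TRUE
```

Ionic crystals collapse to disconnected ions, haloanions can be recharged,
and two representations of the same entry can be classified:

```r
run_entry(parse_cif(build_fixture("nacl")$cif)[[1]])$smiles
#> [1] "[Cl-].[Na+]"
recharge_haloanions("[P](F)(F)(F)(F)(F)[F-]")
#> [1] "[P-](F)(F)(F)(F)(F)F"
classify_discrepancy("CN(=O)=O", "C[N+](=O)[O-]")
#> [1] "nitro_representation"
```

A thin command-line front end ships in `inst/cli/cifsmiles`
(`triage`, `molecule`, `convert`, `curate`, `recharge`, `classify`,
`fixtures` subcommands) for running the pipeline from a shell.

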