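---
title: "Assessing missense variants at the integrin αIIb genu: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing missense variants at the integrin alphaIIb genu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genuvar)
```

## Scope and model

genuvar implements the desk-scale workflow for judging whether a missense
variant in the αIIb genu region (the linker between the thigh and calf-1
domains of the platelet integrin αIIbβ3) is structurally disruptive. The
workflow has four independent axes — coordinate mapping, physicochemical
distance, conservation, and structure-based impact — plus a curated
catalog of the published variants in the aa471–769 window and a synthetic
data generator that makes every geometric detector testable without
downloading crystal structures.

The guiding structural picture: the thigh and calf-1 domains are β-sandwich
folds whose connecting loops carry polar residues engaged in structuring
hydrogen bonds; the genu itself contains a Ca²⁺-binding loop (backbone
carbonyls of Cys633 and Val638, side-chain carboxylates of Asp636 and
Glu673, with Cys633–Cys639 disulfide-bonded) and an H-bond clasp
(Gln626–Asn722, Asp495–Ser759) linking thigh to calf-1. A substitution can
disturb this region by deleting H-bond partners, introducing steric bumps,
removing a disulfide cysteine, removing a Ca²⁺ ligand, or burying a charge
in a hydrophobic core — each of which has a dedicated detector here.

## Coordinate systems

All public coordinates are 1-based and inclusive, in HGVS conventions:
cDNA position +1 is the A of the start ATG, protein position +1 the
initiator Met. Mature-protein numbering subtracts the cleaved signal
peptide — 31 residues for αIIb, 26 for β3 — so Asp591 of αIIb is D560 of
the mature chain. `codon_of()` is `ceiling(position/3)`;
`predict_protein_change()` extracts the codon from the CDS, checks the
stated reference base, applies the substitution and translates both codons
with the standard genetic code (`Biostrings::GENETIC_CODE`). Only
single-nucleotide substitutions are computed objects; indels, splice-site
names (e.g. `IVS29(+2)T>C` partner alleles) and genomic g. coordinates are
carried as verbatim annotation strings because the inputs needed to map
them (exon structure, genome alignment) are out of scope. Structure code
always uses the PDB file's own author numbering; conversion between HGVS
and mature numbering happens only in the coordinates module, never inside
geometry code.

## Grantham distance

The physicochemical distance is computed from the side-chain composition,
polarity and molecular-volume properties with weights α = 1.833,
β = 0.1018, γ = 0.000399. The scale factor ρ is not hard-coded: it is
derived at load time from the normalisation that defines the score — the
mean over all 190 unordered amino-acid pairs equals 100 — which yields
ρ ≈ 50.79. Integer reporting uses round-half-away-from-zero, the
convention of the published matrix. The implementation is anchored by the
scores quoted for the region's variants (Asp/Ala 126, Ile/Thr 89,
Pro/Arg 103) and spot-checked against further published entries
(Arg/Trp 101, Leu/Ile 5, Cys/Trp 215) in the test suite.

## Conservation

`column_identity()` is the fraction of panel sequences carrying the
reference residue at a column, gaps counting as mismatches (an all-gap
reference column scores 0). Strict retention requires every sequence to
match; class retention accepts exchanges within a standard
physicochemical grouping ({ILVMA}, {FWY}, {KRH}, {DE}, {STNQ}, {C}, {G},
{P}), which mirrors the situation where a position is "not conserved" in
sequence but all replacements are biochemically similar. Qualitative
labels use high ≥ 0.9 and moderate ≥ 0.5. These thresholds are design
choices, not published values — the source material uses only qualitative
wording ("highly conserved", "relatively well conserved", "poorly
conserved") — and both the thresholds and the class table are function
arguments. Real species/paralog panels are user-supplied: the published
panel figures are not machine-readable, so the module is validated on
synthetic alignments with controlled per-column conservation.

## Structure-based analysis

**Parsing.** `read_pdb()` delegates to `bio3d::read.pdb` after validating
coordinate records (malformed lines are reported with their line number).
Waters are dropped, metal HETATMs kept, hydrogens discarded, and alternate
locations resolved to the highest-occupancy conformer with ties going to
conformer A. Writing uses fixed-column formatting that is byte-deterministic.

**Hydrogen bonds.** X-ray structures of this resolution class carry no
hydrogens, so bonds are scored from heavy atoms only: a donor from the
standard protein donor set (backbone N; Arg NE/NH1/NH2; Lys NZ; His
ND1/NE2; Asn ND2; Gln NE2; Trp NE1; Ser OG; Thr OG1; Tyr OH) within
3.5 Å of an acceptor (backbone O/OXT; Asp/Glu carboxylates; Asn/Gln amide
O; Ser/Thr/Tyr hydroxyls; His ring N; Met SD), with the
antecedent–donor–acceptor angle ≥ 90° whenever the antecedent atom is
present. 3.5 Å is the conventional heavy-atom cutoff; because modelling
sessions also flag weaker "potential" contacts, a second tier up to 4.0 Å
is reported with `tier = "potential"`. Both cutoffs and the angle are
arguments of `hbond_criteria()`. Intra-residue pairs and the covalently
constrained backbone pair N(i+1)⋯O(i) are excluded.
`diff_hbonds()` restricts the before/after comparison to bonds touching
the focus residue or its pre-substitution partners, so unrelated network
noise never enters a variant report.

**Substitution.** `substitute_residue()` keeps the backbone (N, CA, C, O,
OXT) bit-identical, rebuilds CB at the ideal position from the backbone
frame, and grows the new side chain from ideal bond lengths and angles
using the natural-extension reference frame, with χ angles taken from the
maximum-probability entry of the rotamer library. The default library is a
coarse backbone-independent table (one or two modal rotamers per residue
type with their probabilities); `read_rotamer_library()` loads a fuller
TSV library if one is available. Neighbouring residues are never repacked
and no energies are computed — the output is a single-rotamer model of the
substitution, which is exactly the level of the analysis this package
reproduces. Ring closure for Pro and the fused Trp ring system is
approximate (chained dihedrals, planar to well under 0.1 Å), which is
ample for distance-based inventories.

**Clashes.** A pair clashes when its distance falls below the sum of van
der Waals radii (C 1.70, N 1.55, O 1.52, S 1.80, Ca²⁺ 2.31 Å) minus the
overlap threshold, default 0.4 Å — the conventional "serious bump" level,
chosen because the source material shows bumps graphically without
printing criteria. Covalently bonded pairs and their 1–3 neighbours are
excluded. Clash counts are monotone non-increasing in the threshold, a
property the test suite checks, and the threshold is an argument.

**Disulfides and the Ca²⁺ site.** Disulfides are Cys SG–SG pairs within
2.3 Å (covalent bridges sit near 2.05 Å). The coordination shell of a
metal ion collects oxygen atoms within 3.0 Å — Ca²⁺ in proteins is
coordinated almost exclusively by oxygen, which is why the ligand element
set defaults to `"O"` — and classifies each ligand as backbone-carbonyl
(atom name O/OXT) or side-chain. `coordination_disruption()` reports three
atom-level flags for a substitution at the site: *side-chain ligand
removed* (true when a coordinating carboxylate/hydroxyl disappears — a
backbone-carbonyl ligand survives any missense change, so Cys633Ser keeps
its ligation while Glu673Lys loses its), *disulfide lost* (the residue was
a bridged Cys and the replacement is not Cys), and *ion clash* (a newly
built side-chain atom overlaps the ion; coordinating atoms themselves are
exempt because coordination bonds are shorter than van der Waals sums by
nature).

**Orientation.** `side_chain_orientation()` classifies a side chain as
core- or exterior-facing by whether the CB→side-chain-centroid vector
makes an angle below 90° with the direction to the CA centroid of
user-designated barrel residues. Alanine falls back to the CA→CB vector;
glycine returns `NA` with an explanatory attribute.

## The synthetic-data generator

The generator produces minimal legal PDB files (ATOM/HETATM/TER/END,
single chain, occupancy 1.00, B-factor 0.00, heavy atoms only — matching
what an X-ray structure provides) in which the feature of interest is
exact by construction:

- `make_hbond_fixture(d, angle)`: an Arg donor and Asp acceptor with
  NH1⋯OD1 exactly at `d` (2.0–6.0 Å) and the CZ–NH1⋯OD1 angle as
  requested. The engineered pair is axis-aligned and snapped to the PDB
  0.001 Å coordinate grid, so the requested distance survives the
  fixed-width file format exactly rather than only to rounding error.
- `make_disulfide_fixture(d)`: two cysteines with SG–SG exactly `d`.
- `make_metal_site_fixture(n, d)`: a Ca²⁺ ion with `n` oxygen ligands at
  exactly `d`, cycling the genu shell composition (backbone-carbonyl Cys,
  side-chain Asp, backbone-carbonyl Val, side-chain Glu, numbered
  633/636/638/673), optionally with a Cys639 bridged to Cys633.
- `make_clash_pocket_fixture()`: an alanine whose site is clash-free
  natively and for smaller replacements, but where the tryptophan ring
  built by the package's own substitution machinery meets a wall residue
  at 2.5 Å (a 0.72 Å overlap).
- `make_msa(n, conservation, seed)`: an aligned panel whose per-column
  match probability to the reference is controlled.
- `make_gene_model()`: a synthetic CDS whose codons at the catalog
  positions reproduce the published cDNA→protein correspondences (codon
  591 GAC so c.1772A>C gives Asp591Ala; codon 626 CAG so c.1878G>C gives
  Gln626His), signal-peptide length 31.

All structure generators are fully deterministic; the two sequence
generators are pure functions of their arguments and a seed (default 0)
routed through a single scoped RNG so global RNG state is never touched.
Scaffold residues sit ≥ 8 Å from the engineered feature so they cannot
contaminate interaction inventories. Placement details that the contract
does not pin down (the spin of a placed residue about its anchor axis) are
chosen deterministically to maximise the clearance to already-placed
atoms.

What the fixtures deliberately do **not** emulate: real protein folds,
crystallographic symmetry, solvent, B-factor variation, alternate
conformers, or the dense second-shell packing of a real β-sandwich.
Passing tests therefore demonstrate that the detectors implement their
geometric definitions correctly (each is cross-checked against an
independent brute-force pairwise-distance oracle and against rigid-body
invariance), not that the criteria themselves capture everything a real
structure would show. Statements about specific crystal-structure contacts
(e.g. the Asp591 partner set in the real αIIbβ3 ectodomain) can be checked
by running the same functions on the downloaded structure, which this
package intentionally does not require.

## The catalog

`load_catalog()` ships the published variants of the aa471–769 window as
versioned TSV data: 16 GT-causing records (the Asp591Ala index case plus
15 literature variants), the two low-frequency platelet alloantigens
Ser503Asn (HPA-24b) and Thr650Met (HPA-20b), three database-only genu
variants (Cys633Ser, Asp636Asn, Glu673Lys, with rsIDs and recorded
frequencies), and the explicitly excluded interface record Pro772Arg.
Zygosity, GT type, mechanism flags, prediction-program calls where quoted,
and frequencies are transcribed annotations with provenance strings — they
are data the package validates, not quantities it recomputes. Frequency
strings are stored verbatim (one printed value, "0.00002/8", is ambiguous
and is deliberately left unparsed) alongside a numeric field where
unambiguous. The source tallies nine disease-causing calf-1 variants while
naming eight; the catalog records the discrepancy in its load-time note
rather than inventing a record. Domain boundaries (β-propeller ≤ 483,
thigh 484–632, genu linker 633–644, calf-1 645–769, interface 770–775, in
HGVS numbering) are approximate config defaults chosen so every published
domain placement comes out right; no authoritative boundary residues are
printed anywhere in the source material.

```{r catalog}
cat21 <- load_catalog()
table(cat21$category)
```

## Worked assessment

```{r assess}
s <- read_pdb(make_hbond_fixture(2.8, 160))
assess_variant("c.1772A>C", structure = s)
```

## Numerical choices and degenerate inputs

- Distances are exact in fixtures because engineered pairs are axis-aligned
  on the 0.001 Å grid; everything else is compared at 1e-3 Å, the PDB
  format's own resolution.
- Ties in alternate-location occupancy resolve to conformer A; equal-probability
  rotamers resolve to the first listed (the library is sorted by
  probability).
- Empty inventories are honest zero-row data frames, never `NULL`;
  `diff_hbonds` of an identity substitution is exactly empty.
- A substitution at a residue with missing backbone atoms raises a
  cannot-model error naming the atoms; glycine targets get no side chain;
  glycine orientation is `NA`, not a guess.
- An overlap threshold of `Inf` yields no clashes for any structure; a
  coordination cutoff of 0 yields an empty shell.

## Known limitations

Single-rotamer substitution without neighbour repacking overestimates
clashes for substitutions a real structure would accommodate by small
adjustments, and the heavy-atom H-bond criterion cannot distinguish donor
protonation states (His) or resolve Asn/Gln amide flips. Conservation
scoring is unweighted — a panel of close orthologs will inflate identity
relative to a phylogenetically weighted score. Long-range and dynamic
effects (the mechanism suggested for calf-1 substitutions such as
Arg755Pro/Gln) are explicitly out of scope, as are splicing predictions:
Gln626His is flagged `splicing_mRNA_decay` from its catalog annotation,
not from sequence analysis. These boundaries match the package's purpose —
reproducing and testing the short-range, geometry-level assessment — and
are the reason the impact report separates computed findings from catalog
annotations.
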