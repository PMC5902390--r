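# genuvar

Structural impact assessment of missense variants in and around the genu
("knee") of the platelet integrin αIIb subunit.

## The problem

The fibrinogen receptor αIIbβ3 rests on platelets in a bent conformation
whose fulcrum is the αIIb genu, the short linker between the thigh and
calf-1 domains. Missense variants in this region cause Glanzmann
thrombasthenia (GT), a recessive bleeding disorder with absent (type I) or
severely reduced (type II) αIIbβ3. Assessing such variants at the desk
combines four ingredients, all implemented here:

- **Coordinate mapping.** HGVS cDNA numbering (+1 at the A of the start
  ATG) to codon/protein numbering (`codon = ceiling(position/3)`), and HGVS
  protein numbering to the mature-protein numbering used in crystal
  structures (subtract the cleaved signal peptide: 31 residues for αIIb,
  26 for β3 — so αIIb Asp591 is D560 of the mature subunit).
- **Grantham physicochemical distance.** For amino acids *i, j* with
  composition *c*, polarity *p* and molecular volume *v*:
  *D<sub>ij</sub>* = ρ·[α(c<sub>i</sub>−c<sub>j</sub>)² +
  β(p<sub>i</sub>−p<sub>j</sub>)² + γ(v<sub>i</sub>−v<sub>j</sub>)²]^½,
  with α = 1.833, β = 0.1018, γ = 0.000399 and ρ scaling the mean over the
  190 amino-acid pairs to 100.
- **Conservation.** Per-column identity fractions, strict vs
  physicochemical-class retention, and qualitative labels on aligned
  species/paralog panels.
- **Structure-based analysis** on PDB coordinates: substitution of a
  residue by the maximum-probability rotamer of its replacement (ideal
  internal coordinates, backbone untouched), then differencing of the
  hydrogen-bond network (heavy-atom donor–acceptor ≤ 3.5 Å, donor angle
  ≥ 90°), van der Waals bump detection (overlap > 0.4 Å), disulfide-bridge
  bookkeeping (SG–SG ≤ 2.3 Å), and Ca²⁺ coordination-shell analysis
  (oxygen ligands ≤ 3.0 Å, classified backbone-carbonyl vs side-chain).

The package also ships a schema-validated catalog of the published
variants in the αIIb aa471–769 region (16 GT-causing records, 2 platelet
alloantigens, 3 rare database-only genu variants) and a deterministic
synthetic-structure generator so that every detector is testable offline
against brute-force oracles.

## Worked example

```r
library(genuvar)

# the index-case variant, assessed on a synthetic salt-bridge structure
s   <- read_pdb(make_hbond_fixture(2.8, 160))
rep <- assess_variant("c.1772A>C", structure = s)
rep
#> <impact_report> c.1772A>C p.Asp591Ala (D560A mature)
#>   domain:   thigh
#>   Grantham: 126
#>   conservation: not assessed
#>   structure: 1 H-bond(s) lost, 0 gained, 0 clash(es)
#>   - Asp -> Ala at position 591 (thigh domain): Grantham distance 126 (large physicochemical deviation).
#>   - Substitution by Ala results in the loss of 1 structuring H-bond(s) (partners: ARG551).
#>   - Catalog: GT-causing record, type I GT (homozygous).
```

Reading the output: the c.1772A>C transversion falls in codon 591 and
converts Asp (GAC) to Ala (GCC); position 591 sits in the thigh domain and
maps to D560 of the mature subunit; the Asp→Ala exchange is
physicochemically radical (Grantham 126); and on the structure the
substitution deletes the engineered Asp–Arg hydrogen bond without
introducing steric bumps. The catalog identifies the variant as the
homozygous type I GT index record.

Other entry points: `grantham()`, `grantham_matrix()`,
`predict_protein_change()`, `conservation_profile()`, `detect_hbonds()`,
`detect_clashes()`, `detect_disulfides()`, `metal_coordination()`,
`coordination_disruption()`, `side_chain_orientation()`,
`load_catalog()` / `filter_catalog()`. A thin command-line wrapper lives
at `inst/scripts/genuvar.R` (e.g. `Rscript inst/scripts/genuvar.R grantham D A`).

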