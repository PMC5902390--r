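variant	cdna	gene	category	gt_type	index_case	zygosity	mechanisms	uncertain	rsid	maf_text	maf_numeric	hpa_system	provenance	notes
p.Ala477Pro		ITGA2B	GT-causing	II	FALSE	homozygous	hbond_loss	FALSE					Fu et al. 2012	3rd beta-strand of blade 7 of the beta-propeller; Pro weakens H-bonds linking strands 3 and 4; surface expression 14% of wild type in CHO cells; pro-alphaIIb retained in the ER
p.Ser503Asn		ITGA2B	HPA	n/a	FALSE	polymorphism		FALSE				HPA-24b	Jallu et al.	low-frequency platelet alloantigen in the thigh domain; no loss of function
p.Pro507Arg		ITGA2B	GT-causing	I	FALSE	homozygous		FALSE					Peretz et al.	poorly conserved loop-tip residue, partially buried; prediction programs disagree (deleterious/possibly damaging/polymorphism)
p.Ile518Asp		ITGA2B	GT-causing	I	FALSE	compound heterozygous with c.1946+3G>T	buried_charge	FALSE					Nurden et al. 2015, case 3	hydrophobic thigh beta-barrel residue; buried charge introduced by Asp
p.Arg551Trp		ITGA2B	GT-causing	I	FALSE	homozygous (two patients, Southern India)	hbond_loss;steric	FALSE					Nelson et al.	mutation hotspot; loss of multiple structuring H-bonds with added steric encumbrance from Trp
p.Arg551Gln		ITGA2B	GT-causing	I	FALSE	homozygous (six patients, three families)	hbond_loss	FALSE					Haghighi et al.; Vijapurkar et al.	mutation hotspot; loss of multiple structuring H-bonds
p.Ala581Asp		ITGA2B	GT-causing	I	FALSE	heterozygous (second defect unidentified)	buried_charge	FALSE					D'Andrea et al.	hydrophobic thigh beta-barrel residue; buried charge introduced by Asp
p.Asp591Ala	c.1772A>C	ITGA2B	GT-causing	I	TRUE	homozygous	hbond_loss	FALSE	rs778608263	G = 0.000008354 (ExAC)	0.000008354		index case, Belgian type I GT patient	connecting loop of the lower thigh; H-bonds with Arg551, Leu593 and Ser594 lost on Ala substitution; genomic NC_000017.11:g.44379795T>G
p.Ile596Thr		ITGA2B	GT-causing	I	FALSE	homozygous (2) or compound heterozygous with IVS29(+2)T>C, c.3091delC or Glu355Lys		FALSE					French & Coller; Jallu et al.; Ruan et al.; Sandrock et al.	likely mutational hotspot; Thr hydroxyl 3.4 A from Arg551 competes for H-bonds with Asp542, Ser594 and Asp591, adding an H-bond within the connecting loops
p.Gln626His	c.1878G>C	ITGA2B	GT-causing	I	FALSE	homozygous (four independent European studies)	splicing_mRNA_decay	FALSE					Jallu et al.; Nurden et al.; Pillitteri et al.; Sandrock et al.	primary mechanism is exon skipping with mRNA decay, not the His substitution itself; recombinant alphaIIb-His626-beta3 expresses normally; Gln626-Asn722 H-bond clasp
p.Thr646Ala		ITGA2B	GT-causing	I	FALSE	homozygous		FALSE					Tokgoz et al.	calf-1; side chain points to the exterior, structural effect of the smaller Ala difficult to predict
p.Thr650Met		ITGA2B	HPA	n/a	FALSE	polymorphism		FALSE				HPA-20b	Peterson et al.	low-frequency platelet alloantigen in calf-1; post-transfusion immune response without loss of function
p.Leu684Arg		ITGA2B	GT-causing	I	FALSE	heterozygous (second allele unidentified)	steric;buried_charge	FALSE					Pillitteri et al.	hydrophobic core of the calf-1 beta-barrel; larger polar Arg introduces steric encumbrance, highly destabilizing
p.Cys705Arg		ITGA2B	GT-causing	II	FALSE	compound heterozygous or homozygous (several European families; probable founder)	disulfide_loss	FALSE					Gonzalez-Manchon et al.; D'Andrea et al.; Mitchell et al.; Jallu et al.; Nurden et al.	loss of the Cys705-Cys718 disulfide bridge destabilizes the calf-1 beta-barrel, exposing the hydrophobic core; pro-alphaIIb-beta3 still forms in CHO cells
p.Cys705Leu		ITGA2B	GT-causing	I	FALSE	heterozygous (second allele not found)	disulfide_loss	FALSE					Santoro et al.	loss of the Cys705-Cys718 disulfide bridge; patient with <5% alphaIIb-beta3
p.Leu752Val		ITGA2B	GT-causing	I	FALSE	homozygous, co-expressed with Arg755Pro (rare haplotype)		TRUE					D'Andrea et al.	only weakly conserved; independent pathogenicity unresolved
p.Arg755Pro		ITGA2B	GT-causing	I	FALSE	homozygous		FALSE					D'Andrea et al.; Vijapurkar et al.	upper end of a calf-1 beta-strand, side chain toward the exterior; short-range effect limited, long-range effects suggested by molecular dynamics
p.Arg755Gln		ITGA2B	GT-causing	I	FALSE	heterozygous, with two potentially disease-causing ITGB3 variants		FALSE					Nurden et al., cases 35a/b	role in the GT phenotype difficult to assign given the ITGB3 background
p.Cys633Ser		ITGA2B	database-only	n/a	FALSE	single allele, control population	disulfide_loss	FALSE	rs1126555	no frequency data			Ensembl	genu Ca2+ loop; disrupts the Cys633-Cys639 disulfide bridge; backbone-carbonyl Ca2+ ligation retained
p.Asp636Asn		ITGA2B	database-only	n/a	FALSE	single allele, control population		FALSE	rs749873100	MAF 0.00004	0.00004		Ensembl	genu Ca2+ loop; side-chain carboxylate ligand exchanged for amide
p.Glu673Lys		ITGA2B	database-only	n/a	FALSE	single allele, control population	metal_disruption;steric	FALSE	rs368974006	MAF 0.00002/8			Ensembl	calf-1 Ca2+ ligand; Lys removes the carboxylate ligand and pushes the Ca2+ away by steric encumbrance; printed MAF ambiguous, stored verbatim
p.Pro772Arg		ITGA2B	excluded	n/a	FALSE	not assessed		FALSE					literature	at the calf-1/calf-2 interface (erroneously placed in calf-2 in the original report); outside the aa471-769 scan window and not considered further
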