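gm <- make_gene_model()
b3 <- gene_model("ITGB3", signal_peptide_length = 26L)

test_that("variant strings parse in cDNA, three-letter and one-letter forms", {
  v <- parse_variant("c.1772A>C")
  expect_identical(v$cdna_position, 1772L)
  expect_identical(v$ref_nt, "A")
  expect_identical(v$alt_nt, "C")
  expect_identical(v$protein_position_hgvs, 591L)

  p <- parse_variant("p.Asp591Ala")
  expect_identical(p$protein_position_hgvs, 591L)
  expect_identical(p$ref_aa, "D")
  expect_identical(p$alt_aa, "A")

  short <- parse_variant("p.Q626H")
  long <- parse_variant("p.Gln626His")
  expect_identical(short[c("protein_position_hgvs", "ref_aa", "alt_aa")],
                   long[c("protein_position_hgvs", "ref_aa", "alt_aa")])

  expect_error(parse_variant("p.Asp591del"), "cannot parse variant")
  expect_error(parse_variant("g.44379795T>G"), "cannot parse")
})

test_that("cDNA positions map to codons by thirds", {
  expect_identical(codon_of(1772), 591L)
  expect_identical(codon_of(1878), 626L)
  expect_identical(codon_of(c(1, 3, 4)), c(1L, 1L, 2L))
  expect_error(codon_of(0), "positive")
  expect_error(codon_of(-3), "positive")
})

test_that("codon_of round-trips every in-codon offset", {
  for (codon in c(1L, 2L, 591L, 626L, 800L)) {
    for (offset in 1:3) {
      expect_identical(codon_of(3L * (codon - 1L) + offset), codon)
    }
  }
})

test_that("mature numbering subtracts the signal peptide", {
  expect_identical(mature_position(gm, 591L), 560L)   # D560A
  expect_identical(mature_position(b3, 145L), 119L)   # D119
  expect_identical(mature_position(gm, 32L), 1L)
  expect_error(mature_position(gm, 31L), "signal peptide")
  # inverse on the valid range
  for (p in c(32L, 100L, 591L, 769L))
    expect_identical(hgvs_position(gm, mature_position(gm, p)), p)
})

test_that("protein consequences are predicted from the synthetic CDS", {
  v <- predict_protein_change(gm, "c.1772A>C")
  expect_identical(v$ref_aa, "D")
  expect_identical(v$alt_aa, "A")
  expect_identical(v$protein_position_hgvs, 591L)
  expect_identical(v$mature_position, 560L)

  v2 <- predict_protein_change(gm, "c.1878G>C")
  expect_identical(v2$ref_aa, "Q")
  expect_identical(v2$alt_aa, "H")
  expect_identical(v2$protein_position_hgvs, 626L)

  # synonymous / no-change: same alt as ref
  syn <- predict_protein_change(gm, parse_variant("c.1772A>A"))
  expect_identical(syn$ref_aa, syn$alt_aa)

  # reference mismatch is a consistency error
  expect_error(predict_protein_change(gm, "c.1772G>C"), "reference mismatch")
})

test_that("predicted changes agree with independent whole-CDS translation", {
  translate_all <- function(cds) {
    strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds))), "")[[1]]
  }
  for (txt in c("c.1772A>C", "c.1878G>C", "c.1430C>T", "c.2113T>A")) {
    v0 <- parse_variant(txt)
    cds_mut <- gm$cds
    substr(cds_mut, v0$cdna_position, v0$cdna_position) <- v0$alt_nt
    ref_prot <- translate_all(gm$cds)
    alt_prot <- translate_all(cds_mut)
    pos <- codon_of(v0$cdna_position)
    if (ref_prot[pos] == alt_prot[pos]) {
      v <- predict_protein_change(gm, v0)
      expect_identical(v$ref_aa, v$alt_aa)
    } else {
      v <- predict_protein_change(gm, v0)
      expect_identical(v$ref_aa, ref_prot[pos])
      expect_identical(v$alt_aa, alt_prot[pos])
    }
  }
})

test_that("nucleotide changes classify as transition or transversion", {
  expect_identical(classify_nt_change("A", "C"), "transversion")
  expect_identical(classify_nt_change("G", "C"), "transversion")
  expect_identical(classify_nt_change("G", "A"), "transition")
  expect_identical(classify_nt_change("C", "T"), "transition")
  expect_error(classify_nt_change("A", "A"), "identical")
  expect_error(classify_nt_change("A", "U"), "nucleotides")
})

test_that("gene model invariants are enforced", {
  expect_error(gene_model("X", "ATGAA", 0), "multiple of 3")
  expect_error(gene_model("X", "TTGAAA", 0), "start with ATG")
  expect_error(gene_model("X", signal_peptide_length = -1), "non-negative")
})
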