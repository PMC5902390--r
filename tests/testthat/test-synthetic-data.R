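# The generators are the test-bed for everything downstream, so their own
# ground truth is verified here by the independent fixed-column oracle
# parser (helper-oracle.R), never through the package's reader.

test_that("generators are byte-deterministic", {
  expect_identical(make_hbond_fixture(2.8, 160), make_hbond_fixture(2.8, 160))
  expect_identical(make_disulfide_fixture(2.05), make_disulfide_fixture(2.05))
  expect_identical(make_metal_site_fixture(4, 2.4),
                   make_metal_site_fixture(4, 2.4))
  expect_identical(make_clash_pocket_fixture(), make_clash_pocket_fixture())
  expect_identical(make_msa(8, c(0.5, 0.9), seed = 3),
                   make_msa(8, c(0.5, 0.9), seed = 3))
  expect_identical(make_gene_model()$cds, make_gene_model()$cds)
  # different seeds change the msa
  expect_false(identical(make_msa(8, c(0.5, 0.9), seed = 3),
                         make_msa(8, c(0.5, 0.9), seed = 4)))
})

test_that("hbond fixture places the donor-acceptor pair at the requested geometry", {
  for (d in c(2.2, 2.8, 3.4, 5.5)) {
    at <- oracle_atoms(make_hbond_fixture(d, 160))
    nh1 <- at[at$name == "NH1", ]
    od1 <- at[at$name == "OD1", ]
    cz <- at[at$name == "CZ", ]
    expect_lt(abs(oracle_dist(nh1, od1) - d), 1e-3)
    expect_lt(abs(oracle_angle(cz, nh1, od1) - 160), 0.5)
  }
  # requested angle is honoured too
  at <- oracle_atoms(make_hbond_fixture(2.8, 120))
  expect_lt(abs(oracle_angle(at[at$name == "CZ", ], at[at$name == "NH1", ],
                             at[at$name == "OD1", ]) - 120), 0.5)
  expect_error(make_hbond_fixture(1.5, 160), "\\[2.0, 6.0\\]")
  expect_error(make_hbond_fixture(6.5, 160), "\\[2.0, 6.0\\]")
})

test_that("scaffold residues stay clear of the engineered feature", {
  for (txt in list(make_hbond_fixture(2.8, 160), make_disulfide_fixture(2.05),
                   make_metal_site_fixture(4, 2.4),
                   make_clash_pocket_fixture())) {
    at <- oracle_atoms(txt)
    scaffold <- at[at$resno >= 700 & at$resid == "GLY", ]
    feature <- at[at$resno < 700 | at$record == "HETATM", ]
    if (!nrow(scaffold)) next
    dmin <- min(sapply(seq_len(nrow(scaffold)), function(i)
      min(sapply(seq_len(nrow(feature)), function(j)
        oracle_dist(scaffold[i, ], feature[j, ])))))
    expect_gte(dmin, 8)
  }
})

test_that("disulfide fixture honours the requested SG-SG separation", {
  for (d in c(2.05, 4.0)) {
    at <- oracle_atoms(make_disulfide_fixture(d))
    sg <- at[at$name == "SG", ]
    expect_identical(nrow(sg), 2L)
    expect_lt(abs(oracle_dist(sg[1, ], sg[2, ]) - d), 1e-3)
  }
  expect_error(make_disulfide_fixture(0), "positive")
  expect_error(make_disulfide_fixture(-1), "positive")
})

test_that("disulfide fixture round-trips through the PDB writer and reader", {
  txt <- make_disulfide_fixture(2.05)
  s <- read_pdb(txt)
  txt2 <- write_pdb(s)
  at1 <- oracle_atoms(txt)
  at2 <- oracle_atoms(txt2)
  expect_identical(nrow(at1), nrow(at2))
  m1 <- at1[order(at1$resno, at1$name), c("x", "y", "z")]
  m2 <- at2[order(at2$resno, at2$name), c("x", "y", "z")]
  expect_true(max(abs(as.matrix(m1) - as.matrix(m2))) <= 1e-3)
  sg <- at2[at2$name == "SG", ]
  expect_lt(abs(oracle_dist(sg[1, ], sg[2, ]) - 2.05), 1e-3)
})

test_that("metal fixture builds the requested coordination shell", {
  at <- oracle_atoms(make_metal_site_fixture(4, 2.4))
  ion <- at[at$record == "HETATM", ]
  expect_identical(nrow(ion), 1L)
  expect_identical(oracle_shell_size(at, cutoff = 3.0), 4L)
  # ligand distances exact
  ox <- at[at$record == "ATOM" & at$element == "O", ]
  d <- sapply(seq_len(nrow(ox)), function(i) oracle_dist(ox[i, ], ion))
  expect_identical(sum(abs(d - 2.4) < 1e-3), 4L)

  # ligands beyond the cutoff leave an empty shell
  at2 <- oracle_atoms(make_metal_site_fixture(4, 3.5))
  expect_identical(oracle_shell_size(at2, cutoff = 3.0), 0L)

  # no ligands at all
  at3 <- oracle_atoms(make_metal_site_fixture(0))
  expect_identical(oracle_shell_size(at3, cutoff = 3.0), 0L)
})

test_that("clash pocket is clash-free natively and bumps on Ala->Trp", {
  txt <- make_clash_pocket_fixture()
  at <- oracle_atoms(txt)
  expect_identical(oracle_clash_count(at, focus_resno = 600), 0L)
  s <- read_pdb(txt)
  trp <- substitute_residue(s, "A", 600, "Trp")
  at_trp <- oracle_atoms(write_pdb(trp))
  expect_gte(oracle_clash_count(at_trp, focus_resno = 600), 1L)
  gly <- substitute_residue(s, "A", 600, "Gly")
  at_gly <- oracle_atoms(write_pdb(gly))
  expect_identical(oracle_clash_count(at_gly, focus_resno = 600), 0L)
})

test_that("msa columns realise the requested conservation", {
  # fully conserved and single-sequence panels are exactly identical
  m <- as_alignment_matrix(make_msa(12, c(1, 1, 1), seed = 5))
  for (j in 1:3) expect_equal(column_identity(m, j), 1.0)
  m1 <- as_alignment_matrix(make_msa(1, c(0.2, 0.9), seed = 5))
  for (j in 1:2) expect_equal(column_identity(m1, j), 1.0)
  # a 0.5 column over many sequences stays within binomial tolerance
  n <- 200
  m2 <- as_alignment_matrix(make_msa(n, 0.5, seed = 8))
  f <- column_identity(m2, 1)
  # matches among the n-1 non-reference rows ~ Binomial(n-1, 0.5);
  # 4 standard deviations around the mean (plus the reference row)
  p_hat <- (f * n - 1) / (n - 1)
  expect_lt(abs(p_hat - 0.5), 4 * sqrt(0.25 / (n - 1)))
})

test_that("the synthetic gene model reproduces the published codon identities", {
  gm <- make_gene_model()
  codon <- function(i) substr(gm$cds, 3 * (i - 1) + 1, 3 * i)
  expect_identical(codon(591), "GAC")   # Asp
  expect_identical(codon(626), "CAG")   # Gln
  expect_identical(Biostrings::GENETIC_CODE[[codon(591)]], "D")
  expect_identical(Biostrings::GENETIC_CODE[[codon(626)]], "Q")
  expect_identical(nchar(gm$cds) %% 3L, 0L)
  expect_identical(substr(gm$cds, 1, 3), "ATG")
  expect_identical(gm$signal_peptide_length, 31L)
})
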