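# Structural core: each detector is checked against the brute-force
# pairwise oracle on fixtures whose ground truth is known by construction.

hb_fix <- read_pdb(make_hbond_fixture(2.8, 160))
ss_fix <- read_pdb(make_disulfide_fixture(2.05))
pocket <- read_pdb(make_clash_pocket_fixture())
metal <- read_pdb(make_metal_site_fixture(4, 2.4, with_disulfide_partner = TRUE))

test_that("hydrogen-bond detection agrees with the brute-force oracle on all fixtures", {
  fixtures <- list(
    make_hbond_fixture(2.8, 160), make_hbond_fixture(3.4, 150),
    make_hbond_fixture(5.5, 160), make_disulfide_fixture(2.05),
    make_clash_pocket_fixture(), make_metal_site_fixture(4, 2.4))
  keys_of <- function(h) {
    if (!nrow(h)) return(character(0))
    sort(paste(h$donor_chain, h$donor_resno, h$donor_atom, "->",
               h$acceptor_chain, h$acceptor_resno, h$acceptor_atom))
  }
  for (txt in fixtures) {
    h <- detect_hbonds(read_pdb(txt))
    h <- h[h$tier == "firm", , drop = FALSE]
    expect_identical(keys_of(h), oracle_hbond_keys(oracle_atoms(txt)))
  }
})

test_that("the engineered salt bridge is detected at 2.8 A and absent at 5.5 A", {
  h <- detect_hbonds(hb_fix)
  expect_identical(nrow(h), 1L)
  expect_identical(h$donor_atom, "NH1")
  expect_identical(h$acceptor_atom, "OD1")
  expect_identical(h$tier, "firm")
  expect_equal(h$distance, 2.8, tolerance = 1e-3)
  expect_identical(nrow(detect_hbonds(read_pdb(make_hbond_fixture(5.5, 160)))),
                   0L)
  # the 3.5-4.0 band is reported as a potential (not firm) bond
  h2 <- detect_hbonds(read_pdb(make_hbond_fixture(3.8, 160)))
  expect_identical(h2$tier, "potential")
})

test_that("substitution rebuilds the full target topology and nothing else", {
  s2 <- substitute_residue(pocket, "A", 600, "Trp")
  trp <- residue_atoms(s2, "A", 600)
  expect_setequal(trp$elety,
                  c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1",
                    "CE2", "CE3", "CZ2", "CZ3", "CH2"))
  # backbone bit-identical
  before <- residue_atoms(pocket, "A", 600)
  for (nm in c("N", "CA", "C", "O")) {
    expect_identical(unlist(trp[trp$elety == nm, c("x", "y", "z")]),
                     unlist(before[before$elety == nm, c("x", "y", "z")]))
  }
  # atoms outside the focus residue never move
  norm_rest <- function(s) {
    r <- s[s$resno != 600, c("resno", "elety", "x", "y", "z")]
    r <- r[order(r$resno, r$elety), ]
    rownames(r) <- NULL
    class(r) <- "data.frame"
    r
  }
  expect_identical(norm_rest(pocket), norm_rest(s2))

  # Asp -> Ala leaves exactly the alanine topology
  ala <- residue_atoms(substitute_residue(hb_fix, "A", 591, "Ala"), "A", 591)
  expect_setequal(ala$elety, c("N", "CA", "C", "O", "CB"))
  # Gly removes the side chain entirely
  gly <- residue_atoms(substitute_residue(hb_fix, "A", 591, "Gly"), "A", 591)
  expect_setequal(gly$elety, c("N", "CA", "C", "O"))
  expect_identical(gly$resid, rep("GLY", 4L))
})

test_that("identity substitution rebuilds an idealised side chain on an unchanged backbone", {
  s2 <- substitute_residue(hb_fix, "A", 591, "Asp")
  asp_b <- residue_atoms(hb_fix, "A", 591)
  asp_a <- residue_atoms(s2, "A", 591)
  expect_setequal(asp_a$elety, asp_b$elety)
  for (nm in c("N", "CA", "C", "O"))
    expect_identical(unlist(asp_a[asp_a$elety == nm, c("x", "y", "z")]),
                     unlist(asp_b[asp_b$elety == nm, c("x", "y", "z")]))
})

test_that("substitution on a missing residue or broken backbone errors", {
  expect_error(substitute_residue(hb_fix, "A", 999, "Ala"), "no residue")
  broken <- hb_fix[!(hb_fix$resno == 591 & hb_fix$elety == "CA"), ]
  class(broken) <- class(hb_fix)
  expect_error(substitute_residue(broken, "A", 591, "Ala"),
               "missing backbone")
})

test_that("H-bond differencing isolates losses and gains around the focus residue", {
  before <- detect_hbonds(hb_fix)
  # identity substitution: empty diff
  same <- substitute_residue(hb_fix, "A", 591, "Asp")
  d0 <- diff_hbonds(before, detect_hbonds(same), 591)
  expect_identical(nrow(d0$lost), 0L)
  expect_identical(nrow(d0$gained), 0L)
  # Asp -> Ala: the engineered bond is lost, nothing gained
  ala <- substitute_residue(hb_fix, "A", 591, "Ala")
  d1 <- diff_hbonds(before, detect_hbonds(ala), 591)
  expect_identical(nrow(d1$lost), 1L)
  expect_identical(d1$lost$acceptor_atom, "OD1")
  expect_identical(nrow(d1$gained), 0L)
})

test_that("clash inventories match the oracle and are monotone in the threshold", {
  trp <- substitute_residue(pocket, "A", 600, "Trp")
  for (thr in c(0.2, 0.4, 0.6)) {
    cl <- detect_clashes(trp, focus_resno = 600, overlap_threshold = thr)
    expect_identical(nrow(cl),
                     oracle_clash_count(oracle_atoms(write_pdb(trp)),
                                        threshold = thr, focus_resno = 600))
  }
  counts <- sapply(c(0, 0.2, 0.4, 0.8, 1.5),
                   function(thr) nrow(detect_clashes(trp, focus_resno = 600,
                                                     overlap_threshold = thr)))
  expect_true(all(diff(counts) <= 0))
  # threshold -> infinity gives the empty set for any structure
  expect_identical(nrow(detect_clashes(trp, overlap_threshold = Inf)), 0L)
  expect_identical(nrow(detect_clashes(metal, overlap_threshold = Inf)), 0L)
})

test_that("disulfide detection matches the oracle and dies with either cysteine", {
  expect_identical(nrow(detect_disulfides(ss_fix)), 1L)
  expect_identical(nrow(detect_disulfides(ss_fix)),
                   oracle_disulfide_count(oracle_atoms(write_pdb(ss_fix))))
  far <- read_pdb(make_disulfide_fixture(4.0))
  expect_identical(nrow(detect_disulfides(far)), 0L)
  for (res in c(633, 639)) {
    gone <- substitute_residue(ss_fix, "A", res, "Ser")
    expect_identical(nrow(detect_disulfides(gone)), 0L)
  }
})

test_that("metal coordination shells match construction and the oracle", {
  shell <- metal_coordination(metal)
  expect_identical(nrow(shell$ligands), 4L)
  expect_setequal(shell$residues, c(633L, 636L, 638L, 673L))
  lt <- setNames(shell$ligands$ligand_type, shell$ligands$resno)
  expect_identical(lt[["633"]], "backbone_carbonyl")
  expect_identical(lt[["638"]], "backbone_carbonyl")
  expect_identical(lt[["636"]], "side_chain")
  expect_identical(lt[["673"]], "side_chain")
  expect_identical(nrow(shell$ligands),
                   as.integer(oracle_shell_size(oracle_atoms(write_pdb(metal)))))
  # zero cutoff: empty shell
  expect_identical(nrow(metal_coordination(metal, cutoff = 0)$ligands), 0L)
})

test_that("coordination disruption flags follow atom-level chemistry", {
  # Glu -> Lys: the carboxylate side-chain ligand disappears
  glu <- coordination_disruption(metal, "A", 673, "Lys")
  expect_true(glu$side_chain_ligand_removed)
  expect_false(glu$disulfide_lost)
  # Cys -> Ser at a backbone-carbonyl ligand: carbonyl ligation survives,
  # but the Cys633-Cys639 bridge is lost
  cys <- coordination_disruption(metal, "A", 633, "Ser")
  expect_false(cys$side_chain_ligand_removed)
  expect_true(cys$disulfide_lost)
  # substitution far from the site: all flags false
  null <- coordination_disruption(metal, "A", 900, "Ala")
  expect_false(null$side_chain_ligand_removed)
  expect_false(null$disulfide_lost)
  expect_false(null$ion_clash)
})

test_that("minimum distances reproduce engineered separations", {
  expect_equal(min_distance(hb_fix, "A", 551, "A", 591), 2.8,
               tolerance = 1e-3)
  expect_equal(min_distance(hb_fix, "A", 551, "A", 591,
                            atoms_a = "NH1", atoms_b = "OD1"), 2.8,
               tolerance = 1e-3)
  expect_identical(min_distance(hb_fix, "A", 551, "A", 551), 0)
  expect_error(min_distance(hb_fix, "A", 551, "A", 999), "no atoms")
})

test_that("side-chain orientation classifies toward/away and is null for glycine", {
  # Asp591 was placed with its side chain pointing back toward Arg551
  expect_identical(side_chain_orientation(hb_fix, "A", 591,
                                          core_residues = 551), "core")
  # in the metal fixture, Asp636's carboxylate aims at the site centre...
  expect_identical(side_chain_orientation(metal, "A", 636,
                                          core_residues = c(633, 638, 673)),
                   "core")
  # ...and therefore away from the far-corner scaffold residue
  expect_identical(side_chain_orientation(metal, "A", 636,
                                          core_residues = 900), "exterior")
  o <- side_chain_orientation(hb_fix, "A", 700, core_residues = 551)
  expect_true(is.na(o))
  expect_match(attr(o, "reason"), "glycine")
})

test_that("interaction inventories are invariant under rigid-body transforms", {
  for (seed in 1:3) {
    moved <- rigid_transform_structure(hb_fix, seed)
    h0 <- detect_hbonds(hb_fix)
    h1 <- detect_hbonds(moved)
    expect_identical(h1[, c("donor_resno", "donor_atom", "acceptor_resno",
                            "acceptor_atom", "tier")],
                     h0[, c("donor_resno", "donor_atom", "acceptor_resno",
                            "acceptor_atom", "tier")])
    expect_equal(h1$distance, h0$distance, tolerance = 1e-9)

    trp <- substitute_residue(pocket, "A", 600, "Trp")
    moved_trp <- rigid_transform_structure(trp, seed)
    expect_identical(nrow(detect_clashes(moved_trp, focus_resno = 600)),
                     nrow(detect_clashes(trp, focus_resno = 600)))

    moved_ss <- rigid_transform_structure(ss_fix, seed)
    expect_identical(nrow(detect_disulfides(moved_ss)), 1L)

    moved_metal <- rigid_transform_structure(metal, seed)
    expect_identical(nrow(metal_coordination(moved_metal)$ligands), 4L)
  }
})
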