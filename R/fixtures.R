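# Deterministic synthetic fixtures: small PDB structures with known
# ground-truth interactions, controlled-conservation alignments, and a
# synthetic coding sequence reproducing the alphaIIb cDNA->protein
# correspondences. Everything downstream is testable against these without
# any download.
#
# Engineered atom pairs are axis-aligned and snapped to the PDB 0.001-A
# coordinate grid before writing, so requested distances survive the
# fixed-width format exactly.

GRID_ORIGIN <- c(10, 10, 10)

# assemble a residue's coordinate list into structure3d rows
residue_rows <- function(coords, resid, chain, resno) {
  do.call(rbind, lapply(names(coords), function(nm) {
    data.frame(record = "ATOM", eleno = 0L, elety = nm, resid = resid,
               chain = chain, resno = as.integer(resno),
               x = coords[[nm]][1], y = coords[[nm]][2], z = coords[[nm]][3],
               o = 1, b = 0, elesy = substr(nm, 1, 1),
               stringsAsFactors = FALSE)
  }))
}

coords_to_matrix <- function(coords) do.call(rbind, coords)
matrix_to_coords <- function(m, names) {
  stats::setNames(lapply(seq_len(nrow(m)), function(i) m[i, ]), names)
}

# Rigid-place a residue: anchor atom to `target`, with `direction_local`
# (a vector in the residue's local frame) aligned onto `direction_world`,
# then spun by `spin` degrees about that axis.
place_residue <- function(coords, anchor, target, direction_local,
                          direction_world, spin = 0) {
  m <- coords_to_matrix(coords)
  a <- coords[[anchor]]
  R <- rotation_between(direction_local, direction_world)
  if (spin != 0) R <- rotation_about_axis(direction_world, spin) %*% R
  m2 <- sweep(m, 2, a) %*% t(R)
  m2 <- sweep(m2, 2, target, `+`)
  matrix_to_coords(m2, names(coords))
}

# choose the spin (deterministically, 0..350 by 10) that maximises the
# closest approach between the placed residue's non-anchor atoms and a set
# of reference points
best_spin <- function(coords, anchor, target, direction_local,
                      direction_world, ref_points) {
  spins <- seq(0, 350, by = 10)
  score <- vapply(spins, function(s) {
    placed <- place_residue(coords, anchor, target, direction_local,
                            direction_world, spin = s)
    m <- coords_to_matrix(placed[setdiff(names(placed), anchor)])
    min(apply(ref_points, 1, function(p)
      min(sqrt(rowSums(sweep(m, 2, p)^2)))))
  }, numeric(1))
  spins[which.max(score)]
}

finish_fixture <- function(rows_list) {
  at <- do.call(rbind, rows_list)
  at$x <- round(at$x, 3); at$y <- round(at$y, 3); at$z <- round(at$z, 3)
  at$eleno <- seq_len(nrow(at))
  write_pdb(new_structure3d(at))
}

scaffold_residue <- function(offset, chain = "A", resno = 700L) {
  g <- build_residue_local("G")
  g <- matrix_to_coords(sweep(coords_to_matrix(g), 2, offset, `+`), names(g))
  residue_rows(g, "GLY", chain, resno)
}

#' Hydrogen-bond fixture
#'
#' Two residues in Asp/Arg salt-bridge geometry: the Arg NH1 donor and Asp
#' OD1 acceptor lie exactly at the requested heavy-atom distance, with the
#' requested antecedent-donor-acceptor angle at the donor, plus an inert
#' glycine scaffold placed more than 8 Angstrom away. The engineered pair
#' is axis-aligned so the distance is exact in the written file.
#'
#' @param donor_acceptor_distance NH1...OD1 distance, Angstrom (2.0-6.0).
#' @param angle CZ-NH1...OD1 angle at the donor, degrees.
#' @param resnos residue numbers for the Arg donor and Asp acceptor
#'   (defaults 551 and 591, the alphaIIb thigh pair).
#' @return PDB text.
#' @examples
#' s <- read_pdb(make_hbond_fixture(2.8, 160))
#' @export
make_hbond_fixture <- function(donor_acceptor_distance, angle = 160,
                               resnos = c(551L, 591L)) {
  d <- donor_acceptor_distance
  if (!is.numeric(d) || length(d) != 1L || d < 2.0 || d > 6.0)
    stop("donor_acceptor_distance must lie in [2.0, 6.0] Angstrom",
         call. = FALSE)
  arg <- build_residue_local("R")
  h <- arg$NH1; z <- arg$CZ
  u_zh <- unitv(h - z)
  # tilt out of the guanidinium plane, away from NE/NH2
  w <- unitv(pracma_cross(arg$NE - arg$CZ, arg$NH1 - arg$CZ))
  th <- angle * pi / 180
  # angle(z, h, t) = angle: component along (z - h) is cos(angle)
  dir_acc <- -cos(th) * u_zh + sin(th) * w   # direction donor -> acceptor
  # rotate the whole Arg so dir_acc lands on +x, then pin NH1 to the grid
  R <- rotation_between(dir_acc, c(1, 0, 0))
  m <- coords_to_matrix(arg) %*% t(R)
  h_rot <- as.numeric(h %*% t(R))
  m <- sweep(m, 2, GRID_ORIGIN - h_rot, `+`)
  arg <- matrix_to_coords(m, names(arg))
  target <- GRID_ORIGIN + c(round(d, 3), 0, 0)
  asp <- build_residue_local("D")
  dir_local <- asp$CG - asp$OD1   # body extends beyond the acceptor
  ref <- coords_to_matrix(arg)
  spin <- best_spin(asp, "OD1", target, dir_local, c(1, 0, 0), ref)
  asp <- place_residue(asp, "OD1", target, dir_local, c(1, 0, 0), spin)
  asp$OD1 <- target  # exact after grid snap
  finish_fixture(list(
    residue_rows(arg, "ARG", "A", resnos[1]),
    residue_rows(asp, "ASP", "A", resnos[2]),
    scaffold_residue(GRID_ORIGIN + c(0, 20, 0))))
}

#' Disulfide fixture
#'
#' Two cysteines whose SG atoms sit exactly at the requested separation
#' (2.05 Angstrom is a covalent bridge; 4.0 is clearly unbonded), plus a
#' distant glycine scaffold.
#'
#' @param sg_sg_distance SG-SG distance, Angstrom (> 0).
#' @param resnos residue numbers of the two cysteines (defaults 633 and
#'   639, the alphaIIb genu Ca2+-loop bridge).
#' @return PDB text.
#' @export
make_disulfide_fixture <- function(sg_sg_distance = 2.05,
                                   resnos = c(633L, 639L)) {
  d <- sg_sg_distance
  if (!is.numeric(d) || length(d) != 1L || d <= 0)
    stop("sg_sg_distance must be positive", call. = FALSE)
  cys1 <- build_residue_local("C")
  dir1 <- unitv(cys1$SG - cys1$CB)
  R <- rotation_between(dir1, c(1, 0, 0))
  m <- coords_to_matrix(cys1) %*% t(R)
  sg_rot <- as.numeric(cys1$SG %*% t(R))
  m <- sweep(m, 2, GRID_ORIGIN - sg_rot, `+`)
  cys1 <- matrix_to_coords(m, names(cys1))
  target <- GRID_ORIGIN + c(round(d, 3), 0, 0)
  cys2 <- build_residue_local("C")
  dir_local <- cys2$CB - cys2$SG   # body extends beyond its SG
  spin <- best_spin(cys2, "SG", target, dir_local, c(1, 0, 0),
                    coords_to_matrix(cys1))
  cys2 <- place_residue(cys2, "SG", target, dir_local, c(1, 0, 0), spin)
  cys2$SG <- target
  finish_fixture(list(
    residue_rows(cys1, "CYS", "A", resnos[1]),
    residue_rows(cys2, "CYS", "A", resnos[2]),
    scaffold_residue(GRID_ORIGIN + c(0, 20, 0))))
}

# ligand templates for the metal site, cycled in order: the genu Ca2+ shell
# composition (backbone carbonyls of Cys and Val, side-chain carboxylates
# of Asp and Glu)
METAL_LIGAND_TEMPLATES <- list(
  list(aa = "C", resid = "CYS", anchor = "O",   parent = "C",  resno = 633L),
  list(aa = "D", resid = "ASP", anchor = "OD1", parent = "CG", resno = 636L),
  list(aa = "V", resid = "VAL", anchor = "O",   parent = "C",  resno = 638L),
  list(aa = "E", resid = "GLU", anchor = "OE1", parent = "CD", resno = 673L)
)

#' Metal coordination-site fixture
#'
#' A Ca2+ ion with `n_ligands` oxygen ligands placed exactly at
#' `ligand_distance`, emulating the alphaIIb genu Ca2+ loop: ligating
#' residues cycle through backbone-carbonyl Cys, side-chain Asp,
#' backbone-carbonyl Val and side-chain Glu (numbered 633/636/638/673 for
#' the first four). Optionally adds a second cysteine disulfide-bridged to
#' Cys633, mirroring the Cys633-Cys639 bridge.
#'
#' @param n_ligands number of coordinating oxygen atoms (0-6).
#' @param ligand_distance ion-oxygen distance, Angstrom.
#' @param with_disulfide_partner add Cys639 bridged (2.05 A) to Cys633?
#' @return PDB text.
#' @export
make_metal_site_fixture <- function(n_ligands = 4L, ligand_distance = 2.4,
                                    with_disulfide_partner = FALSE) {
  n_ligands <- as.integer(n_ligands)
  if (is.na(n_ligands) || n_ligands < 0L || n_ligands > 6L)
    stop("n_ligands must be between 0 and 6", call. = FALSE)
  if (n_ligands > 0L &&
      (!is.numeric(ligand_distance) || ligand_distance <= 0))
    stop("ligand_distance must be positive", call. = FALSE)
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  rows <- list()
  placed <- list()
  for (i in seq_len(n_ligands)) {
    tmpl <- METAL_LIGAND_TEMPLATES[[(i - 1L) %% 4L + 1L]]
    resno <- if (i <= 4L) tmpl$resno else 700L + i
    res <- build_residue_local(tmpl$aa)
    target <- GRID_ORIGIN + round(ligand_distance, 3) * dirs[[i]]
    dir_local <- res[[tmpl$parent]] - res[[tmpl$anchor]]  # body outward
    res <- place_residue(res, tmpl$anchor, target, dir_local, dirs[[i]])
    res[[tmpl$anchor]] <- target
    rows[[length(rows) + 1L]] <- residue_rows(res, tmpl$resid, "A", resno)
    placed[[length(placed) + 1L]] <- list(tmpl = tmpl, coords = res,
                                          resno = resno)
  }
  if (with_disulfide_partner) {
    if (n_ligands < 1L)
      stop("disulfide partner requires the Cys633 ligand", call. = FALSE)
    sg1 <- placed[[1]]$coords$SG
    u <- unitv(sg1 - GRID_ORIGIN)
    target <- sg1 + 2.05 * u
    cys2 <- build_residue_local("C")
    dir_local <- cys2$CB - cys2$SG
    ref <- do.call(rbind, lapply(placed, function(p) coords_to_matrix(p$coords)))
    spin <- best_spin(cys2, "SG", target, dir_local, u, ref)
    cys2 <- place_residue(cys2, "SG", target, dir_local, u, spin)
    rows[[length(rows) + 1L]] <- residue_rows(cys2, "CYS", "A", 639L)
  }
  ion <- data.frame(record = "HETATM", eleno = 0L, elety = "CA",
                    resid = "CA", chain = "A", resno = 801L,
                    x = GRID_ORIGIN[1], y = GRID_ORIGIN[2], z = GRID_ORIGIN[3],
                    o = 1, b = 0, elesy = "CA", stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- scaffold_residue(GRID_ORIGIN + c(14.5, 14.5, 14.5),
                                                resno = 900L)
  rows[[length(rows) + 1L]] <- ion
  finish_fixture(rows)
}

#' Steric-clash pocket fixture
#'
#' A pocket in which the native alanine side chain is clash-free but
#' substitution by tryptophan (built with the maximum-probability rotamer)
#' produces at least one van der Waals overlap: a glycine "wall" is placed
#' against the position the Trp six-membered ring will occupy. Substituting
#' the alanine by glycine removes the side chain entirely and stays
#' clash-free.
#'
#' @param resno residue number of the mutable alanine (default 600).
#' @return PDB text.
#' @export
make_clash_pocket_fixture <- function(resno = 600L) {
  ala <- build_residue_local("A")
  # predicted Trp ring position under substitute_residue
  trp_sc <- build_side_chain("W", ala$N, ala$CA, ala$C, ideal_cb(ala$N, ala$CA, ala$C))
  cz2 <- trp_sc$CZ2
  out_dir <- unitv(cz2 - ala$CB)
  target <- cz2 + 2.5 * out_dir   # wall oxygen: 2.5 A from ring CZ2
  wall <- build_residue_local("G")
  dir_local <- wall$C - wall$O   # backbone extends away from the pocket
  spin <- best_spin(wall, "O", target, dir_local, out_dir,
                    coords_to_matrix(ala))
  wall <- place_residue(wall, "O", target, dir_local, out_dir, spin)
  finish_fixture(list(
    residue_rows(ala, "ALA", "A", resno),
    residue_rows(wall, "GLY", "A", 650L),
    scaffold_residue(c(0, 20, 0))))
}

#' Synthetic multiple sequence alignment with controlled conservation
#'
#' Emulates a species/paralog panel: sequence 1 is the reference; in column
#' j every other sequence matches the reference residue with probability
#' `column_conservation[j]`, otherwise carries a random different residue.
#' Pure function of its arguments and the seed.
#'
#' @param n_sequences number of aligned sequences (>= 1).
#' @param column_conservation numeric vector in `[0, 1]`, one entry per
#'   alignment column.
#' @param seed integer seed (default 0).
#' @return aligned FASTA text (single string).
#' @examples
#' fa <- make_msa(10, c(1, 0.7, 0.3), seed = 1)
#' @export
make_msa <- function(n_sequences, column_conservation, seed = 0) {
  stopifnot(n_sequences >= 1, length(column_conservation) >= 1,
            all(column_conservation >= 0 & column_conservation <= 1))
  aas <- names(AA_THREE)
  with_seed(seed, {
    ncol <- length(column_conservation)
    ref <- sample(aas, ncol, replace = TRUE)
    seqs <- matrix("", nrow = n_sequences, ncol = ncol)
    seqs[1, ] <- ref
    if (n_sequences > 1) {
      for (j in seq_len(ncol)) {
        for (i in 2:n_sequences) {
          seqs[i, j] <- if (stats::runif(1) < column_conservation[j]) ref[j]
                        else sample(setdiff(aas, ref[j]), 1)
        }
      }
    }
    names_out <- c("reference",
                   if (n_sequences > 1) sprintf("panel_%02d", 2:n_sequences))
    paste0(paste0(">", names_out, "\n",
                  apply(seqs, 1, paste, collapse = ""), collapse = "\n"),
           "\n")
  })
}

# codons pinned so the published cDNA->protein correspondences of the
# alphaIIb aa471-769 region reproduce on the synthetic CDS
PINNED_CODONS <- c(
  `477` = "GCC",  # Ala
  `495` = "GAC",  # Asp
  `503` = "AGC",  # Ser
  `507` = "CCT",  # Pro
  `518` = "ATC",  # Ile
  `551` = "CGG",  # Arg
  `581` = "GCT",  # Ala
  `591` = "GAC",  # Asp  (c.1772A>C -> GCC, Ala)
  `596` = "ATC",  # Ile
  `626` = "CAG",  # Gln  (c.1878G>C -> CAC, His)
  `633` = "TGC",  # Cys
  `636` = "GAC",  # Asp
  `638` = "GTG",  # Val
  `646` = "ACC",  # Thr
  `650` = "ACG",  # Thr
  `673` = "GAG",  # Glu
  `684` = "CTG",  # Leu
  `705` = "TGC",  # Cys
  `718` = "TGT",  # Cys
  `722` = "AAC",  # Asn
  `752` = "CTG",  # Leu
  `755` = "CGG",  # Arg
  `759` = "AGT",  # Ser
  `772` = "CCC"   # Pro
)

#' Synthetic alphaIIb gene model
#'
#' A deterministic coding sequence whose codons reproduce the cDNA-protein
#' correspondences of the alphaIIb aa471-769 region: codon 591 is GAC (Asp,
#' so c.1772A>C yields Asp591Ala), codon 626 is CAG (Gln, so c.1878G>C
#' yields Gln626His), and likewise for the other catalog positions. Signal
#' peptide length is 31 residues, the alphaIIb value. Filler codons are
#' drawn without stop codons from a seeded generator.
#'
#' @param n_codons number of coding codons before the stop (default 800).
#' @param seed integer seed for filler codons (default 0).
#' @return a [gene_model()].
#' @examples
#' gm <- make_gene_model()
#' predict_protein_change(gm, "c.1772A>C")
#' @export
make_gene_model <- function(n_codons = 800L, seed = 0) {
  n_codons <- as.integer(n_codons)
  stopifnot(n_codons >= max(as.integer(names(PINNED_CODONS))))
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*" & gc != "M"]
  codons <- with_seed(seed, sample(sense, n_codons, replace = TRUE))
  codons[1] <- "ATG"
  idx <- as.integer(names(PINNED_CODONS))
  codons[idx] <- unname(PINNED_CODONS)
  cds <- paste0(paste(codons, collapse = ""), "TAA")
  gene_model("ITGA2B_synthetic", cds, signal_peptide_length = 31L)
}
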