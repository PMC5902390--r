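# Metal coordination-shell analysis (the genu Ca2+ loop).
#
# Ca2+ in proteins is coordinated almost exclusively by oxygen: backbone
# carbonyls, Asp/Glu carboxylates, Asn/Gln amide oxygens, Ser/Thr
# hydroxyls. The ligand element set therefore defaults to oxygen only.

#' Find metal ions in a structure
#'
#' @param structure a `structure3d`.
#' @param elements metal element symbols to look for.
#' @return data.frame of HETATM ion rows.
#' @export
find_metal_ions <- function(structure, elements = c("CA", "MG", "MN", "ZN")) {
  het <- structure[structure$record == "HETATM", , drop = FALSE]
  het[toupper(atom_elements(het)) %in% toupper(elements), , drop = FALSE]
}

#' Coordination shell of a metal ion
#'
#' All ligand atoms within `cutoff` of the ion, with each contribution
#' classified as backbone carbonyl (atom name "O"/"OXT") or side chain.
#'
#' @param structure a `structure3d`.
#' @param ion ion selector: an `eleno`, or a one-row data.frame as returned
#'   by [find_metal_ions()].
#' @param cutoff coordination distance cutoff, Angstrom (default 3.0, the
#'   upper end of the typical Ca-O range).
#' @param ligand_elements elements allowed to coordinate (default `"O"`).
#' @return object of class `coordination_shell`: list with the ion row, a
#'   `ligands` data.frame (atom, residue, distance, ligand_type), and the
#'   contributing residue numbers.
#' @export
metal_coordination <- function(structure, ion = NULL, cutoff = 3.0,
                               ligand_elements = "O") {
  if (is.null(ion)) {
    ions <- find_metal_ions(structure)
    if (nrow(ions) != 1L)
      stop("found ", nrow(ions), " metal ions; pass `ion` explicitly",
           call. = FALSE)
    ion <- ions
  } else if (is.numeric(ion)) {
    ion <- structure[structure$eleno == ion & structure$record == "HETATM", ,
                     drop = FALSE]
    if (nrow(ion) != 1L) stop("ion eleno not found", call. = FALSE)
  }
  ipos <- c(ion$x[1], ion$y[1], ion$z[1])
  at <- structure[structure$record == "ATOM", , drop = FALSE]
  at <- at[atom_elements(at) %in% toupper(ligand_elements), , drop = FALSE]
  if (nrow(at)) {
    d <- sqrt(colSums((t(atom_xyz(at)) - ipos)^2))
    sel <- d <= cutoff
    lig <- at[sel, , drop = FALSE]
    lig$distance <- d[sel]
  } else {
    lig <- at
    lig$distance <- numeric(0)
  }
  lig$ligand_type <- ifelse(lig$elety %in% c("O", "OXT"),
                            "backbone_carbonyl", "side_chain")
  lig <- lig[order(lig$distance), , drop = FALSE]
  rownames(lig) <- NULL
  structure(list(
    ion = ion,
    cutoff = cutoff,
    ligands = lig[, c("chain", "resno", "resid", "elety", "distance",
                      "ligand_type")],
    residues = unique(lig$resno)),
    class = "coordination_shell")
}

#' @export
print.coordination_shell <- function(x, ...) {
  cat(sprintf("<coordination_shell> %s ion, %d ligand atom(s) within %.1f A\n",
              trimws(x$ion$elety[1]), nrow(x$ligands), x$cutoff))
  if (nrow(x$ligands)) print.data.frame(x$ligands, digits = 3)
  invisible(x)
}

#' Effect of a substitution on a metal coordination site
#'
#' Substitutes the residue, recomputes the coordination shell, and reports
#' three flags: whether a side-chain ligand contributed by the residue was
#' removed (backbone-carbonyl ligation survives any missense change),
#' whether a disulfide bridge involving the residue was lost, and whether
#' the new side chain clashes with the ion (steric push on the metal).
#'
#' @param structure a `structure3d`.
#' @param chain,resno residue being substituted.
#' @param new_aa target amino acid.
#' @param ion ion selector as in [metal_coordination()].
#' @param cutoff coordination cutoff, Angstrom.
#' @param overlap_threshold van der Waals overlap defining an ion clash.
#' @param library rotamer library for the substitution.
#' @return list of class `coordination_disruption` with the flags
#'   `side_chain_ligand_removed`, `disulfide_lost`, `ion_clash`, plus the
#'   before/after shells.
#' @export
coordination_disruption <- function(structure, chain, resno, new_aa,
                                    ion = NULL, cutoff = 3.0,
                                    overlap_threshold = 0.4,
                                    library = rotamer_library()) {
  before <- metal_coordination(structure, ion = ion, cutoff = cutoff)
  after_s <- substitute_residue(structure, chain, resno, new_aa,
                                library = library)
  after <- metal_coordination(after_s, ion = before$ion, cutoff = cutoff)
  sc_before <- before$ligands[before$ligands$resno == resno &
                              before$ligands$chain == chain &
                              before$ligands$ligand_type == "side_chain", ]
  sc_after <- after$ligands[after$ligands$resno == resno &
                            after$ligands$chain == chain &
                            after$ligands$ligand_type == "side_chain", ]
  ss_before <- detect_disulfides(structure)
  was_bridged <- nrow(ss_before) > 0 &&
    any((ss_before$resno_a == resno & ss_before$chain_a == chain) |
        (ss_before$resno_b == resno & ss_before$chain_b == chain))
  # ion clash: any NEW side-chain atom overlapping the ion. Backbone atoms
  # and atoms that are themselves coordination ligands are excluded -
  # coordination contacts are shorter than van der Waals sums by nature.
  ipos <- c(before$ion$x[1], before$ion$y[1], before$ion$z[1])
  res_after <- residue_atoms(after_s, chain, resno)
  sc <- res_after[!res_after$elety %in% c("N", "CA", "C", "O", "OXT"), ,
                  drop = FALSE]
  sc <- sc[!sc$elety %in% sc_after$elety, , drop = FALSE]
  ion_clash <- FALSE
  if (nrow(sc)) {
    rads <- vdw_radius(atom_elements(sc))
    r_ion <- vdw_radius(atom_elements(before$ion))
    d_ion <- sqrt(colSums((t(atom_xyz(sc)) - ipos)^2))
    ion_clash <- any(rads + r_ion - d_ion > overlap_threshold)
  }
  structure(list(
    residue = list(chain = chain, resno = resno, new_aa = aa_three(new_aa)),
    side_chain_ligand_removed = nrow(sc_before) > 0 && nrow(sc_after) == 0,
    disulfide_lost = was_bridged && aa_one(new_aa) != "C",
    ion_clash = ion_clash,
    shell_before = before, shell_after = after),
    class = "coordination_disruption")
}

#' @export
print.coordination_disruption <- function(x, ...) {
  cat(sprintf("<coordination_disruption> %s%d%s\n", x$residue$chain,
              x$residue$resno, x$residue$new_aa))
  cat("  side-chain ligand removed:", x$side_chain_ligand_removed, "\n")
  cat("  disulfide lost:          ", x$disulfide_lost, "\n")
  cat("  ion clash:               ", x$ion_clash, "\n")
  invisible(x)
}
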