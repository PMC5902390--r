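# Side-chain orientation relative to a beta-barrel core.
#
# In the thigh and calf-1 beta-sandwich folds, hydrophobic side chains
# point into the barrel core while polar/charged side chains point to the
# exterior; whether a substituted side chain faces the core is part of the
# impact assessment.

#' Classify a side chain as core-facing or exterior-facing
#'
#' Computes the centroid of the user-designated barrel (core) residues and
#' asks whether the CB-to-side-chain-centroid vector points toward it:
#' an angle below 90 degrees classifies the side chain as `"core"`,
#' otherwise `"exterior"`. For residues whose side chain is only CB
#' (alanine), the CA-to-CB vector is used as the direction. Glycine has no
#' side chain and returns `NA` with an explanatory attribute.
#'
#' @param structure a `structure3d`.
#' @param chain,resno residue to classify.
#' @param core_residues residue numbers defining the barrel core (their CA
#'   centroid is the reference point).
#' @param core_chain chain of the core residues (defaults to `chain`).
#' @return `"core"`, `"exterior"`, or `NA` for glycine.
#' @export
side_chain_orientation <- function(structure, chain, resno, core_residues,
                                   core_chain = chain) {
  res <- residue_atoms(structure, chain, resno)
  if (!nrow(res)) stop("residue not found", call. = FALSE)
  if (res$resid[1] == "GLY" || !"CB" %in% res$elety) {
    out <- NA_character_
    attr(out, "reason") <- "glycine has no side chain; orientation undefined"
    return(out)
  }
  core <- structure[structure$record == "ATOM" &
                    structure$chain == core_chain &
                    structure$resno %in% core_residues &
                    structure$elety == "CA", , drop = FALSE]
  if (!nrow(core)) stop("no CA atoms among core residues", call. = FALSE)
  core_centroid <- colMeans(atom_xyz(core))
  cb <- as.numeric(res[res$elety == "CB", c("x", "y", "z")])
  sc <- res[!res$elety %in% c("N", "CA", "C", "O", "OXT", "CB"), , drop = FALSE]
  if (nrow(sc)) {
    dir_vec <- colMeans(atom_xyz(sc)) - cb
  } else {
    ca <- as.numeric(res[res$elety == "CA", c("x", "y", "z")])
    dir_vec <- cb - ca
  }
  ang <- atom_angle(cb + dir_vec, cb, core_centroid)
  if (ang < 90) "core" else "exterior"
}
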