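# In-place residue substitution with the maximum-probability rotamer.

#' Substitute a residue in a structure
#'
#' Replaces the side chain of one residue by the target amino acid's side
#' chain, built from ideal internal coordinates with the maximum-probability
#' chi angles of the rotamer library. Backbone atoms (N, CA, C, O, OXT) are
#' left bit-identical; CB is rebuilt at the ideal position from the
#' backbone frame; glycine gets no side chain. No other residue moves:
#' neighbours are never repacked, matching a single-rotamer modelling
#' session rather than an energy minimisation.
#'
#' @param structure a `structure3d`.
#' @param chain chain identifier.
#' @param resno residue number (author numbering of the input file).
#' @param new_aa target amino acid (one- or three-letter code).
#' @param library rotamer library, see [rotamer_library()].
#' @return the modified `structure3d`.
#' @examples
#' s <- read_pdb(make_hbond_fixture(2.8, 160))
#' s2 <- substitute_residue(s, "A", 591, "Ala")
#' @export
substitute_residue <- function(structure, chain, resno, new_aa,
                               library = rotamer_library()) {
  new_aa <- aa_one(new_aa)
  resno <- as.integer(resno)
  res <- residue_atoms(structure, chain, resno)
  if (!nrow(res))
    stop("no residue ", resno, " in chain '", chain, "'", call. = FALSE)
  bb_names <- c("N", "CA", "C")
  have <- bb_names %in% res$elety
  if (!all(have))
    stop("cannot model substitution at ", resno, ": missing backbone atom(s) ",
         paste(bb_names[!have], collapse = ", "), call. = FALSE)
  getxyz <- function(name) {
    r <- res[res$elety == name, ]
    c(r$x[1], r$y[1], r$z[1])
  }
  n <- getxyz("N"); ca <- getxyz("CA"); c_ <- getxyz("C")
  keep <- res[res$elety %in% c("N", "CA", "C", "O", "OXT"), , drop = FALSE]
  keep$resid <- aa_pdb(new_aa)
  new_rows <- keep
  if (new_aa != "G") {
    cb <- ideal_cb(n, ca, c_)
    sc <- build_side_chain(new_aa, n, ca, c_, cb, library = library)
    sc_df <- do.call(rbind, lapply(names(sc), function(nm) {
      data.frame(record = "ATOM", eleno = 0L, elety = nm,
                 resid = aa_pdb(new_aa), chain = chain, resno = resno,
                 x = sc[[nm]][1], y = sc[[nm]][2], z = sc[[nm]][3],
                 o = 1, b = 0,
                 elesy = substr(nm, 1, 1), stringsAsFactors = FALSE)
    }))
    new_rows <- rbind(keep, sc_df)
  }
  sel <- structure$chain == chain & structure$resno == resno &
    structure$record == "ATOM"
  before <- structure[seq_len(nrow(structure)) < min(which(sel)), , drop = FALSE]
  after <- structure[seq_len(nrow(structure)) > max(which(sel)), , drop = FALSE]
  out <- rbind(before, new_rows, after)
  out$eleno <- seq_len(nrow(out))
  new_structure3d(out)
}
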