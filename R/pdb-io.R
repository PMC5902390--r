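# PDB input/output and the light structure container used by all detectors.
#
# A `structure3d` is a data.frame of heavy-atom records: one row per atom,
# columns record ("ATOM"/"HETATM"), eleno, elety (atom name), resid
# (residue name), chain, resno, x, y, z, o, b, elesy (element symbol).
# Parsing is delegated to bio3d; this wrapper adds the cleanup contracts:
# waters dropped, alternate locations resolved to the highest-occupancy
# conformer, metal HETATMs retained.

STRUCTURE_COLUMNS <- c("record", "eleno", "elety", "resid", "chain", "resno",
                       "x", "y", "z", "o", "b", "elesy")

new_structure3d <- function(atoms) {
  atoms <- atoms[, STRUCTURE_COLUMNS]
  rownames(atoms) <- NULL
  if (anyNA(atoms[, c("x", "y", "z")]) ||
      any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates", call. = FALSE)
  dup <- duplicated(atoms[, c("chain", "resno", "resid", "elety")])
  if (any(dup))
    stop("duplicate atom name within a residue: ",
         paste(atoms$elety[dup][1], atoms$resno[dup][1]), call. = FALSE)
  class(atoms) <- c("structure3d", "data.frame")
  atoms
}

#' @export
print.structure3d <- function(x, ...) {
  res <- unique(x[x$record == "ATOM", c("chain", "resno", "resid")])
  het <- x[x$record == "HETATM", ]
  cat(sprintf("<structure3d> %d atoms, %d residues", nrow(x), nrow(res)))
  if (nrow(het)) cat(sprintf(", %d HETATM (%s)", nrow(het),
                             paste(unique(het$resid), collapse = ",")))
  cat("\n")
  invisible(x)
}

WATER_RESIDS <- c("HOH", "WAT", "DOD", "H2O")

#' Read a PDB structure
#'
#' Parses ATOM/HETATM coordinate records. Waters are dropped by default,
#' metal and other HETATM records are retained, and alternate locations are
#' resolved to the highest-occupancy conformer (ties broken by conformer
#' identifier, 'A' first). Hydrogens, absent from X-ray structures of this
#' resolution class, are dropped so all downstream criteria are
#' heavy-atom-only.
#'
#' @param input path to a PDB file, or PDB text (detected by embedded
#'   newlines).
#' @param keep_waters keep water residues? Default `FALSE`.
#' @return a `structure3d` data.frame of atoms.
#' @export
read_pdb <- function(input, keep_waters = FALSE) {
  stopifnot(is.character(input))
  if (length(input) > 1L || grepl("\n", input)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(unlist(strsplit(paste(input, collapse = "\n"), "\n")), path)
  } else {
    path <- input
  }
  lines <- readLines(path, warn = FALSE)
  coordish <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(coordish))
    stop("no ATOM/HETATM records: empty structure", call. = FALSE)
  for (i in which(coordish)) {
    ln <- lines[i]
    ok <- nchar(ln) >= 54 &&
      !is.na(suppressWarnings(as.numeric(substr(ln, 31, 38)))) &&
      !is.na(suppressWarnings(as.numeric(substr(ln, 39, 46)))) &&
      !is.na(suppressWarnings(as.numeric(substr(ln, 47, 54)))) &&
      !is.na(suppressWarnings(as.integer(substr(ln, 23, 26))))
    if (!ok)
      stop("malformed PDB coordinate record at line ", i, ": ",
           substr(ln, 1, 30), call. = FALSE)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                          rm.alt = FALSE))
  at <- pdb$atom
  at$record <- at$type
  at$elesy <- trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                            substr(at$elety, 1, 1), at$elesy))
  if (!keep_waters) at <- at[!at$resid %in% WATER_RESIDS, ]
  at <- at[at$elesy != "H", ]
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  # resolve altlocs: within (chain, resno, resid, elety) keep max occupancy,
  # ties by alt id (NA/'A' first)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  key <- paste(at$chain, at$resno, at$resid, at$elety, sep = "|")
  ord <- order(key, -at$o, alt)
  at <- at[ord, ]
  at <- at[!duplicated(paste(at$chain, at$resno, at$resid, at$elety,
                             sep = "|")), ]
  at <- at[order(match(at$record, c("ATOM", "HETATM")), at$chain, at$resno,
                 at$eleno), ]
  new_structure3d(at)
}

# Format one PDB coordinate line (fixed columns, element right-justified
# in 77-78). Atom names shorter than 4 characters start in column 14.
format_pdb_line <- function(record, eleno, elety, resid, chain, resno,
                            x, y, z, o = 1, b = 0, elesy = "") {
  name_fmt <- if (nchar(elety) >= 4L) substr(elety, 1, 4)
              else sprintf(" %-3s", elety)
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, eleno, name_fmt, resid, chain, resno, x, y, z, o, b,
          toupper(elesy))
}

#' Write a structure as PDB text
#'
#' Minimal legal coordinate records (ATOM/HETATM/TER/END). Output is
#' byte-deterministic for a given structure.
#'
#' @param structure a `structure3d`.
#' @param file optional path; when `NULL` the text is returned invisibly.
#' @return PDB text as a single string (invisibly when writing to file).
#' @export
write_pdb <- function(structure, file = NULL) {
  stopifnot(inherits(structure, "structure3d"))
  at <- structure
  lines <- character(0)
  atom <- at[at$record == "ATOM", ]
  for (i in seq_len(nrow(atom)))
    lines <- c(lines, format_pdb_line("ATOM", atom$eleno[i], atom$elety[i],
                                      atom$resid[i], atom$chain[i],
                                      atom$resno[i], atom$x[i], atom$y[i],
                                      atom$z[i], atom$o[i], atom$b[i],
                                      atom$elesy[i]))
  if (nrow(atom)) lines <- c(lines, "TER")
  het <- at[at$record == "HETATM", ]
  for (i in seq_len(nrow(het)))
    lines <- c(lines, format_pdb_line("HETATM", het$eleno[i], het$elety[i],
                                      het$resid[i], het$chain[i],
                                      het$resno[i], het$x[i], het$y[i],
                                      het$z[i], het$o[i], het$b[i],
                                      het$elesy[i]))
  lines <- c(lines, "END")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    con <- file(file, "wb")
    writeBin(charToRaw(txt), con)
    close(con)
    return(invisible(txt))
  }
  txt
}

# --- small selection helpers used across detectors ------------------------

residue_atoms <- function(structure, chain, resno) {
  structure[structure$chain == chain & structure$resno == resno &
            structure$record == "ATOM", , drop = FALSE]
}

atom_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

# unique residue table (ATOM records only)
residue_table <- function(structure) {
  unique(structure[structure$record == "ATOM",
                   c("chain", "resno", "resid")])
}

# element of each atom row with fallback from the atom name
atom_elements <- function(atoms) {
  e <- trimws(atoms$elesy)
  e[e == ""] <- substr(atoms$elety[e == ""], 1, 1)
  toupper(e)
}

#' Apply a rigid-body transform to a structure
#'
#' Rotates (about the origin) then translates every atom. Used mainly for
#' invariance testing: interaction inventories must not change under
#' rigid-body motion.
#'
#' @param structure a `structure3d`.
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector.
#' @return transformed `structure3d`.
#' @export
transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  xyz <- transform_xyz(atom_xyz(structure), R, t)
  structure$x <- xyz[, 1]; structure$y <- xyz[, 2]; structure$z <- xyz[, 3]
  structure
}
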