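# Side-chain topology (ideal internal coordinates) and a coarse
# backbone-independent rotamer library.
#
# Each side-chain atom is defined by three reference atoms a-b-c, a bond
# length (Angstrom), a bond angle at c (degrees) and a dihedral a-b-c-new.
# The dihedral is either a fixed value or "chi<k>" plus an offset, so the
# same topology serves every rotamer. Bond lengths/angles follow standard
# ideal protein geometry; rings are built by chained dihedrals, which keeps
# them planar to well under 0.1 Angstrom - ample for distance-based
# interaction inventories (no energetics are computed here).

.sc_atom <- function(name, a, b, c, bond, angle, chi = NA_integer_,
                     offset = 0, fixed = NA_real_) {
  list(name = name, refs = c(a, b, c), bond = bond, angle = angle,
       chi = chi, offset = offset, fixed = fixed)
}

SIDECHAIN_TOPOLOGY <- list(
  A = list(),
  G = list(),
  S = list(.sc_atom("OG",  "N", "CA", "CB", 1.417, 110.8, chi = 1)),
  C = list(.sc_atom("SG",  "N", "CA", "CB", 1.808, 114.4, chi = 1)),
  T = list(.sc_atom("OG1", "N", "CA", "CB", 1.433, 109.5, chi = 1),
           .sc_atom("CG2", "N", "CA", "CB", 1.521, 110.5, chi = 1, offset = -120)),
  V = list(.sc_atom("CG1", "N", "CA", "CB", 1.527, 110.5, chi = 1),
           .sc_atom("CG2", "N", "CA", "CB", 1.527, 110.5, chi = 1, offset = 120)),
  L = list(.sc_atom("CG",  "N", "CA", "CB", 1.530, 116.3, chi = 1),
           .sc_atom("CD1", "CA", "CB", "CG", 1.521, 110.7, chi = 2),
           .sc_atom("CD2", "CA", "CB", "CG", 1.521, 110.7, chi = 2, offset = 120)),
  I = list(.sc_atom("CG1", "N", "CA", "CB", 1.530, 110.4, chi = 1),
           .sc_atom("CG2", "N", "CA", "CB", 1.521, 110.5, chi = 1, offset = -120),
           .sc_atom("CD1", "CA", "CB", "CG1", 1.513, 113.8, chi = 2)),
  M = list(.sc_atom("CG",  "N", "CA", "CB", 1.520, 114.1, chi = 1),
           .sc_atom("SD",  "CA", "CB", "CG", 1.803, 112.7, chi = 2),
           .sc_atom("CE",  "CB", "CG", "SD", 1.791, 100.9, chi = 3)),
  P = list(.sc_atom("CG",  "N", "CA", "CB", 1.492, 104.5, chi = 1),
           .sc_atom("CD",  "CA", "CB", "CG", 1.503, 106.1, chi = 2)),
  F = list(.sc_atom("CG",  "N", "CA", "CB", 1.502, 113.8, chi = 1),
           .sc_atom("CD1", "CA", "CB", "CG", 1.384, 120.8, chi = 2),
           .sc_atom("CD2", "CA", "CB", "CG", 1.384, 120.8, chi = 2, offset = 180),
           .sc_atom("CE1", "CB", "CG", "CD1", 1.382, 120.8, fixed = 180),
           .sc_atom("CE2", "CB", "CG", "CD2", 1.382, 120.8, fixed = 180),
           .sc_atom("CZ",  "CG", "CD1", "CE1", 1.372, 120.3, fixed = 0)),
  Y = list(.sc_atom("CG",  "N", "CA", "CB", 1.502, 113.8, chi = 1),
           .sc_atom("CD1", "CA", "CB", "CG", 1.384, 120.8, chi = 2),
           .sc_atom("CD2", "CA", "CB", "CG", 1.384, 120.8, chi = 2, offset = 180),
           .sc_atom("CE1", "CB", "CG", "CD1", 1.382, 120.8, fixed = 180),
           .sc_atom("CE2", "CB", "CG", "CD2", 1.382, 120.8, fixed = 180),
           .sc_atom("CZ",  "CG", "CD1", "CE1", 1.372, 120.3, fixed = 0),
           .sc_atom("OH",  "CD1", "CE1", "CZ", 1.376, 119.9, fixed = 180)),
  W = list(.sc_atom("CG",  "N", "CA", "CB", 1.498, 113.6, chi = 1),
           .sc_atom("CD1", "CA", "CB", "CG", 1.365, 126.9, chi = 2),
           .sc_atom("CD2", "CA", "CB", "CG", 1.433, 126.6, chi = 2, offset = 180),
           .sc_atom("NE1", "CB", "CG", "CD1", 1.374, 110.2, fixed = 180),
           .sc_atom("CE2", "CB", "CG", "CD2", 1.409, 107.2, fixed = 180),
           .sc_atom("CE3", "CB", "CG", "CD2", 1.398, 133.9, fixed = 0),
           .sc_atom("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, fixed = 180),
           .sc_atom("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, fixed = 180),
           .sc_atom("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, fixed = 0)),
  D = list(.sc_atom("CG",  "N", "CA", "CB", 1.516, 112.6, chi = 1),
           .sc_atom("OD1", "CA", "CB", "CG", 1.249, 118.4, chi = 2),
           .sc_atom("OD2", "CA", "CB", "CG", 1.249, 118.4, chi = 2, offset = 180)),
  N = list(.sc_atom("CG",  "N", "CA", "CB", 1.516, 112.6, chi = 1),
           .sc_atom("OD1", "CA", "CB", "CG", 1.231, 120.8, chi = 2),
           .sc_atom("ND2", "CA", "CB", "CG", 1.328, 116.4, chi = 2, offset = 180)),
  E = list(.sc_atom("CG",  "N", "CA", "CB", 1.520, 114.1, chi = 1),
           .sc_atom("CD",  "CA", "CB", "CG", 1.516, 112.6, chi = 2),
           .sc_atom("OE1", "CB", "CG", "CD", 1.249, 118.4, chi = 3),
           .sc_atom("OE2", "CB", "CG", "CD", 1.249, 118.4, chi = 3, offset = 180)),
  Q = list(.sc_atom("CG",  "N", "CA", "CB", 1.520, 114.1, chi = 1),
           .sc_atom("CD",  "CA", "CB", "CG", 1.516, 112.6, chi = 2),
           .sc_atom("OE1", "CB", "CG", "CD", 1.231, 120.8, chi = 3),
           .sc_atom("NE2", "CB", "CG", "CD", 1.328, 116.4, chi = 3, offset = 180)),
  K = list(.sc_atom("CG",  "N", "CA", "CB", 1.520, 114.1, chi = 1),
           .sc_atom("CD",  "CA", "CB", "CG", 1.520, 111.3, chi = 2),
           .sc_atom("CE",  "CB", "CG", "CD", 1.520, 111.3, chi = 3),
           .sc_atom("NZ",  "CG", "CD", "CE", 1.489, 111.9, chi = 4)),
  R = list(.sc_atom("CG",  "N", "CA", "CB", 1.520, 114.1, chi = 1),
           .sc_atom("CD",  "CA", "CB", "CG", 1.520, 111.3, chi = 2),
           .sc_atom("NE",  "CB", "CG", "CD", 1.461, 112.0, chi = 3),
           .sc_atom("CZ",  "CG", "CD", "NE", 1.329, 124.2, chi = 4),
           .sc_atom("NH1", "CD", "NE", "CZ", 1.326, 120.0, fixed = 0),
           .sc_atom("NH2", "CD", "NE", "CZ", 1.326, 120.0, fixed = 180)),
  H = list(.sc_atom("CG",  "N", "CA", "CB", 1.497, 113.8, chi = 1),
           .sc_atom("ND1", "CA", "CB", "CG", 1.371, 122.7, chi = 2),
           .sc_atom("CD2", "CA", "CB", "CG", 1.356, 131.0, chi = 2, offset = 180),
           .sc_atom("CE1", "CB", "CG", "ND1", 1.319, 109.0, fixed = 180),
           .sc_atom("NE2", "CB", "CG", "CD2", 1.374, 107.2, fixed = 180))
)

# Coarse backbone-independent rotamer library: per residue type, chi-angle
# tuples with probabilities sorted descending. Values are the modal rotamers
# of standard backbone-independent statistics; only the top entry is used by
# default (maximum-probability selection), the rest document the ranking.
DEFAULT_ROTAMER_LIBRARY <- list(
  A = list(list(chi = numeric(0), p = 1.00)),
  G = list(list(chi = numeric(0), p = 1.00)),
  S = list(list(chi = c(64.7), p = 0.48),
           list(chi = c(-69.7), p = 0.33),
           list(chi = c(-176.1), p = 0.19)),
  C = list(list(chi = c(-65.2), p = 0.50),
           list(chi = c(-179.6), p = 0.29),
           list(chi = c(63.5), p = 0.21)),
  T = list(list(chi = c(59.0), p = 0.49),
           list(chi = c(-61.2), p = 0.43),
           list(chi = c(-175.0), p = 0.08)),
  V = list(list(chi = c(175.8), p = 0.73),
           list(chi = c(-60.5), p = 0.20),
           list(chi = c(63.8), p = 0.07)),
  I = list(list(chi = c(-64.9, 168.7), p = 0.60),
           list(chi = c(-57.4, -60.4), p = 0.15)),
  L = list(list(chi = c(-64.9, 176.0), p = 0.59),
           list(chi = c(-176.4, 63.1), p = 0.29)),
  M = list(list(chi = c(-64.5, -68.5, -75.6), p = 0.20),
           list(chi = c(-78.3, 174.7, 72.1), p = 0.18)),
  P = list(list(chi = c(-25.3, 38.5), p = 0.44),
           list(chi = c(28.9, -38.5), p = 0.41)),
  F = list(list(chi = c(-66.3, 94.3), p = 0.44),
           list(chi = c(-179.2, 78.9), p = 0.33)),
  Y = list(list(chi = c(-66.5, 96.6), p = 0.43),
           list(chi = c(-179.7, 77.3), p = 0.34)),
  W = list(list(chi = c(-70.4, 100.5), p = 0.29),
           list(chi = c(-177.3, -95.1), p = 0.26)),
  D = list(list(chi = c(-70.2, -15.2), p = 0.51),
           list(chi = c(-177.0, 5.4), p = 0.30)),
  N = list(list(chi = c(-68.3, -36.8), p = 0.47),
           list(chi = c(-177.1, -3.5), p = 0.27)),
  E = list(list(chi = c(-69.0, -177.2, -11.4), p = 0.34),
           list(chi = c(-176.2, 175.2, -6.9), p = 0.21)),
  Q = list(list(chi = c(-66.7, -178.5, -24.0), p = 0.36),
           list(chi = c(-174.8, 177.8, -1.6), p = 0.20)),
  K = list(list(chi = c(-67.5, -179.6, -179.7, 179.3), p = 0.27),
           list(chi = c(-177.0, 179.1, 179.4, 179.6), p = 0.17)),
  R = list(list(chi = c(-67.0, 180.0, 180.0, 180.0), p = 0.22),
           list(chi = c(-177.5, 177.2, 179.5, 178.8), p = 0.14)),
  H = list(list(chi = c(-63.2, -74.3), p = 0.33),
           list(chi = c(-177.3, 64.8), p = 0.25))
)

#' Default rotamer library
#'
#' A coarse backbone-independent library: for each residue type, chi-angle
#' tuples with probabilities sorted in decreasing order. Side-chain
#' substitution uses the first (maximum-probability) entry.
#'
#' @return named list keyed by one-letter amino-acid code; each element is a
#'   list of `list(chi = <numeric chi angles, degrees>, p = <probability>)`.
#' @export
rotamer_library <- function() DEFAULT_ROTAMER_LIBRARY

#' Load a rotamer library from a TSV file
#'
#' Expected columns: `aa` (one- or three-letter code), `chi1`..`chi4`
#' (degrees, empty where undefined) and `prob`. Entries are sorted by
#' decreasing probability per residue type, so the first row per type is
#' the maximum-probability rotamer.
#'
#' @param path TSV file path.
#' @return library in the [rotamer_library()] format.
#' @export
read_rotamer_library <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("aa", "prob") %in% names(d)))
  chis <- intersect(paste0("chi", 1:4), names(d))
  d$aa <- aa_one(d$aa)
  out <- lapply(split(d, d$aa), function(g) {
    g <- g[order(-g$prob), , drop = FALSE]
    lapply(seq_len(nrow(g)), function(i) {
      chi <- as.numeric(g[i, chis])
      list(chi = chi[!is.na(chi)], p = g$prob[i])
    })
  })
  for (aa in c("A", "G"))
    if (is.null(out[[aa]])) out[[aa]] <- list(list(chi = numeric(0), p = 1))
  out
}

top_rotamer <- function(aa, library = rotamer_library()) {
  aa <- aa_one(aa)
  rots <- library[[aa]]
  if (is.null(rots)) stop("rotamer library has no entry for ", aa, call. = FALSE)
  probs <- vapply(rots, `[[`, numeric(1), "p")
  rots[[which.max(probs)]]$chi
}

# Build side-chain atom coordinates (beyond CB) for residue type `aa` given
# backbone N/CA/C and CB positions. Returns a named list of xyz vectors.
build_side_chain <- function(aa, n, ca, c, cb, chi = NULL,
                             library = rotamer_library()) {
  aa <- aa_one(aa)
  topo <- SIDECHAIN_TOPOLOGY[[aa]]
  if (is.null(topo)) stop("no topology for residue ", aa, call. = FALSE)
  if (is.null(chi)) chi <- top_rotamer(aa, library)
  coords <- list(N = n, CA = ca, C = c, CB = cb)
  for (at in topo) {
    tor <- if (!is.na(at$fixed)) at$fixed else {
      if (at$chi > length(chi))
        stop("rotamer for ", aa, " supplies ", length(chi),
             " chi angles; need chi", at$chi, call. = FALSE)
      chi[at$chi] + at$offset
    }
    refs <- lapply(at$refs, function(r) {
      if (is.null(coords[[r]]))
        stop("reference atom ", r, " not yet placed", call. = FALSE)
      coords[[r]]
    })
    coords[[at$name]] <- place_atom(refs[[1]], refs[[2]], refs[[3]],
                                    at$bond, at$angle, tor)
  }
  coords[setdiff(names(coords), c("N", "CA", "C"))]
}

# Ideal CB from backbone N, CA, C (L-amino-acid chirality).
ideal_cb <- function(n, ca, c) {
  place_atom(c, n, ca, 1.521, 110.4, 122.6)
}

# Heavy-atom names expected for each residue type (backbone + side chain).
residue_atom_names <- function(aa) {
  aa <- aa_one(aa)
  sc <- if (aa == "G") character(0)
        else c("CB", vapply(SIDECHAIN_TOPOLOGY[[aa]], `[[`, character(1), "name"))
  c("N", "CA", "C", "O", sc)
}

# Build a complete free-standing residue in a local frame: N at origin,
# CA on +x, C in the xy-plane. psi sets the O dihedral (trans by default).
build_residue_local <- function(aa, chi = NULL, library = rotamer_library()) {
  aa <- aa_one(aa)
  n <- c(0, 0, 0)
  ca <- c(1.458, 0, 0)
  # place C with angle N-CA-C = 111.0 in the xy-plane
  ang <- 111.0 * pi / 180
  c_ <- ca + 1.525 * c(-cos(ang), sin(ang), 0)
  o <- place_atom(n, ca, c_, 1.231, 120.5, 180)
  coords <- list(N = n, CA = ca, C = c_, O = o)
  if (aa != "G") {
    cb <- ideal_cb(n, ca, c_)
    coords$CB <- cb
    if (length(SIDECHAIN_TOPOLOGY[[aa]])) {
      sc <- build_side_chain(aa, n, ca, c_, cb, chi = chi, library = library)
      coords <- c(coords[c("N", "CA", "C", "O")], sc)
    }
  }
  coords
}
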