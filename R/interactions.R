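# Geometric interaction inventories: hydrogen bonds, van der Waals clashes,
# disulfide bridges, minimum interatomic distances.
#
# All criteria are heavy-atom-only: crystal structures at typical
# resolutions carry no hydrogens, so a hydrogen bond is scored from the
# donor--acceptor heavy-atom distance plus, where the donor's antecedent
# atom is present, the angle antecedent-donor-acceptor.

# Donor atom names (with the residues they belong to; NULL = any residue)
# and the antecedent atom used for the angle test.
HBOND_DONORS <- list(
  list(atom = "N",   res = NULL,  antecedent = "CA"),   # backbone amide
  list(atom = "NE",  res = "ARG", antecedent = "CD"),
  list(atom = "NH1", res = "ARG", antecedent = "CZ"),
  list(atom = "NH2", res = "ARG", antecedent = "CZ"),
  list(atom = "NZ",  res = "LYS", antecedent = "CE"),
  list(atom = "ND1", res = "HIS", antecedent = "CG"),
  list(atom = "NE2", res = "HIS", antecedent = "CE1"),
  list(atom = "ND2", res = "ASN", antecedent = "CG"),
  list(atom = "NE2", res = "GLN", antecedent = "CD"),
  list(atom = "NE1", res = "TRP", antecedent = "CD1"),
  list(atom = "OG",  res = "SER", antecedent = "CB"),
  list(atom = "OG1", res = "THR", antecedent = "CB"),
  list(atom = "OH",  res = "TYR", antecedent = "CZ")
)

HBOND_ACCEPTORS <- list(
  list(atom = "O",   res = NULL),    # backbone carbonyl
  list(atom = "OXT", res = NULL),
  list(atom = "OD1", res = NULL),    # Asp/Asn
  list(atom = "OD2", res = "ASP"),
  list(atom = "OE1", res = NULL),    # Glu/Gln
  list(atom = "OE2", res = "GLU"),
  list(atom = "OG",  res = "SER"),
  list(atom = "OG1", res = "THR"),
  list(atom = "OH",  res = "TYR"),
  list(atom = "ND1", res = "HIS"),
  list(atom = "NE2", res = "HIS"),
  list(atom = "SD",  res = "MET")
)

#' Hydrogen-bond detection criteria
#'
#' Two distance tiers are scored: "firm" bonds up to `max_distance`
#' (conventional 3.5 Angstrom heavy-atom cutoff) and "potential" bonds in
#' the looser band up to `potential_max_distance`, mirroring the weaker
#' contacts a modelling session flags as dotted candidate interactions.
#'
#' @param max_distance firm donor-acceptor heavy-atom cutoff, Angstrom.
#' @param potential_max_distance outer cutoff for potential bonds, Angstrom.
#' @param min_angle minimum antecedent-donor-acceptor angle, degrees; the
#'   test is skipped when the antecedent atom is absent.
#' @return list of criteria for [detect_hbonds()].
#' @export
hbond_criteria <- function(max_distance = 3.5, potential_max_distance = 4.0,
                           min_angle = 90) {
  stopifnot(max_distance > 0, potential_max_distance >= max_distance)
  list(max_distance = max_distance,
       potential_max_distance = potential_max_distance,
       min_angle = min_angle)
}

match_role <- function(atoms, roles) {
  hit <- rep(FALSE, nrow(atoms))
  ante <- rep(NA_character_, nrow(atoms))
  for (r in roles) {
    m <- atoms$elety == r$atom &
      (is.null(r$res) | atoms$resid == (if (is.null(r$res)) atoms$resid else r$res))
    hit <- hit | m
    if (!is.null(r$antecedent)) ante[m & is.na(ante)] <- r$antecedent
  }
  list(hit = hit, antecedent = ante)
}

#' Detect hydrogen bonds
#'
#' Inventories donor-acceptor pairs among standard protein heavy-atom
#' donor/acceptor sets. Intra-residue pairs are excluded, as is the
#' covalently constrained backbone pair N(i+1)...O(i) across a peptide
#' bond.
#'
#' @param structure a `structure3d`.
#' @param criteria from [hbond_criteria()].
#' @return data.frame of class `hbond_set`: donor/acceptor chain, residue,
#'   atom, heavy-atom distance, angle (NA when not computable) and tier
#'   (`"firm"` or `"potential"`).
#' @export
detect_hbonds <- function(structure, criteria = hbond_criteria()) {
  at <- structure[structure$record == "ATOM", , drop = FALSE]
  don <- match_role(at, HBOND_DONORS)
  acc <- match_role(at, HBOND_ACCEPTORS)
  di <- which(don$hit)
  ai <- which(acc$hit)
  out <- list()
  xyz <- atom_xyz(at)
  for (d in di) {
    dpos <- xyz[d, ]
    dres <- at$resno[d]; dch <- at$chain[d]
    ante_name <- don$antecedent[d]
    ante_row <- which(at$chain == dch & at$resno == dres &
                      at$elety == ante_name)
    for (a in ai) {
      if (at$chain[a] == dch && at$resno[a] == dres) next
      # exclude peptide-bond N(i+1)..O(i): 1-3 through the carbonyl carbon
      if (at$elety[d] == "N" && at$elety[a] == "O" &&
          at$chain[a] == dch && at$resno[a] == dres - 1L) next
      dist <- vnorm(xyz[a, ] - dpos)
      if (dist > criteria$potential_max_distance) next
      ang <- NA_real_
      if (length(ante_row) == 1L) {
        ang <- atom_angle(xyz[ante_row, ], dpos, xyz[a, ])
        if (ang < criteria$min_angle) next
      }
      tier <- if (dist <= criteria$max_distance) "firm" else "potential"
      out[[length(out) + 1L]] <- data.frame(
        donor_chain = dch, donor_resno = dres, donor_resid = at$resid[d],
        donor_atom = at$elety[d],
        acceptor_chain = at$chain[a], acceptor_resno = at$resno[a],
        acceptor_resid = at$resid[a], acceptor_atom = at$elety[a],
        distance = dist, angle = ang, tier = tier,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    donor_chain = character(0), donor_resno = integer(0),
    donor_resid = character(0), donor_atom = character(0),
    acceptor_chain = character(0), acceptor_resno = integer(0),
    acceptor_resid = character(0), acceptor_atom = character(0),
    distance = numeric(0), angle = numeric(0), tier = character(0),
    stringsAsFactors = FALSE)
  res <- res[order(res$donor_chain, res$donor_resno, res$donor_atom,
                   res$acceptor_chain, res$acceptor_resno,
                   res$acceptor_atom), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("hbond_set", "data.frame")
  res
}

hbond_key <- function(h) {
  if (!nrow(h)) return(character(0))
  paste(h$donor_chain, h$donor_resno, h$donor_atom, "->",
        h$acceptor_chain, h$acceptor_resno, h$acceptor_atom)
}

#' Difference two hydrogen-bond inventories around a focus residue
#'
#' Restricts attention to bonds touching the focus residue or any of its
#' pre-substitution partners, then reports which of those bonds were lost
#' and which were gained.
#'
#' @param before,after `hbond_set`s from [detect_hbonds()].
#' @param focus_resno residue number of the substituted residue.
#' @param focus_chain chain of the substituted residue (default any match).
#' @return list with data.frames `lost` and `gained`.
#' @export
diff_hbonds <- function(before, after, focus_resno, focus_chain = NULL) {
  touches <- function(h, resnos) {
    if (!nrow(h)) return(logical(0))
    sel <- h$donor_resno %in% resnos | h$acceptor_resno %in% resnos
    if (!is.null(focus_chain))
      sel <- sel & (h$donor_chain == focus_chain |
                    h$acceptor_chain == focus_chain)
    sel
  }
  pre <- before[touches(before, focus_resno), , drop = FALSE]
  partners <- unique(c(pre$donor_resno, pre$acceptor_resno))
  scope <- unique(c(focus_resno, partners))
  b <- before[touches(before, scope), , drop = FALSE]
  a <- after[touches(after, scope), , drop = FALSE]
  lost <- b[!hbond_key(b) %in% hbond_key(a), , drop = FALSE]
  gained <- a[!hbond_key(a) %in% hbond_key(b), , drop = FALSE]
  rownames(lost) <- rownames(gained) <- NULL
  list(lost = lost, gained = gained)
}

# van der Waals radii, Angstrom (standard Bondi-style set; CA = calcium ion)
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               H = 1.20, CA = 2.31, MG = 1.73, MN = 2.05, ZN = 2.10,
               FE = 2.05, "NA" = 2.27, K = 2.75)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# pairs excluded from clash scoring: same residue, the peptide bond
# C(i)-N(i+1) and its 1-3 neighbours CA(i)-N(i+1), O(i)-N(i+1), C(i)-CA(i+1)
clash_excluded <- function(at, i, j) {
  if (at$chain[i] == at$chain[j] && at$resno[i] == at$resno[j]) return(TRUE)
  if (at$chain[i] != at$chain[j]) return(FALSE)
  lo <- if (at$resno[i] < at$resno[j]) i else j
  hi <- if (at$resno[i] < at$resno[j]) j else i
  if (at$resno[hi] - at$resno[lo] != 1L) return(FALSE)
  (at$elety[lo] %in% c("C", "CA", "O") && at$elety[hi] == "N") ||
    (at$elety[lo] == "C" && at$elety[hi] == "CA")
}

#' Detect steric clashes
#'
#' Flags atom pairs whose distance is below the sum of their van der Waals
#' radii minus `overlap_threshold` ("bumps"). Covalently bonded pairs and
#' their 1-3 neighbours are excluded.
#'
#' @param structure a `structure3d`.
#' @param focus_resno optional residue number: only pairs involving this
#'   residue are scored. `NULL` scores all pairs.
#' @param overlap_threshold minimum van der Waals overlap, Angstrom
#'   (default 0.4, the conventional "serious bump" level).
#' @param focus_chain optional chain for the focus residue.
#' @param include_hetatm score clashes against HETATM atoms (metals)?
#' @return data.frame of class `clash_set` with the clashing pair,
#'   distance and overlap.
#' @export
detect_clashes <- function(structure, focus_resno = NULL,
                           overlap_threshold = 0.4, focus_chain = NULL,
                           include_hetatm = TRUE) {
  at <- structure
  if (!include_hetatm) at <- at[at$record == "ATOM", , drop = FALSE]
  xyz <- atom_xyz(at)
  el <- atom_elements(at)
  rad <- vdw_radius(el)
  n <- nrow(at)
  if (is.null(focus_resno)) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  } else {
    idx_i <- which(at$resno == focus_resno & at$record == "ATOM" &
                   (if (is.null(focus_chain)) TRUE else at$chain == focus_chain))
    other <- setdiff(seq_len(n), idx_i)
    pairs <- rbind(
      if (length(other)) expand.grid(row = idx_i, col = other),
      if (length(idx_i) > 1L) {
        w <- utils::combn(idx_i, 2L)
        data.frame(row = w[1, ], col = w[2, ])
      })
    pairs <- as.matrix(pairs)
  }
  out <- list()
  if (!is.null(pairs) && nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    {
      if (clash_excluded(at, i, j)) next
      d <- vnorm(xyz[i, ] - xyz[j, ])
      overlap <- rad[i] + rad[j] - d
      if (overlap > overlap_threshold) {
        out[[length(out) + 1L]] <- data.frame(
          chain_a = at$chain[i], resno_a = at$resno[i],
          resid_a = at$resid[i], atom_a = at$elety[i],
          chain_b = at$chain[j], resno_b = at$resno[j],
          resid_b = at$resid[j], atom_b = at$elety[j],
          distance = d, overlap = overlap, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    chain_a = character(0), resno_a = integer(0), resid_a = character(0),
    atom_a = character(0), chain_b = character(0), resno_b = integer(0),
    resid_b = character(0), atom_b = character(0),
    distance = numeric(0), overlap = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("clash_set", "data.frame")
  res
}

#' Detect disulfide bridges
#'
#' Cys pairs whose SG atoms lie within `cutoff` of each other.
#'
#' @param structure a `structure3d`.
#' @param cutoff SG-SG distance cutoff, Angstrom (default 2.3; the covalent
#'   S-S bond is about 2.05).
#' @return data.frame with one row per bridged pair.
#' @export
detect_disulfides <- function(structure, cutoff = 2.3) {
  sg <- structure[structure$record == "ATOM" & structure$resid == "CYS" &
                  structure$elety == "SG", , drop = FALSE]
  out <- list()
  if (nrow(sg) >= 2L) {
    xyz <- atom_xyz(sg)
    for (i in seq_len(nrow(sg) - 1L)) {
      for (j in seq(i + 1L, nrow(sg))) {
        d <- vnorm(xyz[i, ] - xyz[j, ])
        if (d <= cutoff)
          out[[length(out) + 1L]] <- data.frame(
            chain_a = sg$chain[i], resno_a = sg$resno[i],
            chain_b = sg$chain[j], resno_b = sg$resno[j],
            distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    chain_a = character(0), resno_a = integer(0),
    chain_b = character(0), resno_b = integer(0),
    distance = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Minimum interatomic distance between two residues
#'
#' @param structure a `structure3d`.
#' @param chain_a,resno_a,chain_b,resno_b residue selectors.
#' @param atoms_a,atoms_b optional atom-name filters (character vectors).
#' @return minimum distance in Angstrom (0 when both selectors address the
#'   same residue with no distinguishing filters).
#' @export
min_distance <- function(structure, chain_a, resno_a, chain_b, resno_b,
                         atoms_a = NULL, atoms_b = NULL) {
  a <- residue_atoms(structure, chain_a, resno_a)
  b <- residue_atoms(structure, chain_b, resno_b)
  if (!is.null(atoms_a)) a <- a[a$elety %in% atoms_a, , drop = FALSE]
  if (!is.null(atoms_b)) b <- b[b$elety %in% atoms_b, , drop = FALSE]
  if (!nrow(a) || !nrow(b))
    stop("residue selection matched no atoms", call. = FALSE)
  if (chain_a == chain_b && resno_a == resno_b &&
      is.null(atoms_a) && is.null(atoms_b)) return(0)
  xa <- atom_xyz(a); xb <- atom_xyz(b)
  min(apply(xa, 1, function(p) min(sqrt(colSums((t(xb) - p)^2)))))
}
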