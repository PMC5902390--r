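# Independent brute-force oracles used to cross-check every geometric
# detector. These deliberately share no code with the package: PDB text is
# parsed here by fixed-column substring, and every inventory is a plain
# double loop over atom pairs.

oracle_atoms <- function(pdb_text) {
  lines <- strsplit(pdb_text, "\n")[[1]]
  lines <- lines[grepl("^(ATOM  |HETATM)", lines)]
  data.frame(
    record = trimws(substr(lines, 1, 6)),
    name = trimws(substr(lines, 13, 16)),
    resid = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    resno = as.integer(substr(lines, 23, 26)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
}

oracle_dist <- function(a, b) {
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
}

oracle_angle <- function(a, b, c) {
  u <- c(a$x - b$x, a$y - b$y, a$z - b$z)
  v <- c(c$x - b$x, c$y - b$y, c$z - b$z)
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# donor atoms (with antecedent for the angle test) and acceptor atoms,
# restated independently of the package tables
ORACLE_DONORS <- rbind(
  data.frame(name = "N", resid = NA, ante = "CA"),
  data.frame(name = c("NE", "NH1", "NH2"), resid = "ARG",
             ante = c("CD", "CZ", "CZ")),
  data.frame(name = "NZ", resid = "LYS", ante = "CE"),
  data.frame(name = c("ND1", "NE2"), resid = "HIS", ante = c("CG", "CE1")),
  data.frame(name = "ND2", resid = "ASN", ante = "CG"),
  data.frame(name = "NE2", resid = "GLN", ante = "CD"),
  data.frame(name = "NE1", resid = "TRP", ante = "CD1"),
  data.frame(name = "OG", resid = "SER", ante = "CB"),
  data.frame(name = "OG1", resid = "THR", ante = "CB"),
  data.frame(name = "OH", resid = "TYR", ante = "CZ")
)

ORACLE_ACCEPTORS <- rbind(
  data.frame(name = c("O", "OXT", "OD1", "OE1"), resid = NA),
  data.frame(name = "OD2", resid = "ASP"),
  data.frame(name = "OE2", resid = "GLU"),
  data.frame(name = "OG", resid = "SER"),
  data.frame(name = "OG1", resid = "THR"),
  data.frame(name = "OH", resid = "TYR"),
  data.frame(name = c("ND1", "NE2"), resid = "HIS"),
  data.frame(name = "SD", resid = "MET")
)

# returns "chain resno atom -> chain resno atom" keys for every qualifying
# donor/acceptor pair
oracle_hbond_keys <- function(atoms, max_dist = 3.5, min_angle = 90) {
  at <- atoms[atoms$record == "ATOM", ]
  keys <- character(0)
  for (i in seq_len(nrow(at))) {
    drow <- at[i, ]
    dm <- ORACLE_DONORS[ORACLE_DONORS$name == drow$name &
                        (is.na(ORACLE_DONORS$resid) |
                         ORACLE_DONORS$resid == drow$resid), ]
    if (!nrow(dm)) next
    ante <- at[at$chain == drow$chain & at$resno == drow$resno &
               at$name == dm$ante[1], ]
    for (j in seq_len(nrow(at))) {
      arow <- at[j, ]
      am <- ORACLE_ACCEPTORS[ORACLE_ACCEPTORS$name == arow$name &
                             (is.na(ORACLE_ACCEPTORS$resid) |
                              ORACLE_ACCEPTORS$resid == arow$resid), ]
      if (!nrow(am)) next
      if (arow$chain == drow$chain && arow$resno == drow$resno) next
      if (drow$name == "N" && arow$name == "O" &&
          arow$chain == drow$chain && arow$resno == drow$resno - 1L) next
      if (oracle_dist(drow, arow) > max_dist) next
      if (nrow(ante) == 1L && oracle_angle(ante, drow, arow) < min_angle) next
      keys <- c(keys, paste(drow$chain, drow$resno, drow$name, "->",
                            arow$chain, arow$resno, arow$name))
    }
  }
  sort(keys)
}

ORACLE_VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, CA = 2.31)

oracle_clash_count <- function(atoms, threshold = 0.4, focus_resno = NULL) {
  n <- nrow(atoms)
  count <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- atoms[i, ]; b <- atoms[j, ]
      if (!is.null(focus_resno) &&
          !(a$resno == focus_resno || b$resno == focus_resno)) next
      if (a$chain == b$chain && a$resno == b$resno) next
      if (a$chain == b$chain && abs(a$resno - b$resno) == 1L) {
        lo <- if (a$resno < b$resno) a else b
        hi <- if (a$resno < b$resno) b else a
        if ((lo$name %in% c("C", "CA", "O") && hi$name == "N") ||
            (lo$name == "C" && hi$name == "CA")) next
      }
      ra <- ORACLE_VDW[a$element]; rb <- ORACLE_VDW[b$element]
      if (is.na(ra)) ra <- 1.70
      if (is.na(rb)) rb <- 1.70
      if (ra + rb - oracle_dist(a, b) > threshold) count <- count + 1L
    }
  }
  count
}

oracle_disulfide_count <- function(atoms, cutoff = 2.3) {
  sg <- atoms[atoms$resid == "CYS" & atoms$name == "SG", ]
  count <- 0L
  if (nrow(sg) >= 2L)
    for (i in seq_len(nrow(sg) - 1L))
      for (j in seq(i + 1L, nrow(sg)))
        if (oracle_dist(sg[i, ], sg[j, ]) <= cutoff) count <- count + 1L
  count
}

oracle_shell_size <- function(atoms, cutoff = 3.0) {
  ion <- atoms[atoms$record == "HETATM" & atoms$element == "CA", ]
  stopifnot(nrow(ion) == 1L)
  ox <- atoms[atoms$record == "ATOM" & atoms$element == "O", ]
  if (!nrow(ox)) return(0L)
  sum(sapply(seq_len(nrow(ox)), function(i) oracle_dist(ox[i, ], ion)) <=
        cutoff)
}

# a deterministic "random" rigid-body transform for invariance tests
rigid_transform_structure <- function(structure, seed) {
  set.seed(seed)
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  t <- stats::runif(3, -20, 20)
  transform_structure(structure, R, t)
}
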