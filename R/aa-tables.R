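# Amino-acid code tables shared across modules.

AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
  Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
  L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
  S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val"
)
AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

#' Normalise an amino-acid code to its one-letter form
#'
#' Accepts one-letter ("D"), three-letter ("Asp", any case) or full-width
#' PDB residue names ("ASP") and returns the standard one-letter code.
#'
#' @param aa character vector of amino-acid codes.
#' @return character vector of one-letter codes.
#' @examples
#' aa_one(c("Asp", "ALA", "q"))
#' @export
aa_one <- function(aa) {
  vapply(as.character(aa), function(x) {
    if (nchar(x) == 1L) {
      x <- toupper(x)
      if (!x %in% names(AA_THREE))
        stop("not a standard amino acid: '", x, "'", call. = FALSE)
      return(x)
    }
    key <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
    if (!key %in% AA_THREE)
      stop("not a standard amino acid: '", x, "'", call. = FALSE)
    unname(AA_ONE[[key]])
  }, character(1), USE.NAMES = FALSE)
}

#' Normalise an amino-acid code to its three-letter form
#'
#' @inheritParams aa_one
#' @return character vector of three-letter codes ("Asp" style).
#' @export
aa_three <- function(aa) {
  unname(AA_THREE[aa_one(aa)])
}

# PDB-style residue name, e.g. "ASP"
aa_pdb <- function(aa) toupper(aa_three(aa))

# Translate one codon with the standard genetic code ("*" for stop).
translate_codon <- function(codon) {
  codon <- toupper(codon)
  stopifnot(nchar(codon) == 3L)
  Biostrings::GENETIC_CODE[[codon]]
}

# Run code under a temporary RNG state so generators are pure in (args, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
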