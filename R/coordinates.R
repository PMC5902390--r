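# Coordinate systems and variant parsing.
#
# HGVS conventions: cDNA position +1 is the A of the ATG start codon;
# protein position +1 is the initiator Met (signal peptide included).
# Mature-protein numbering, used in integrin crystal structures, subtracts
# the cleaved signal peptide: 31 residues for alphaIIb, 26 for beta3.
# All coordinates are 1-based and inclusive throughout.

#' Construct a gene model
#'
#' A gene model ties a coding sequence to the signal-peptide length that
#' separates HGVS protein numbering from mature-protein numbering.
#'
#' @param gene_symbol gene name, e.g. `"ITGA2B"`.
#' @param cds coding sequence (character, A/C/G/T), starting with ATG and a
#'   whole number of codons. May be `NA` for numbering-only models.
#' @param signal_peptide_length residues removed on maturation
#'   (31 for alphaIIb, 26 for beta3).
#' @return object of class `gene_model`.
#' @examples
#' itga2b <- gene_model("ITGA2B", make_gene_model()$cds, 31)
#' @export
gene_model <- function(gene_symbol, cds = NA_character_,
                       signal_peptide_length = 0L) {
  signal_peptide_length <- as.integer(signal_peptide_length)
  if (is.na(signal_peptide_length) || signal_peptide_length < 0L)
    stop("signal_peptide_length must be a non-negative integer", call. = FALSE)
  if (!is.na(cds)) {
    cds <- toupper(cds)
    if (nchar(cds) %% 3L != 0L)
      stop("CDS length must be a multiple of 3", call. = FALSE)
    if (substr(cds, 1, 3) != "ATG")
      stop("CDS must start with ATG", call. = FALSE)
    if (grepl("[^ACGT]", cds))
      stop("CDS contains non-ACGT characters", call. = FALSE)
  }
  structure(
    list(gene_symbol = gene_symbol, cds = cds,
         signal_peptide_length = signal_peptide_length),
    class = "gene_model"
  )
}

#' Read a gene model from a FASTA coding sequence
#'
#' @param path FASTA file containing a single CDS record.
#' @inheritParams gene_model
#' @return a `gene_model`.
#' @export
read_gene_model <- function(path, gene_symbol, signal_peptide_length) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L)
    stop("expected exactly one CDS record in ", path, call. = FALSE)
  gene_model(gene_symbol, as.character(seqs[[1]]), signal_peptide_length)
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model>", x$gene_symbol,
      if (!is.na(x$cds)) sprintf("CDS %d nt (%d codons)", nchar(x$cds),
                                 nchar(x$cds) %/% 3L) else "no CDS",
      sprintf("signal peptide %d aa", x$signal_peptide_length), "\n")
  invisible(x)
}

#' Codon number of a cDNA position
#'
#' @param cdna_position 1-based position, +1 at the A of the start ATG.
#' @return codon (= HGVS protein) number, `ceiling(position / 3)`.
#' @examples
#' codon_of(1772)  # 591
#' codon_of(1878)  # 626
#' @export
codon_of <- function(cdna_position) {
  cdna_position <- as.numeric(cdna_position)
  if (any(is.na(cdna_position)) || any(cdna_position < 1) ||
      any(cdna_position != floor(cdna_position)))
    stop("cDNA position must be a positive integer", call. = FALSE)
  as.integer(ceiling(cdna_position / 3))
}

#' Mature-protein position of an HGVS protein position
#'
#' Subtracts the signal-peptide length, so alphaIIb Asp591 becomes D560 of
#' the mature subunit and beta3 Asp145 becomes D119.
#'
#' @param model a [gene_model()].
#' @param hgvs_position HGVS protein position (initiator Met = 1).
#' @return mature-protein position.
#' @export
mature_position <- function(model, hgvs_position) {
  stopifnot(inherits(model, "gene_model"))
  hgvs_position <- as.integer(hgvs_position)
  if (any(hgvs_position <= model$signal_peptide_length))
    stop("position ", paste(hgvs_position[hgvs_position <= model$signal_peptide_length],
                            collapse = ", "),
         " lies within the signal peptide (length ",
         model$signal_peptide_length, ")", call. = FALSE)
  hgvs_position - model$signal_peptide_length
}

#' HGVS protein position of a mature-protein position
#'
#' Inverse of [mature_position()].
#' @inheritParams mature_position
#' @param mature mature-protein position (first mature residue = 1).
#' @export
hgvs_position <- function(model, mature) {
  stopifnot(inherits(model, "gene_model"))
  mature <- as.integer(mature)
  if (any(mature < 1L)) stop("mature position must be >= 1", call. = FALSE)
  mature + model$signal_peptide_length
}

new_variant <- function(cdna_position = NA_integer_, ref_nt = NA_character_,
                        alt_nt = NA_character_,
                        protein_position_hgvs = NA_integer_,
                        ref_aa = NA_character_, alt_aa = NA_character_,
                        mature_position = NA_integer_) {
  structure(
    list(cdna_position = cdna_position, ref_nt = ref_nt, alt_nt = alt_nt,
         protein_position_hgvs = protein_position_hgvs,
         ref_aa = ref_aa, alt_aa = alt_aa,
         mature_position = mature_position),
    class = "genu_variant"
  )
}

#' @export
print.genu_variant <- function(x, ...) {
  cat("<variant>", format(x), "\n")
  invisible(x)
}

#' @export
format.genu_variant <- function(x, ...) {
  parts <- character(0)
  if (!is.na(x$cdna_position))
    parts <- c(parts, sprintf("c.%d%s>%s", x$cdna_position, x$ref_nt, x$alt_nt))
  if (!is.na(x$protein_position_hgvs) && !is.na(x$ref_aa))
    parts <- c(parts, sprintf("p.%s%d%s", aa_three(x$ref_aa),
                              x$protein_position_hgvs,
                              if (is.na(x$alt_aa)) "?" else aa_three(x$alt_aa)))
  if (!is.na(x$mature_position) && !is.na(x$ref_aa) && !is.na(x$alt_aa))
    parts <- c(parts, sprintf("(%s%d%s mature)", aa_one(x$ref_aa),
                              x$mature_position, aa_one(x$alt_aa)))
  paste(parts, collapse = " ")
}

#' Parse an HGVS-style variant string
#'
#' Accepts cDNA substitutions (`"c.1772A>C"`) and protein substitutions in
#' three-letter (`"p.Asp591Ala"`) or one-letter (`"p.D591A"`) code. Only
#' single-nucleotide / single-residue substitutions are in scope; indels and
#' splice-site names are catalog annotations, not computed objects.
#'
#' @param text a variant string.
#' @param model optional [gene_model()]; when given, protein variants gain a
#'   mature position and cDNA variants gain predicted protein fields.
#' @return object of class `genu_variant`.
#' @examples
#' parse_variant("c.1772A>C")
#' parse_variant("p.Asp591Ala")
#' @export
parse_variant <- function(text, model = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(text)
  m <- regmatches(txt, regexec("^c\\.([0-9]+)([ACGTacgt])>([ACGTacgt])$", txt))[[1]]
  if (length(m)) {
    v <- new_variant(cdna_position = as.integer(m[2]),
                     ref_nt = toupper(m[3]), alt_nt = toupper(m[4]))
    v$protein_position_hgvs <- codon_of(v$cdna_position)
    if (!is.null(model)) {
      if (!is.na(model$cds)) v <- predict_protein_change(model, v)
      if (v$protein_position_hgvs > model$signal_peptide_length)
        v$mature_position <- mature_position(model, v$protein_position_hgvs)
    }
    return(v)
  }
  m <- regmatches(txt, regexec(
    "^p\\.([A-Za-z]{3}|[A-Za-z])([0-9]+)([A-Za-z]{3}|[A-Za-z])$", txt))[[1]]
  if (length(m)) {
    aas <- lapply(m[c(2, 4)], function(tok) {
      tryCatch(aa_one(tok), error = function(e)
        stop("cannot parse variant '", text, "': '", tok,
             "' is not an amino-acid code", call. = FALSE))
    })
    v <- new_variant(protein_position_hgvs = as.integer(m[3]),
                     ref_aa = aas[[1]], alt_aa = aas[[2]])
    if (!is.null(model) && v$protein_position_hgvs > model$signal_peptide_length)
      v$mature_position <- mature_position(model, v$protein_position_hgvs)
    return(v)
  }
  stop("cannot parse variant '", text,
       "': expected 'c.<pos><NT>><NT>' or 'p.<Aaa><pos><Aaa>'", call. = FALSE)
}

#' Predict the protein consequence of a cDNA substitution
#'
#' Extracts the affected codon from the gene model's CDS, checks that the
#' stated reference nucleotide matches, applies the substitution, and
#' translates reference and alternate codons with the standard genetic code.
#'
#' @inheritParams mature_position
#' @param variant a `genu_variant` with cDNA fields (or a string to parse).
#' @return the variant with `ref_aa`, `alt_aa`, protein and mature positions
#'   filled in. A synonymous change yields `ref_aa == alt_aa`.
#' @examples
#' gm <- gene_model("ITGA2B", make_gene_model()$cds, 31)
#' predict_protein_change(gm, "c.1772A>C")  # p.Asp591Ala
#' @export
predict_protein_change <- function(model, variant) {
  stopifnot(inherits(model, "gene_model"))
  if (is.character(variant)) variant <- parse_variant(variant)
  if (is.na(variant$cdna_position))
    stop("variant carries no cDNA fields", call. = FALSE)
  if (is.na(model$cds))
    stop("gene model has no CDS", call. = FALSE)
  pos <- variant$cdna_position
  if (pos > nchar(model$cds))
    stop("cDNA position ", pos, " beyond CDS end (", nchar(model$cds), ")",
         call. = FALSE)
  codon_no <- codon_of(pos)
  start <- 3L * (codon_no - 1L) + 1L
  ref_codon <- substr(model$cds, start, start + 2L)
  offset <- pos - start + 1L
  found <- substr(ref_codon, offset, offset)
  if (found != variant$ref_nt)
    stop("reference mismatch at c.", pos, ": CDS has ", found,
         ", variant states ", variant$ref_nt, call. = FALSE)
  alt_codon <- ref_codon
  substr(alt_codon, offset, offset) <- variant$alt_nt
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  if (ref_aa == "*" || alt_aa == "*")
    stop("stop codon involved at codon ", codon_no,
         "; only missense/synonymous changes are modelled", call. = FALSE)
  variant$protein_position_hgvs <- codon_no
  variant$ref_aa <- ref_aa
  variant$alt_aa <- alt_aa
  if (codon_no > model$signal_peptide_length)
    variant$mature_position <- mature_position(model, codon_no)
  variant
}

#' Classify a nucleotide substitution as transition or transversion
#'
#' Purine<->purine or pyrimidine<->pyrimidine exchanges are transitions;
#' purine<->pyrimidine exchanges (like the index case's c.1772A>C) are
#' transversions.
#'
#' @param ref,alt single nucleotides.
#' @return `"transition"` or `"transversion"`.
#' @export
classify_nt_change <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  nts <- c("A", "C", "G", "T")
  if (!ref %in% nts || !alt %in% nts)
    stop("nucleotides must be one of A, C, G, T", call. = FALSE)
  if (ref == alt) stop("ref and alt are identical", call. = FALSE)
  purine <- c("A", "G")
  if ((ref %in% purine) == (alt %in% purine)) "transition" else "transversion"
}
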