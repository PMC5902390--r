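# Positional conservation scoring on pre-aligned species / paralog panels.

#' Coerce an alignment to a character matrix
#'
#' Accepts a path to an aligned FASTA file, FASTA text, a
#' `Biostrings::AAStringSet`, a named character vector of equal-length
#' sequences, or an already-built character matrix.
#'
#' @param alignment any of the accepted forms.
#' @return character matrix, sequences in rows, columns as alignment
#'   columns; residues upper-case, gaps as `"-"`.
#' @export
as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else if (methods::is(alignment, "AAStringSet") ||
             methods::is(alignment, "XStringSet")) {
    seqs <- as.character(alignment)
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(alignment)
  } else if (is.character(alignment)) {
    if (length(alignment) == 1L && grepl("^>", alignment)) {
      path <- tempfile(fileext = ".fasta")
      on.exit(unlink(path))
      writeLines(sub("\n$", "", alignment), path)
      return(as_alignment_matrix(Biostrings::readAAStringSet(path)))
    }
    if (length(alignment) == 1L && file.exists(alignment))
      return(as_alignment_matrix(Biostrings::readAAStringSet(alignment)))
    m <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(m) <- names(alignment)
  } else {
    stop("unsupported alignment representation", call. = FALSE)
  }
  if (length(unique(nchar(apply(m, 1, paste, collapse = "")))) > 1L)
    stop("sequences differ in aligned length", call. = FALSE)
  m[m == "."] <- "-"
  m
}

#' Identity fraction of one alignment column
#'
#' Fraction of sequences (reference included) carrying the reference
#' sequence's residue at the column. Gaps count as mismatches; an all-gap
#' column (reference gapped) scores 0.
#'
#' @param alignment see [as_alignment_matrix()].
#' @param column 1-based column index.
#' @param reference row index or name of the reference sequence (default
#'   first row).
#' @return fraction in `[0, 1]`.
#' @export
column_identity <- function(alignment, column, reference = 1L) {
  m <- as_alignment_matrix(alignment)
  if (column < 1L || column > ncol(m))
    stop("column ", column, " outside alignment width ", ncol(m),
         call. = FALSE)
  col <- m[, column]
  ref <- col[reference]
  if (ref == "-") return(0)
  mean(col == ref)
}

# default physicochemical similarity classes, config-replaceable
DEFAULT_SIMILARITY_CLASSES <- list(
  aliphatic = c("I", "L", "V", "M", "A"),
  aromatic = c("F", "W", "Y"),
  basic = c("K", "R", "H"),
  acidic = c("D", "E"),
  polar = c("S", "T", "N", "Q"),
  cysteine = "C",
  glycine = "G",
  proline = "P"
)

residue_class <- function(aa, classes = DEFAULT_SIMILARITY_CLASSES) {
  vapply(aa, function(x) {
    hit <- names(classes)[vapply(classes, function(cl) x %in% cl, logical(1))]
    if (length(hit)) hit[1] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Is a residue retained across the panel at a column?
#'
#' Strict mode requires every sequence to carry exactly the reference
#' residue. Class mode accepts substitutions within the same
#' physicochemical similarity class (e.g. an Ile/Leu/Val column is
#' class-conserved but not strictly conserved).
#'
#' @inheritParams column_identity
#' @param reference_residue the residue expected (one-letter code).
#' @param mode `"strict"` or `"class"`.
#' @param classes similarity classes; see `DEFAULT_SIMILARITY_CLASSES`.
#' @return logical.
#' @export
is_retained_in_all <- function(alignment, column, reference_residue,
                               mode = c("strict", "class"),
                               classes = DEFAULT_SIMILARITY_CLASSES) {
  mode <- match.arg(mode)
  m <- as_alignment_matrix(alignment)
  if (column < 1L || column > ncol(m))
    stop("column outside alignment width", call. = FALSE)
  col <- m[, column]
  ref <- aa_one(reference_residue)
  if (mode == "strict") return(all(col == ref))
  ref_class <- residue_class(ref, classes)
  cls <- residue_class(col, classes)
  all(!is.na(cls) & cls == ref_class)
}

#' Qualitative conservation label
#'
#' Maps an identity fraction to the qualitative labels used in variant
#' write-ups ("highly conserved", "relatively well conserved", "poorly
#' conserved"). Thresholds default to high >= 0.9 and moderate >= 0.5 and
#' are caller-adjustable.
#'
#' @param fraction identity fraction in `[0, 1]`.
#' @param high,moderate lower bounds of the high and moderate bands.
#' @return `"high"`, `"moderate"` or `"low"`.
#' @export
classify_conservation <- function(fraction, high = 0.9, moderate = 0.5) {
  stopifnot(all(fraction >= 0 & fraction <= 1), high >= moderate)
  ifelse(fraction >= high, "high",
         ifelse(fraction >= moderate, "moderate", "low"))
}

#' Per-column conservation profile
#'
#' @inheritParams column_identity
#' @inheritParams classify_conservation
#' @param classes similarity classes for the class-conservation column.
#' @return data.frame with one row per column: `column`,
#'   `identity_fraction`, `strict_conservation`, `class_conservation`,
#'   `label`, and the residue classes present.
#' @export
conservation_profile <- function(alignment, reference = 1L,
                                 high = 0.9, moderate = 0.5,
                                 classes = DEFAULT_SIMILARITY_CLASSES) {
  m <- as_alignment_matrix(alignment)
  out <- do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
    f <- column_identity(m, j, reference)
    ref <- m[reference, j]
    strict <- ref != "-" && all(m[, j] == ref)
    cls <- if (ref == "-") FALSE else
      is_retained_in_all(m, j, ref, mode = "class", classes = classes)
    present <- unique(residue_class(setdiff(m[, j], "-"), classes))
    data.frame(column = j, identity_fraction = f,
               strict_conservation = strict, class_conservation = cls,
               label = classify_conservation(f, high, moderate),
               classes_present = paste(sort(present), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a conservation profile as TSV
#'
#' @param profile output of [conservation_profile()].
#' @param path output file.
#' @export
write_conservation_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
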