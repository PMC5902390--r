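# The embedded variant catalog: published Glanzmann thrombasthenia (GT)
# missense variants, low-frequency platelet alloantigens (HPA), and rare
# database-only variants in the alphaIIb aa471-769 region around the genu.
# Catalog contents are transcribed annotations with provenance strings;
# zygosity, GT type, mechanisms and minor-allele frequencies are data, not
# computed results. MAF strings are stored verbatim (frequencies drift
# between database releases, and one printed value is ambiguous) with a
# parsed numeric only where unambiguous.

# Default domain boundaries in HGVS numbering. The boundaries are
# approximate: they are chosen so that every published domain placement in
# the region (Ala477 beta-propeller, Asp591 thigh, the Cys633-Cys639 loop
# at the genu, Thr646 through Arg755 calf-1, Pro772 at the calf-1/calf-2
# interface) comes out right, and they are caller-replaceable.
DEFAULT_DOMAIN_BOUNDARIES <- data.frame(
  domain = c("beta-propeller", "thigh", "genu linker", "calf-1",
             "calf-1/2 interface"),
  from = c(1L, 484L, 633L, 645L, 770L),
  to = c(483L, 632L, 644L, 769L, 775L),
  stringsAsFactors = FALSE
)

#' Assign the alphaIIb domain of a protein position
#'
#' @param protein_position HGVS protein position(s).
#' @param boundaries boundary table (`domain`, `from`, `to`); defaults to
#'   the approximate alphaIIb ectodomain boundaries.
#' @return character vector of domain labels (`NA` outside all bands).
#' @examples
#' assign_domain(c(477, 591, 633, 705))
#' @export
assign_domain <- function(protein_position,
                          boundaries = DEFAULT_DOMAIN_BOUNDARIES) {
  vapply(as.integer(protein_position), function(p) {
    hit <- boundaries$domain[p >= boundaries$from & p <= boundaries$to]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
}

VALID_MECHANISMS <- c("hbond_loss", "steric", "disulfide_loss",
                      "metal_disruption", "splicing_mRNA_decay",
                      "buried_charge")

#' Load the embedded variant catalog
#'
#' Returns the versioned catalog of published missense variants in the
#' alphaIIb aa471-769 region: 16 GT-causing records (including the
#' Asp591Ala index case), 2 HPA polymorphisms, 3 rare database-only genu
#' variants, and one explicitly excluded interface record. The catalog is
#' schema-validated on load: positions, categories, mechanism flags and
#' domain assignments are all checked.
#'
#' @param path optional path to an alternative catalog TSV.
#' @return data.frame of class `variant_catalog`, one row per record, with
#'   parsed `protein_position`, `ref_aa`, `alt_aa` and `domain` columns
#'   added.
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "variant_catalog.tsv", package = "genuvar",
                        mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  required <- c("variant", "cdna", "gene", "category", "gt_type",
                "index_case", "zygosity", "mechanisms", "uncertain", "rsid",
                "maf_text", "maf_numeric", "hpa_system", "provenance",
                "notes")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("catalog missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  parsed <- lapply(d$variant, parse_variant)
  d$protein_position <- vapply(parsed, `[[`, integer(1),
                               "protein_position_hgvs")
  d$ref_aa <- vapply(parsed, `[[`, character(1), "ref_aa")
  d$alt_aa <- vapply(parsed, `[[`, character(1), "alt_aa")
  d$domain <- assign_domain(d$protein_position)
  # schema validation
  stopifnot(all(d$category %in% c("GT-causing", "HPA", "database-only",
                                  "excluded")))
  stopifnot(all(d$gt_type %in% c("I", "II", "n/a")))
  gt <- d$category == "GT-causing"
  if (any(gt & (d$protein_position < 471L | d$protein_position > 769L)))
    stop("GT-causing record outside the aa471-769 scan window", call. = FALSE)
  if (any(d$category == "database-only" & is.na(d$rsid)))
    stop("database-only record without an rsID", call. = FALSE)
  mech <- strsplit(ifelse(is.na(d$mechanisms), "", d$mechanisms), ";")
  bad <- setdiff(unlist(mech), VALID_MECHANISMS)
  if (length(bad))
    stop("unknown mechanism flag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (sum(d$index_case) != 1L)
    stop("catalog must contain exactly one index case", call. = FALSE)
  class(d) <- c("variant_catalog", "data.frame")
  attr(d, "note") <- paste(
    "Nine disease-causing missense variants are reported for the",
    "genu-proximal part of calf-1 while only eight are named in the",
    "source's main text; the unnamed record is not invented here.")
  d
}

#' @export
print.variant_catalog <- function(x, ...) {
  cat(sprintf("<variant_catalog> %d records: %d GT-causing, %d HPA, %d database-only, %d excluded\n",
              nrow(x), sum(x$category == "GT-causing"),
              sum(x$category == "HPA"), sum(x$category == "database-only"),
              sum(x$category == "excluded")))
  print.data.frame(x[, c("variant", "category", "gt_type", "domain",
                         "mechanisms")], right = FALSE)
  invisible(x)
}

#' Filter catalog records
#'
#' All predicates are optional and conjunctive; an empty call returns the
#' catalog unchanged.
#'
#' @param records a `variant_catalog` from [load_catalog()].
#' @param region length-2 integer vector: keep protein positions within
#'   `[region[1], region[2]]`.
#' @param category,gt_type keep records with these values.
#' @param mechanism keep records whose mechanism flags include this value.
#' @param include_index keep the index case? Default `TRUE`.
#' @return filtered `variant_catalog`.
#' @examples
#' cat21 <- load_catalog()
#' nrow(filter_catalog(cat21, region = c(471, 769), category = "GT-causing"))
#' @export
filter_catalog <- function(records, region = NULL, category = NULL,
                           gt_type = NULL, mechanism = NULL,
                           include_index = TRUE) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(region))
    keep <- keep & records$protein_position >= region[1] &
      records$protein_position <= region[2]
  if (!is.null(category)) keep <- keep & records$category %in% category
  if (!is.null(gt_type)) keep <- keep & records$gt_type %in% gt_type
  if (!is.null(mechanism))
    keep <- keep & vapply(strsplit(ifelse(is.na(records$mechanisms), "",
                                          records$mechanisms), ";"),
                          function(m) mechanism %in% m, logical(1))
  if (!include_index) keep <- keep & !records$index_case
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
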