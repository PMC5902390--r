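# Per-variant impact reports merging coordinate, physicochemical,
# conservation and structural analyses. Every numeric field traces to one
# upstream operation; analyses whose inputs are absent are reported as
# "not assessed", never silently dropped.

#' Assess a missense variant
#'
#' Runs every analysis for which inputs are available: coordinate mapping
#' (HGVS, mature, cDNA where known), Grantham distance, conservation at an
#' alignment column, and structural impact on a PDB structure (rotamer
#' substitution, hydrogen-bond differencing, steric clashes, disulfide and
#' metal-coordination checks). Catalog annotations are attached when the
#' variant is a catalog record.
#'
#' @param variant a variant string (`"p.Asp591Ala"`, `"c.1772A>C"`) or a
#'   parsed `genu_variant`.
#' @param structure optional `structure3d`. Residue numbers in the
#'   structure are taken as-is (author numbering); see
#'   `structure_position`.
#' @param alignment optional alignment (see [as_alignment_matrix()]).
#' @param catalog a `variant_catalog`; set `NULL` to skip annotation.
#' @param model gene model used for numbering (default the synthetic
#'   alphaIIb model, signal peptide 31).
#' @param chain chain holding the residue (default `"A"`).
#' @param structure_position residue number of the variant in the
#'   structure's own numbering; defaults to the HGVS protein position.
#' @param alignment_column alignment column for conservation scoring;
#'   defaults to the HGVS protein position when it fits the alignment.
#' @param hbond hydrogen-bond criteria, see [hbond_criteria()].
#' @param clash_threshold van der Waals overlap threshold, Angstrom.
#' @param library rotamer library.
#' @return object of class `impact_report`.
#' @examples
#' rep <- assess_variant("p.Asp591Ala",
#'                       structure = read_pdb(make_hbond_fixture(2.8, 160)))
#' rep$grantham
#' @export
assess_variant <- function(variant, structure = NULL, alignment = NULL,
                           catalog = load_catalog(),
                           model = make_gene_model(), chain = "A",
                           structure_position = NULL,
                           alignment_column = NULL,
                           hbond = hbond_criteria(), clash_threshold = 0.4,
                           library = rotamer_library()) {
  if (is.character(variant)) variant <- parse_variant(variant, model = model)
  if (is.na(variant$ref_aa) || is.na(variant$alt_aa))
    stop("variant lacks protein-level fields; supply a protein variant or ",
         "a cDNA variant with a gene model carrying a CDS", call. = FALSE)
  pos <- variant$protein_position_hgvs
  report <- list(
    variant = list(
      label = format(variant),
      protein_position_hgvs = pos,
      mature_position = variant$mature_position,
      cdna = if (!is.na(variant$cdna_position))
        sprintf("c.%d%s>%s", variant$cdna_position, variant$ref_nt,
                variant$alt_nt) else NA_character_,
      nt_change_class = if (!is.na(variant$cdna_position))
        classify_nt_change(variant$ref_nt, variant$alt_nt) else NA_character_,
      ref_aa = aa_three(variant$ref_aa),
      alt_aa = aa_three(variant$alt_aa)),
    domain = assign_domain(pos),
    grantham = grantham(variant$ref_aa, variant$alt_aa),
    conservation = list(assessed = FALSE),
    structural = list(assessed = FALSE),
    catalog = list(annotated = FALSE),
    rationale = character(0)
  )
  report$rationale <- c(report$rationale, sprintf(
    "%s -> %s at position %d (%s domain): Grantham distance %d (%s physicochemical deviation).",
    report$variant$ref_aa, report$variant$alt_aa, pos,
    ifelse(is.na(report$domain), "unassigned", report$domain),
    report$grantham,
    if (report$grantham >= 100) "large" else if (report$grantham >= 50)
      "moderate" else "small"))

  if (!is.null(alignment)) {
    m <- as_alignment_matrix(alignment)
    col <- if (!is.null(alignment_column)) alignment_column
           else if (pos <= ncol(m)) pos else NA_integer_
    if (!is.na(col)) {
      f <- column_identity(m, col)
      report$conservation <- list(
        assessed = TRUE, column = col, identity_fraction = f,
        label = classify_conservation(f),
        strict = is_retained_in_all(m, col, m[1, col], mode = "strict"),
        class_conserved = is_retained_in_all(m, col, m[1, col],
                                             mode = "class"))
      report$rationale <- c(report$rationale, sprintf(
        "Conservation at alignment column %d: identity %.2f (%s).",
        col, f, report$conservation$label))
    } else {
      report$conservation <- list(assessed = FALSE,
                                  reason = "position outside alignment width")
    }
  }

  if (!is.null(structure)) {
    spos <- if (!is.null(structure_position)) structure_position else pos
    res <- residue_atoms(structure, chain, spos)
    if (!nrow(res)) {
      report$structural <- list(
        assessed = FALSE, unmodelable = TRUE,
        reason = sprintf("residue %d not among the structure's modelled residues",
                         spos))
    } else if (aa_pdb(variant$ref_aa) != res$resid[1]) {
      report$structural <- list(
        assessed = FALSE, unmodelable = TRUE,
        reason = sprintf("structure has %s at %d, variant states %s",
                         res$resid[1], spos, aa_pdb(variant$ref_aa)))
    } else {
      before_h <- detect_hbonds(structure, hbond)
      before_ss <- detect_disulfides(structure)
      mutated <- substitute_residue(structure, chain, spos, variant$alt_aa,
                                    library = library)
      after_h <- detect_hbonds(mutated, hbond)
      dh <- diff_hbonds(before_h, after_h, spos, focus_chain = chain)
      clashes <- detect_clashes(mutated, focus_resno = spos,
                                overlap_threshold = clash_threshold,
                                focus_chain = chain)
      after_ss <- detect_disulfides(mutated)
      ss_lost <- nrow(before_ss) - nrow(after_ss)
      ions <- find_metal_ions(structure)
      metal <- NULL
      if (nrow(ions) == 1L)
        metal <- coordination_disruption(structure, chain, spos,
                                         variant$alt_aa, ion = ions,
                                         library = library)
      report$structural <- list(
        assessed = TRUE, structure_position = spos,
        hbonds_lost = dh$lost, hbonds_gained = dh$gained,
        n_hbonds_lost = nrow(dh$lost), n_hbonds_gained = nrow(dh$gained),
        clashes = clashes, n_clashes = nrow(clashes),
        disulfides_before = before_ss, disulfides_after = after_ss,
        disulfide_loss = ss_lost > 0,
        metal = metal)
      if (nrow(dh$lost))
        report$rationale <- c(report$rationale, sprintf(
          "Substitution by %s results in the loss of %d structuring H-bond(s) (partners: %s).",
          report$variant$alt_aa, nrow(dh$lost),
          paste(unique(c(
            sprintf("%s%d", dh$lost$acceptor_resid, dh$lost$acceptor_resno)[
              dh$lost$donor_resno == spos],
            sprintf("%s%d", dh$lost$donor_resid, dh$lost$donor_resno)[
              dh$lost$acceptor_resno == spos])), collapse = ", ")))
      if (nrow(dh$gained))
        report$rationale <- c(report$rationale, sprintf(
          "The substitution creates %d additional H-bond(s) within the surrounding loops.",
          nrow(dh$gained)))
      if (nrow(clashes))
        report$rationale <- c(report$rationale, sprintf(
          "%d van der Waals bump(s) reveal steric encumbrance caused by the substitution (largest overlap %.2f A).",
          nrow(clashes), max(clashes$overlap)))
      if (ss_lost > 0)
        report$rationale <- c(report$rationale,
          "The substitution disrupts a disulfide bridge.")
      if (!is.null(metal) && (metal$side_chain_ligand_removed || metal$ion_clash))
        report$rationale <- c(report$rationale, paste0(
          "Metal site impact: ",
          paste(c(if (metal$side_chain_ligand_removed)
                    "a side-chain Ca2+ ligand is removed",
                  if (metal$ion_clash)
                    "the new side chain pushes against the Ca2+ ion"),
                collapse = "; "), "."))
    }
  }

  if (!is.null(catalog)) {
    lbl <- sprintf("p.%s%d%s", report$variant$ref_aa, pos,
                   report$variant$alt_aa)
    hit <- catalog[catalog$variant == lbl, , drop = FALSE]
    if (nrow(hit) == 1L) {
      report$catalog <- list(
        annotated = TRUE, category = hit$category, gt_type = hit$gt_type,
        index_case = hit$index_case, zygosity = hit$zygosity,
        mechanisms = hit$mechanisms, uncertain = hit$uncertain,
        rsid = hit$rsid, maf_text = hit$maf_text,
        maf_numeric = hit$maf_numeric, hpa_system = hit$hpa_system,
        provenance = hit$provenance, notes = hit$notes)
      if (!is.na(hit$gt_type) && hit$gt_type != "n/a")
        report$rationale <- c(report$rationale, sprintf(
          "Catalog: %s record, type %s GT (%s).", hit$category, hit$gt_type,
          hit$zygosity))
    }
  }
  structure(report, class = "impact_report")
}

#' @export
print.impact_report <- function(x, ...) {
  cat("<impact_report>", x$variant$label, "\n")
  cat("  domain:  ", ifelse(is.na(x$domain), "unassigned", x$domain), "\n")
  cat("  Grantham:", x$grantham, "\n")
  if (isTRUE(x$conservation$assessed))
    cat(sprintf("  conservation: identity %.2f (%s)\n",
                x$conservation$identity_fraction, x$conservation$label))
  else cat("  conservation: not assessed\n")
  if (isTRUE(x$structural$assessed))
    cat(sprintf("  structure: %d H-bond(s) lost, %d gained, %d clash(es)%s\n",
                x$structural$n_hbonds_lost, x$structural$n_hbonds_gained,
                x$structural$n_clashes,
                if (x$structural$disulfide_loss) ", disulfide lost" else ""))
  else cat("  structure: not assessed",
           if (isTRUE(x$structural$unmodelable))
             paste0(" (", x$structural$reason, ")"), "\n")
  for (r in x$rationale) cat("  -", r, "\n")
  invisible(x)
}

#' Serialise an impact report to JSON
#'
#' @param report an `impact_report`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "impact_report"))
  x <- unclass(report)
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null",
                          dataframe = "rows", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Render an impact report as Markdown
#'
#' @param report an `impact_report`.
#' @return character vector of Markdown lines.
#' @export
report_markdown <- function(report) {
  stopifnot(inherits(report, "impact_report"))
  c(paste("##", report$variant$label),
    "",
    paste("- Domain:", ifelse(is.na(report$domain), "unassigned",
                              report$domain)),
    paste("- Grantham score:", report$grantham),
    if (isTRUE(report$conservation$assessed))
      sprintf("- Conservation: identity %.2f (%s)",
              report$conservation$identity_fraction,
              report$conservation$label)
    else "- Conservation: not assessed",
    if (isTRUE(report$structural$assessed))
      sprintf("- Structure: %d H-bond(s) lost, %d gained, %d clash(es)",
              report$structural$n_hbonds_lost,
              report$structural$n_hbonds_gained, report$structural$n_clashes)
    else "- Structure: not assessed",
    "",
    vapply(report$rationale, function(r) paste("*", r), character(1),
           USE.NAMES = FALSE))
}
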