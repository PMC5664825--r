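#' Discriminate the retrogene among multiple genes in one element
#'
#' When two or three genes are annotated inside a single element, exactly one
#' is the retrogene. Genes with no parental sequence are excluded before the
#' rules apply (the caller passes `parent_status`); among the remainder the
#' rules are, in order: (1) if every gene has the same exon number, select
#' the gene with the longest exonic extent; (2) if exon numbers differ and
#' the gene containing the single longest exon has that exon more than
#' `exon_ratio`-fold larger than every exon of every neighbouring gene,
#' select it; (3) otherwise select the gene with the smallest exon number.
#' Ties are broken by longer CDS, then smaller start, so the selection does
#' not depend on input order.
#'
#' @param genes_in_element List of [gene_model()] objects sharing one element.
#' @param parent_status Optional named logical: does each gene have a
#'   verified parent? Genes marked `FALSE` are excluded before the rules.
#' @param exon_ratio Dominance factor for rule (2); default 1.5.
#' @return List with `selected` (gene id or `NA` when no gene is eligible),
#'   `rejected` (ids receiving `rejected_multi_gene_rule`) and `rule`
#'   (which branch decided).
#' @export
resolve_multi_gene_element <- function(genes_in_element, parent_status = NULL,
                                       exon_ratio = 1.5) {
  if (!length(genes_in_element)) stop("no genes supplied")
  genes <- genes_in_element[order(vapply(genes_in_element, `[[`, "", "gene_id"))]
  if (!is.null(parent_status)) {
    keep <- vapply(genes, function(g) isTRUE(parent_status[[g$gene_id]]), TRUE)
    genes <- genes[keep]
  }
  all_ids <- vapply(genes_in_element, `[[`, "", "gene_id")
  if (!length(genes))
    return(list(selected = NA_character_, rejected = character(), rule = "none_eligible"))
  if (length(genes) == 1L)
    return(list(selected = genes[[1L]]$gene_id,
                rejected = character(), rule = "single"))

  tie_break <- function(cands) {
    cds_len <- vapply(cands, function(g) if (is.na(g$cds)) 0L else nchar(g$cds), 0L)
    starts <- vapply(cands, function(g) g$span$start, 0L)
    cands[[order(-cds_len, starts)[1L]]]$gene_id
  }

  counts <- vapply(genes, n_exons, 0L)
  if (length(unique(counts)) == 1L) {
    ext <- vapply(genes, exonic_length, 0L)
    sel <- tie_break(genes[ext == max(ext)])
    rule <- "equal_counts_longest_exonic"
  } else {
    longest_each <- vapply(genes, function(g) max(g$exons$end - g$exons$start + 1L), 0L)
    dom <- which.max(longest_each)
    others_max <- max(longest_each[-dom])
    if (longest_each[dom] > exon_ratio * others_max) {
      sel <- genes[[dom]]$gene_id
      rule <- "dominant_exon"
    } else {
      sel <- tie_break(genes[counts == min(counts)])
      rule <- "smallest_exon_count"
    }
  }
  eligible_ids <- vapply(genes, `[[`, "", "gene_id")
  list(selected = sel, rejected = setdiff(eligible_ids, sel), rule = rule)
}

#' Reject orphan candidates
#'
#' A multi-exon candidate with no verified parental sequence is an unclear
#' case and is rejected. A single-exon candidate without a parent is kept as
#' a signature-only candidate when it carries at least one retro signature
#' (poly(A) or flanking direct repeats) and rejected otherwise.
#'
#' @param calls Call `data.frame` with columns `exon_count`, `parent_id`,
#'   `polyA`, `direct_repeats`, `verdict`.
#' @return `calls` with verdicts `"rejected_orphan_multiexon"` filled in and
#'   signature-retained rows marked `"candidate_signature_only"`.
#' @export
drop_orphan_multiexon <- function(calls) {
  if (!nrow(calls)) return(calls)
  open <- is.na(calls$verdict)
  orphan <- open & is.na(calls$parent_id)
  multi <- orphan & calls$exon_count >= 2L
  single <- orphan & calls$exon_count == 1L
  has_sig <- (!is.na(calls$polyA) & calls$polyA) |
    (!is.na(calls$direct_repeats) & calls$direct_repeats)
  calls$verdict[multi] <- "rejected_orphan_multiexon"
  calls$verdict[single & !has_sig] <- "rejected_orphan_multiexon"
  calls$verdict[single & has_sig] <- "candidate_signature_only"
  calls
}

#' Partition family genes into retro / ambiguous / normal
#'
#' The comparison class for retro calls: after excluding finalized
#' retrogenes, family genes substantially covered (`> overlap_threshold`) by
#' LTR-order repeat annotations are ambiguous (possible unresolved retro
#' context); the remainder are normal genes. The three sets are disjoint and
#' exhaustive over the input.
#'
#' @param family_genes List of [gene_model()] objects (the family under
#'   study).
#' @param calls Finalized call `data.frame` (`verdict == "retro"` rows define
#'   the retro set).
#' @param repeats [repeat_features()] table.
#' @param overlap_threshold LTR-coverage fraction above which a non-retro
#'   gene is ambiguous; default 0.8.
#' @return `data.frame` with columns `gene_id`, `class` in
#'   `{"retro", "ambiguous", "normal"}`.
#' @export
classify_normal_genes <- function(family_genes, calls, repeats,
                                  overlap_threshold = 0.8) {
  ids <- vapply(family_genes, `[[`, "", "gene_id")
  retro_ids <- if (nrow(calls)) calls$gene_id[calls$verdict == "retro"] else character()
  cls <- vapply(family_genes, function(g) {
    if (g$gene_id %in% retro_ids) return("retro")
    if (gene_repeat_coverage(g, repeats, "LTR") > overlap_threshold) return("ambiguous")
    "normal"
  }, "")
  data.frame(gene_id = ids, class = cls, row.names = NULL,
             stringsAsFactors = FALSE)[order(ids), , drop = FALSE]
}
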