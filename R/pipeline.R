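#' Pipeline configuration
#'
#' All decision thresholds of the detection and curation chain, pre-filled
#' with the defaults used throughout the analysis: parental query coverage
#' > 0.95, normal-set LTR overlap > 0.8, multi-gene exon dominance ratio
#' 1.5, TE-conflict coverage 0.5, and the two clock rates.
#'
#' @param parent_min_coverage Query coverage a parent alignment must exceed.
#' @param normal_overlap LTR-coverage fraction above which a non-retro
#'   family gene is ambiguous rather than normal.
#' @param exon_ratio Dominance factor of the multi-gene discrimination rule.
#' @param conflict_fraction Gene coverage by DNA/RC repeats above which a
#'   full-length candidate is rejected.
#' @param clock [clock_params()].
#' @param ks_cutoff Ks threshold for single-linkage duplication clustering.
#' @param signature_window Flank width (nt) for the retro-signature scan.
#' @param min_orf_nt Minimum internal ORF length for an autonomous element.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(parent_min_coverage = 0.95,
                            normal_overlap = 0.8,
                            exon_ratio = 1.5,
                            conflict_fraction = 0.5,
                            clock = clock_params(),
                            ks_cutoff = 0.1,
                            signature_window = 200L,
                            min_orf_nt = 900L) {
  structure(as.list(environment()), class = "pipeline_config")
}

# Ka/Ks of a candidate/parent CDS pair; sequences are globally aligned when
# lengths differ, gap columns removed, length trimmed to a codon multiple.
pair_rates_safe <- function(cds_a, cds_b) {
  res <- tryCatch({
    if (nchar(cds_a) != nchar(cds_b)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(cds_a), Biostrings::DNAString(cds_b),
        type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3),
        gapOpening = 5, gapExtension = 2)
      a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
      b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
      keep <- a != "-" & b != "-"
      a <- a[keep]; b <- b[keep]
      n <- (length(a) %/% 3L) * 3L
      cds_a <- paste(a[seq_len(n)], collapse = "")
      cds_b <- paste(b[seq_len(n)], collapse = "")
    }
    ng86_ka_ks(cds_a, cds_b)
  }, error = function(e) NULL)
  if (is.null(res)) list(Ka = NA_real_, Ks = NA_real_, ka_ks = NA_real_) else res
}

#' Run the full retroduplication discovery pipeline
#'
#' Executes the whole chain on an annotation bundle: full-length and
#' partial-LTR candidate detection, TE-conflict removal, parental-gene
#' verification, multi-gene-per-element discrimination, orphan filtering,
#' the retro/ambiguous/normal partition of the gene family, retro-signature
#' scanning, autonomy classification, LTR insertion dating and
#' duplication dating with single-linkage Ks clustering. Every stage's
#' in/out counts reconcile in the report.
#'
#' @param bundle An [annotation_bundle()].
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory; when given, the call table,
#'   partition, duplication table, clusters, resolved configuration and a
#'   JSON summary are written there (byte-identical for identical inputs).
#' @return An object of class `retro_report`: list with `calls`,
#'   `partition`, `partition_by_family`, `duplications`, `ks_clusters`,
#'   `counts`, `config`.
#' @export
run_retro_pipeline <- function(bundle, config = pipeline_config(),
                               outdir = NULL) {
  stopifnot(inherits(bundle, "annotation_bundle"),
            inherits(config, "pipeline_config"))
  genes <- bundle$genes
  seqs <- bundle$sequences

  full <- detect_candidates_full_ltr(genes, bundle$ltr_elements)
  partial <- detect_candidates_partial_ltr(genes, bundle$repeats)
  partial <- partial[!(partial$gene_id %in% full$gene_id), , drop = FALSE]

  full <- remove_te_conflicts(full, genes, bundle$repeats,
                              config$conflict_fraction)
  partial$verdict <- rep(NA_character_, nrow(partial))

  calls <- rbind(full, partial)
  if (nrow(calls)) {
    calls$seq_id <- vapply(calls$gene_id, function(g) genes[[g]]$span$seq_id, "")
    calls$start <- vapply(calls$gene_id, function(g) genes[[g]]$span$start, 1L)
    calls$end <- vapply(calls$gene_id, function(g) genes[[g]]$span$end, 1L)
    calls$exon_count <- vapply(calls$gene_id, function(g) n_exons(genes[[g]]), 1L)
  } else {
    calls$seq_id <- character(0); calls$start <- integer(0)
    calls$end <- integer(0); calls$exon_count <- integer(0)
  }
  calls$parent_id <- rep(NA_character_, nrow(calls))
  calls$parent_coverage <- rep(NA_real_, nrow(calls))
  calls$parent_identity <- rep(NA_real_, nrow(calls))
  calls$introns_lost <- rep(NA_integer_, nrow(calls))

  # parental verification: the search pool excludes every candidate; when
  # family labels exist, the pool is restricted to the candidate's family
  cand_ids <- calls$gene_id
  pool_all <- genes[setdiff(names(genes), cand_ids)]
  any_labels <- any(!vapply(genes, function(g) is.na(g$family), TRUE))
  for (i in seq_len(nrow(calls))) {
    if (!is.na(calls$verdict[i])) next
    g <- genes[[calls$gene_id[i]]]
    pool <- pool_all
    if (any_labels && !is.na(g$family))
      pool <- pool[vapply(pool, function(p) identical(p$family, g$family), TRUE)]
    pm <- find_parent(g, pool, config$parent_min_coverage)
    if (!is.null(pm)) {
      calls$parent_id[i] <- pm$parent_id
      calls$parent_coverage[i] <- pm$query_coverage
      calls$parent_identity[i] <- pm$identity
      calls$introns_lost[i] <- pm$introns_lost
    }
  }

  # multi-gene elements: exactly one retrogene per element among the
  # parent-verified genes
  open <- is.na(calls$verdict) & !is.na(calls$element_id)
  for (eid in unique(calls$element_id[open])) {
    rows <- which(open & calls$element_id == eid)
    if (length(rows) < 2L) next
    gs <- genes[calls$gene_id[rows]]
    status <- setNames(!is.na(calls$parent_id[rows]), calls$gene_id[rows])
    res <- resolve_multi_gene_element(gs, status, config$exon_ratio)
    rej <- which(calls$gene_id %in% res$rejected)
    calls$verdict[rej] <- "rejected_multi_gene_rule"
  }

  # retro signatures (needed by the orphan rule for single-exon orphans)
  calls$polyA <- rep(NA, nrow(calls))
  calls$direct_repeats <- rep(NA, nrow(calls))
  if (!is.null(seqs)) {
    for (i in seq_len(nrow(calls))) {
      if (!is.na(calls$verdict[i]) &&
          calls$verdict[i] != "candidate_signature_only") next
      g <- genes[[calls$gene_id[i]]]
      span <- if (!is.na(calls$element_id[i]))
        bundle$ltr_elements[[calls$element_id[i]]]$span else NULL
      sig <- retro_signature_scan(g, seqs, window = config$signature_window,
                                  span = span)
      calls$polyA[i] <- sig[["polyA"]]
      calls$direct_repeats[i] <- sig[["direct_repeats"]]
    }
  }

  calls <- drop_orphan_multiexon(calls)
  calls$verdict[is.na(calls$verdict) & !is.na(calls$parent_id)] <- "retro"

  # autonomy and insertion ages for calls inside full-length elements
  calls$autonomy <- rep("unknown", nrow(calls))
  calls$insertion_age_my <- rep(NA_real_, nrow(calls))
  if (length(bundle$ltr_elements)) {
    for (i in seq_len(nrow(calls))) {
      eid <- calls$element_id[i]
      if (is.na(eid)) next
      el <- bundle$ltr_elements[[eid]]
      in_el <- calls$gene_id[!is.na(calls$element_id) & calls$element_id == eid]
      excl <- lapply(in_el, function(g) genes[[g]]$span)
      calls$autonomy[i] <- classify_autonomy(el, seqs, exclude = excl,
                                             min_orf_nt = config$min_orf_nt)
      if (calls$verdict[i] %in% c("retro", "candidate_signature_only") &&
          !is.null(seqs)) {
        age <- suppressWarnings(ltr_insertion_time(el, seqs, config$clock))
        calls$insertion_age_my[i] <- as.numeric(age) / 1e6
      }
    }
  }

  # duplication dating of retro/parent pairs
  dup_rows <- which(calls$verdict == "retro")
  duplications <- do.call(rbind, lapply(dup_rows, function(i) {
    g <- genes[[calls$gene_id[i]]]
    p <- genes[[calls$parent_id[i]]]
    rates <- if (is.null(seqs) || is.na(g$cds) || is.na(p$cds))
      list(Ka = NA_real_, Ks = NA_real_, ka_ks = NA_real_)
    else pair_rates_safe(g$cds, p$cds)
    data.frame(gene_id = g$gene_id, parent_id = p$gene_id,
               family = if (is.na(g$family)) NA_character_ else g$family,
               ka = rates$Ka, ks = rates$Ks, ka_ks = rates$ka_ks,
               duplication_age_my = if (is.na(rates$Ks)) NA_real_ else
                 duplication_time(rates$Ks, config$clock) / 1e6,
               stringsAsFactors = FALSE)
  }))
  if (is.null(duplications))
    duplications <- data.frame(gene_id = character(), parent_id = character(),
                               family = character(), ka = numeric(),
                               ks = numeric(), ka_ks = numeric(),
                               duplication_age_my = numeric(),
                               stringsAsFactors = FALSE)

  # duplication-event clusters per family from the available Ks pairs
  ks_clusters <- local({
    dd <- duplications[!is.na(duplications$ks), , drop = FALSE]
    if (!nrow(dd)) return(data.frame(family = character(), cluster = integer(),
                                     n_genes = integer(), min_ks = numeric(),
                                     age_my = numeric()))
    out <- lapply(split(dd, ifelse(is.na(dd$family), "", dd$family)), function(d) {
      sl <- ks_single_linkage(
        data.frame(gene_a = d$gene_id, gene_b = d$parent_id, ks = d$ks),
        cutoff = config$ks_cutoff, params = config$clock)
      cbind(family = d$family[1L], sl$clusters)
    })
    res <- do.call(rbind, out); rownames(res) <- NULL
    res
  })

  # family partition: retro / ambiguous / normal
  fam_genes <- Filter(function(g) g$is_nlr, genes)
  if (!length(fam_genes)) fam_genes <- genes
  partition <- classify_normal_genes(fam_genes, calls, bundle$repeats,
                                     config$normal_overlap)
  fam_label <- vapply(partition$gene_id, function(g) {
    f <- genes[[g]]$family
    if (is.na(f)) "unlabelled" else f
  }, "")
  partition_by_family <- as.data.frame(table(family = fam_label,
                                             class = partition$class),
                                       stringsAsFactors = FALSE)

  counts <- list(
    n_genes = length(genes),
    n_family_genes = length(fam_genes),
    full_candidates = sum(calls$evidence == "full_length"),
    partial_candidates = sum(calls$evidence == "partial"),
    candidates_total = nrow(calls),
    rejected_te_conflict = sum(calls$verdict == "rejected_te_conflict"),
    rejected_multi_gene_rule = sum(calls$verdict == "rejected_multi_gene_rule"),
    rejected_orphan_multiexon = sum(calls$verdict == "rejected_orphan_multiexon"),
    candidate_signature_only = sum(calls$verdict == "candidate_signature_only"),
    retro_final = sum(calls$verdict == "retro"),
    partition = as.list(table(partition$class)))

  calls <- calls[order(calls$seq_id, calls$start), , drop = FALSE]
  rownames(calls) <- NULL
  report <- structure(list(calls = calls, partition = partition,
                           partition_by_family = partition_by_family,
                           duplications = duplications,
                           ks_clusters = ks_clusters,
                           counts = counts, config = config),
                      class = "retro_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.retro_report <- function(x, ...) {
  c0 <- x$counts
  cat("retro_report\n")
  cat(sprintf("  candidates: %d (full %d, partial %d)\n", c0$candidates_total,
              c0$full_candidates, c0$partial_candidates))
  cat(sprintf("  rejected: te_conflict %d, multi_gene %d, orphan %d\n",
              c0$rejected_te_conflict, c0$rejected_multi_gene_rule,
              c0$rejected_orphan_multiexon))
  cat(sprintf("  retro calls: %d (+%d signature-only candidates)\n",
              c0$retro_final, c0$candidate_signature_only))
  cat("  partition:", paste(names(c0$partition), unlist(c0$partition),
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a pipeline report to a directory
#'
#' Emits `calls.tsv`, `partition.tsv`, `duplications.tsv`,
#' `ks_clusters.tsv`, `summary.json` and the resolved configuration
#' `config.json`. Content is deterministic: no timestamps.
#'
#' @param report A `retro_report`.
#' @param outdir Output directory (created if needed).
#' @return Named vector of paths, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(calls = file.path(outdir, "calls.tsv"),
             partition = file.path(outdir, "partition.tsv"),
             duplications = file.path(outdir, "duplications.tsv"),
             clusters = file.path(outdir, "ks_clusters.tsv"),
             summary = file.path(outdir, "summary.json"),
             config = file.path(outdir, "config.json"))
  write_retro_calls(report$calls, paths[["calls"]])
  write.table(report$partition, paths[["partition"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$duplications, paths[["duplications"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$ks_clusters, paths[["clusters"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$counts, paths[["summary"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  cfg <- report$config
  cfg$clock <- unclass(cfg$clock)
  jsonlite::write_json(unclass(cfg), paths[["config"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Score a pipeline report against a simulation truth table
#'
#' Precision and recall of the final retro calls against the planted events,
#' and the verdict observed for each decoy class.
#'
#' @param report A `retro_report`.
#' @param truth Truth `data.frame` from [simulate_genome()].
#' @return List with `precision`, `recall`, `n_true`, `n_called`,
#'   `decoy_verdicts` (data.frame gene_id, decoy_class, verdict).
#' @export
score_against_truth <- function(report, truth) {
  pos <- truth$retro_gene_id[is.na(truth$decoy_class)]
  called <- report$calls$gene_id[report$calls$verdict == "retro"]
  tp <- length(intersect(called, pos))
  precision <- if (length(called)) tp / length(called) else NA_real_
  recall <- if (length(pos)) tp / length(pos) else NA_real_
  dec <- truth[!is.na(truth$decoy_class), c("retro_gene_id", "decoy_class")]
  dec$verdict <- vapply(dec$retro_gene_id, function(g) {
    v <- report$calls$verdict[report$calls$gene_id == g]
    if (length(v)) v[1L] else "not_called"
  }, "")
  names(dec)[1L] <- "gene_id"
  rownames(dec) <- NULL
  list(precision = precision, recall = recall, n_true = length(pos),
       n_called = length(called), decoy_verdicts = dec)
}
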