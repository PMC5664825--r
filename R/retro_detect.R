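#' Detect candidate retrogenes inside full-length LTR elements
#'
#' A gene becomes a full-length-pass candidate when its whole span (not just
#' its CDS) lies inside an element's span, in either orientation. A gene
#' contained in several (e.g. nested) elements is attached to the smallest
#' containing element.
#'
#' @param genes List of [gene_model()] objects.
#' @param ltr_elements List of [ltr_element()] objects.
#' @return `data.frame` with columns `gene_id`, `element_id`,
#'   `evidence = "full_length"`.
#' @export
detect_candidates_full_ltr <- function(genes, ltr_elements) {
  rows <- list()
  for (g in genes) {
    best <- NULL; best_w <- Inf
    for (e in ltr_elements) {
      if (gi_contains(e$span, g$span)) {
        w <- gi_width(e$span)
        if (w < best_w || (w == best_w && e$element_id < best$element_id)) {
          best <- e; best_w <- w
        }
      }
    }
    if (!is.null(best))
      rows[[g$gene_id]] <- data.frame(gene_id = g$gene_id,
                                      element_id = best$element_id,
                                      evidence = "full_length",
                                      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), element_id = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

# Merge overlapping or bookended intervals (matrix of start/end), sorted.
merge_runs <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  rs <- starts[1L]; re <- ends[1L]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= re + 1L) re <- max(re, ends[i])
    else { out_s <- c(out_s, rs); out_e <- c(out_e, re); rs <- starts[i]; re <- ends[i] }
  }
  cbind(start = c(out_s, rs), end = c(out_e, re))
}

#' Detect candidate retrogenes inside partial LTR fragments
#'
#' Rapid deletion degrades many elements below the full-length annotator's
#' radar; their remnants survive in the repeat table as LTR-order fragments.
#' A gene becomes a partial-pass candidate when the union of LTR-order
#' repeat fragments fully covers its span and the covering run extends
#' beyond the gene on both sides (an LTR fragment lies on each flank, the
#' direct-repeat geometry degraded by deletion).
#'
#' @param genes List of [gene_model()] objects.
#' @param repeats [repeat_features()] table.
#' @return `data.frame` with columns `gene_id`, `element_id` (`NA`),
#'   `evidence = "partial"`.
#' @export
detect_candidates_partial_ltr <- function(genes, repeats) {
  ltr <- repeats[repeats$order == "LTR", , drop = FALSE]
  rows <- list()
  if (nrow(ltr)) {
    runs_by_seq <- lapply(split(ltr, ltr$seq_id),
                          function(d) merge_runs(d$start, d$end))
    for (g in genes) {
      runs <- runs_by_seq[[g$span$seq_id]]
      if (is.null(runs)) next
      hit <- runs[, "start"] < g$span$start & runs[, "end"] > g$span$end
      if (any(hit))
        rows[[g$gene_id]] <- data.frame(gene_id = g$gene_id,
                                        element_id = NA_character_,
                                        evidence = "partial",
                                        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), element_id = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

# Fraction of a gene's span covered by the union of repeats of given orders.
gene_repeat_coverage <- function(gene, repeats, orders) {
  rr <- repeats[repeats$order %in% orders &
                  repeats$seq_id == gene$span$seq_id, , drop = FALSE]
  if (!nrow(rr)) return(0)
  runs <- merge_runs(rr$start, rr$end)
  s <- pmax(runs[, "start"], gene$span$start)
  e <- pmin(runs[, "end"], gene$span$end)
  sum(pmax(e - s + 1L, 0L)) / gi_width(gene$span)
}

#' Remove candidates in TE-conflicted elements
#'
#' When a candidate gene inside a predicted element is substantially covered
#' by repeats of another class (DNA transposons, Helitrons), the element
#' prediction is considered incorrect and the candidate is rejected. LINE
#' and SINE overlaps do not trigger rejection. Coverage is measured against
#' the union of DNA- and RC-order repeats over the gene span.
#'
#' @param candidates Candidate `data.frame` (full-length pass).
#' @param genes Named list of [gene_model()] objects.
#' @param repeats [repeat_features()] table.
#' @param conflict_threshold Gene-coverage fraction above which a candidate
#'   is rejected; default 0.5 so incidental few-bp overlaps do not reject.
#' @return The candidate table with a `verdict` column:
#'   `"rejected_te_conflict"` for dropped rows, `NA` otherwise.
#' @export
remove_te_conflicts <- function(candidates, genes, repeats,
                                conflict_threshold = 0.5) {
  if (!nrow(candidates)) {
    candidates$verdict <- character(0)
    return(candidates)
  }
  cov <- vapply(candidates$gene_id, function(gid)
    gene_repeat_coverage(genes[[gid]], repeats, c("DNA", "RC")), 0)
  candidates$verdict <- ifelse(cov > conflict_threshold,
                               "rejected_te_conflict", NA_character_)
  candidates
}

#' Find the parental gene of a retrogene candidate
#'
#' A retrocopy derives from its parent's spliced mRNA, so the candidate CDS
#' (query) is locally aligned against each pool gene's spliced CDS
#' (match +2, mismatch -3, gap open 5, gap extend 2). A valid parent must
#' cover more than `min_coverage` of the query, have at least two exons, and
#' have more exons than the candidate (intron loss). The best-scoring valid
#' match wins; ties broken by higher identity, then lexicographic id.
#'
#' @param candidate A [gene_model()] with a CDS.
#' @param gene_pool Named list of [gene_model()] objects to search; the
#'   candidate itself is always excluded.
#' @param min_coverage Query-coverage threshold (strict `>`), default 0.95.
#' @return A list (`parent_id`, `query_coverage`, `identity`,
#'   `parent_exon_count`, `candidate_exon_count`, `introns_lost`) or `NULL`.
#' @export
find_parent <- function(candidate, gene_pool, min_coverage = 0.95) {
  if (is.na(candidate$cds) || !nchar(candidate$cds)) return(NULL)
  qlen <- nchar(candidate$cds)
  q <- Biostrings::DNAString(candidate$cds)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  best <- NULL
  for (p in gene_pool) {
    if (identical(p$gene_id, candidate$gene_id)) next
    if (n_exons(p) < 2L || n_exons(p) <= n_exons(candidate)) next
    if (is.na(p$cds) || !nchar(p$cds)) next
    aln <- Biostrings::pairwiseAlignment(q, Biostrings::DNAString(p$cds),
                                         type = "local",
                                         substitutionMatrix = sm,
                                         gapOpening = 5, gapExtension = 2)
    apat <- as.character(Biostrings::alignedPattern(aln))
    coverage <- nchar(gsub("-", "", apat, fixed = TRUE)) / qlen
    if (coverage <= min_coverage) next
    identity <- Biostrings::pid(aln, type = "PID1") / 100
    cand <- list(parent_id = p$gene_id, query_coverage = coverage,
                 identity = identity, score = Biostrings::score(aln),
                 parent_exon_count = n_exons(p),
                 candidate_exon_count = n_exons(candidate),
                 introns_lost = n_exons(p) - n_exons(candidate))
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score && cand$identity > best$identity) ||
        (cand$score == best$score && cand$identity == best$identity &&
           cand$parent_id < best$parent_id)) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  best$score <- NULL
  best
}

# Longest ATG-initiated open reading frame (nt, incl. stop) in one strand.
longest_orf_one_strand <- function(chars) {
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  n <- length(chars)
  for (frame in 0:2) {
    idx <- seq.int(1L + frame, n - 2L, by = 3L)
    if (!length(idx)) next
    codons <- paste0(chars[idx], chars[idx + 1L], chars[idx + 2L])
    is_stop <- codons %in% stops
    is_atg <- codons == "ATG"
    seg_start <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(seg_start) && is_atg[i]) seg_start <- i
      if (is_stop[i]) {
        if (!is.na(seg_start)) best <- max(best, (i - seg_start + 1L) * 3L)
        seg_start <- NA_integer_
      }
    }
  }
  best
}

#' Classify an LTR element as autonomous or non-autonomous
#'
#' An autonomous element retains gag/pol coding potential; here that is an
#' ATG-initiated open reading frame of at least `min_orf_nt` nucleotides on
#' either strand of the internal region, excluding the span of the contained
#' candidate gene (the retrocopy itself must not count as element coding
#' potential). Without sequence the status is `"unknown"`.
#'
#' @param element An [ltr_element()].
#' @param sequences Named character vector of genome sequences, or `NULL`.
#' @param exclude Optional `genomic_interval`, or list of them (the spans of
#'   the contained genes), masked out before scanning.
#' @param min_orf_nt Minimum ORF length in nucleotides (default 900).
#' @return `"autonomous"`, `"non_autonomous"` or `"unknown"`.
#' @export
classify_autonomy <- function(element, sequences = NULL, exclude = NULL,
                              min_orf_nt = 900L) {
  if (is.null(sequences) || is.null(sequences[[element$span$seq_id]]))
    return("unknown")
  inside <- internal_region(element)
  chrom <- sequences[[element$span$seq_id]]
  if (inherits(exclude, "genomic_interval")) exclude <- list(exclude)
  segs <- list(c(inside$start, inside$end))
  for (ex in exclude) {
    if (ex$seq_id != inside$seq_id) next
    segs <- unlist(lapply(segs, function(seg) {
      if (ex$start > seg[2L] || ex$end < seg[1L]) return(list(seg))
      out <- list()
      if (ex$start > seg[1L]) out <- c(out, list(c(seg[1L], ex$start - 1L)))
      if (ex$end < seg[2L]) out <- c(out, list(c(ex$end + 1L, seg[2L])))
      out
    }), recursive = FALSE)
  }
  for (seg in segs) {
    if (seg[2L] - seg[1L] + 1L < min_orf_nt) next
    s <- toupper(substring(chrom, seg[1L], seg[2L]))
    fwd <- strsplit(s, "", fixed = TRUE)[[1L]]
    if (longest_orf_one_strand(fwd) >= min_orf_nt) return("autonomous")
    rev <- strsplit(revcomp(s), "", fixed = TRUE)[[1L]]
    if (longest_orf_one_strand(rev) >= min_orf_nt) return("autonomous")
  }
  "non_autonomous"
}

# Poly(A)/poly(T) run detector: a window of `run` bases whose first and last
# base match and with at most `max_mismatch` interior mismatches. Requiring
# matching edges keeps a 9-base run from qualifying through a flanking
# neighbour.
has_tail_run <- function(chars, base, run = 10L, max_mismatch = 1L) {
  n <- length(chars)
  if (n < run) return(FALSE)
  is_b <- chars == base
  cs <- cumsum(is_b)
  for (i in seq_len(n - run + 1L)) {
    hits <- cs[i + run - 1L] - if (i > 1L) cs[i - 1L] else 0L
    if (hits >= run - max_mismatch && is_b[i] && is_b[i + run - 1L]) return(TRUE)
  }
  FALSE
}

#' Scan an insertion for retroduplication signatures
#'
#' Looks for the two genomic hallmarks of a reverse-transcribed insertion:
#' a 3' poly(A) tract downstream of the CDS end (a run of >= `polyA_run`
#' adenines on the coding strand, one interior mismatch allowed) and a pair
#' of near-identical direct repeats flanking the insertion at mirrored
#' offsets (length `tsd_min`..`tsd_max`, identity >= `tsd_identity`,
#' mirrored offset slack `max_offset`). For a gene inside a full-length
#' element the insertion to scan is the element span (pass it as `span`);
#' its own paired LTRs plus any target-site duplication supply the
#' direct-repeat evidence. At a contig edge the windows are truncated and
#' each flag is computed on whatever side remains.
#'
#' @param gene A [gene_model()].
#' @param sequences Named character vector of genome sequences.
#' @param window Flank width scanned on each side (default 200 nt).
#' @param span Optional `genomic_interval` of the insertion (defaults to the
#'   gene span).
#' @param polyA_run Minimum poly(A) run length (default 10).
#' @param tsd_min,tsd_max Direct-repeat length range scanned (default 4-20).
#' @param tsd_identity Minimum identity between the two copies (default 0.9).
#' @param max_offset Maximum distance of each copy from the insertion
#'   boundary (default 5 nt).
#' @return Named logical vector `c(polyA =, direct_repeats =)`.
#' @export
retro_signature_scan <- function(gene, sequences, window = 200L, span = NULL,
                                 polyA_run = 10L, tsd_min = 4L, tsd_max = 20L,
                                 tsd_identity = 0.9, max_offset = 5L) {
  chrom <- sequences[[gene$span$seq_id]]
  if (is.null(chrom)) stop("sequence ", gene$span$seq_id, " not available")
  L <- nchar(chrom)
  if (is.null(span)) span <- gene$span

  # poly(A): downstream of the CDS end in transcription orientation
  if (gene$span$strand == "-") {
    lo <- max(1L, gene$span$start - window)
    flank <- if (gene$span$start > 1L) substring(chrom, lo, gene$span$start - 1L) else ""
    polyA <- nzchar(flank) &&
      has_tail_run(strsplit(toupper(flank), "", fixed = TRUE)[[1L]], "T", polyA_run)
  } else {
    hi <- min(L, gene$span$end + window)
    flank <- if (gene$span$end < L) substring(chrom, gene$span$end + 1L, hi) else ""
    polyA <- nzchar(flank) &&
      has_tail_run(strsplit(toupper(flank), "", fixed = TRUE)[[1L]], "A", polyA_run)
  }

  # direct repeats at mirrored offsets around the insertion span
  up_lo <- max(1L, span$start - window)
  up <- if (span$start > 1L) substring(chrom, up_lo, span$start - 1L) else ""
  dn_hi <- min(L, span$end + window)
  dn <- if (span$end < L) substring(chrom, span$end + 1L, dn_hi) else ""
  direct <- FALSE
  if (nchar(up) >= tsd_min && nchar(dn) >= tsd_min) {
    u <- strsplit(toupper(up), "", fixed = TRUE)[[1L]]
    d <- strsplit(toupper(dn), "", fixed = TRUE)[[1L]]
    nu <- length(u); ndn <- length(d)
    for (k in seq(min(tsd_max, nu, ndn), tsd_min)) {
      for (off in 0:max_offset) {
        if (nu < off + k || ndn < off + k) next
        left <- u[(nu - off - k + 1L):(nu - off)]
        right <- d[(off + 1L):(off + k)]
        if (mean(left == right) >= tsd_identity &&
            length(unique(right)) > 1L) {  # a homopolymer is not a TSD
          direct <- TRUE; break
        }
      }
      if (direct) break
    }
  }
  c(polyA = polyA, direct_repeats = direct)
}
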