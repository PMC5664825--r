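#' Molecular-clock rates
#'
#' Two neutral substitution rates are used: an intergenic rate applied to
#' the divergence between an element's paired LTRs (insertion age = K/2r,
#' r = 1.3e-8 substitutions/site/year, reflecting the higher substitution
#' rate of intergenic DNA) and a synonymous-site rate for dating gene
#' duplications (age = Ks/2r, r = 6.96e-9 substitutions per synonymous site
#' per year).
#'
#' @param r_intergenic Intergenic substitution rate (per site per year).
#' @param r_synonymous Synonymous substitution rate (per site per year).
#' @return An object of class `clock_params`.
#' @export
clock_params <- function(r_intergenic = 1.3e-8, r_synonymous = 6.96e-9) {
  stopifnot(r_intergenic > 0, r_synonymous > 0)
  structure(list(r_intergenic = r_intergenic, r_synonymous = r_synonymous),
            class = "clock_params")
}

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Kimura two-parameter distance
#'
#' `K = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` and `Q` the
#' transition and transversion proportions over ungapped, unambiguous sites
#' of an aligned pair. Columns where either sequence carries a gap or a
#' non-ACGT symbol are excluded from the site count.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length.
#' @return The distance `K` (substitutions/site), with attributes `sites`,
#'   `P` and `Q`.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("aligned sequences must have equal length")
  ok <- a %in% c(PURINES, PYRIMIDINES) & b %in% c(PURINES, PYRIMIDINES)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("no comparable (ungapped ACGT) sites")
  diff <- a != b
  ts <- diff & ((a %in% PURINES & b %in% PURINES) |
                  (a %in% PYRIMIDINES & b %in% PYRIMIDINES))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop(structure(class = c("retroscan_saturation", "error", "condition"),
                   list(message = sprintf(
                     "substitution saturation: P=%.3f, Q=%.3f leave the K2P log arguments non-positive",
                     P, Q), call = sys.call(-1L))))
  K <- -0.5 * log(w1) - 0.25 * log(w2)
  structure(K, sites = n, P = P, Q = Q)
}

#' Insertion age from an LTR-pair distance
#'
#' The two LTRs of an element are identical at integration and each then
#' accumulates substitutions at the neutral intergenic rate, so the age is
#' `K / (2 r)`.
#'
#' @param K Substitution distance between the 5' and 3' LTR.
#' @param params [clock_params()].
#' @return Age in years.
#' @export
insertion_age <- function(K, params = clock_params()) {
  stopifnot(K >= 0)
  as.numeric(K) / (2 * params$r_intergenic)
}

#' Date an LTR element's insertion
#'
#' Extracts the element's two LTR sequences from the genome, aligns them
#' globally with free end gaps, computes the Kimura two-parameter distance
#' over the ungapped columns and converts it to years with `K/2r`. A
#' saturated pair (log argument non-positive) yields `NA` with a warning:
#' the age is not estimable.
#'
#' @param element An [ltr_element()].
#' @param sequences Named character vector of genome sequences.
#' @param params [clock_params()].
#' @return Age in years (`NA` if not estimable), with attribute `K`.
#' @export
ltr_insertion_time <- function(element, sequences, params = clock_params()) {
  chrom <- sequences[[element$span$seq_id]]
  if (is.null(chrom)) stop("sequence ", element$span$seq_id, " not available")
  s5 <- substring(chrom, element$ltr5$start, element$ltr5$end)
  s3 <- substring(chrom, element$ltr3$start, element$ltr3$end)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(s5), Biostrings::DNAString(s3),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3),
    gapOpening = 5, gapExtension = 2)
  K <- tryCatch(
    k2p_distance(as.character(Biostrings::alignedPattern(aln)),
                 as.character(Biostrings::alignedSubject(aln))),
    retroscan_saturation = function(e) {
      warning("element ", element$element_id, ": age not estimable (", conditionMessage(e), ")")
      NA_real_
    })
  if (is.na(K)) return(structure(NA_real_, K = NA_real_))
  structure(insertion_age(K, params), K = as.numeric(K))
}

#' Duplication age from a synonymous distance
#'
#' @param ks Synonymous substitution distance (per synonymous site).
#' @param params [clock_params()].
#' @return Age in years.
#' @export
duplication_time <- function(ks, params = clock_params()) {
  stopifnot(all(ks >= 0, na.rm = TRUE))
  ks / (2 * params$r_synonymous)
}

# --- Nei-Gojobori (1986) ------------------------------------------------

gc_lookup <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

translate_codon <- function(codon, code) {
  aa <- code[codon]
  ifelse(is.na(aa), "X", aa)
}

# Fraction of the 9 single-base changes of a codon that are synonymous.
# Changes producing a stop codon count as nonsynonymous (the usual NG86
# implementation convention).
codon_syn_sites <- function(codon, code) {
  aa <- code[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  cv <- strsplit(codon, "")[[1L]]
  for (pos in 1:3) {
    for (b in setdiff(bases, cv[pos])) {
      alt <- cv; alt[pos] <- b
      alt_aa <- code[[paste(alt, collapse = "")]]
      if (!is.na(alt_aa) && alt_aa != "*" && alt_aa == aa) s <- s + 1 / 3
    }
  }
  s
}

# Average synonymous/nonsynonymous differences between two codons over all
# mutational pathways (orders of the differing positions). Pathways passing
# through a stop codon are excluded; if every pathway does, all are kept.
codon_pair_diffs <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(nd,
                  `1` = list(pos),
                  `2` = list(pos, rev(pos)),
                  `3` = list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
                             pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)]))
  path_counts <- function(order) {
    cur <- strsplit(c1, "")[[1L]]
    tgt <- strsplit(c2, "")[[1L]]
    sd <- 0; nd_ <- 0; through_stop <- FALSE
    for (p in order) {
      from <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      to <- paste(cur, collapse = "")
      aa_from <- code[[from]]; aa_to <- code[[to]]
      if (is.na(aa_to) || aa_to == "*") through_stop <- TRUE
      if (!is.na(aa_from) && !is.na(aa_to) && aa_from == aa_to && aa_to != "*")
        sd <- sd + 1
      else nd_ <- nd_ + 1
    }
    c(sd, nd_, through_stop)
  }
  res <- t(vapply(perms, path_counts, numeric(3)))
  keep <- res[, 3] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(res))
  c(sd = mean(res[keep, 1]), nd = mean(res[keep, 2]))
}

#' Nei-Gojobori (1986) synonymous and nonsynonymous rates
#'
#' Counts synonymous and nonsynonymous sites per codon (fraction of the nine
#' single-base changes that preserve the amino acid; changes to stop codons
#' count as nonsynonymous), averages the site totals over the two sequences,
#' averages observed differences over all mutational pathways between each
#' codon pair (pathways through stop codons excluded), and applies the
#' Jukes-Cantor correction `d = -3/4 log(1 - 4 p / 3)` to each class.
#'
#' @param cds_a,cds_b Aligned coding sequences: equal lengths, a multiple of
#'   3, no internal stop codons. Codons containing gaps or ambiguous bases
#'   are skipped.
#' @return An object of class `pairwise_rates`: a list with the site counts
#'   `S` and `N`, observed differences `Sd` and `Nd`, proportions `ps`,
#'   `pn`, corrected rates `Ks`, `Ka`, and the ratio `ka_ks` (`NA` when
#'   `Ks = 0`).
#' @export
ng86_ka_ks <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) stop("aligned CDS must have equal length")
  if (nchar(cds_a) %% 3L != 0L) stop("aligned CDS length must be a multiple of 3")
  code <- gc_lookup()
  n_codon <- nchar(cds_a) %/% 3L
  S1 <- 0; S2 <- 0; Sd <- 0; Nd <- 0; used <- 0L
  for (i in seq_len(n_codon)) {
    c1 <- substr(cds_a, 3L * i - 2L, 3L * i)
    c2 <- substr(cds_b, 3L * i - 2L, 3L * i)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    aa1 <- code[[c1]]; aa2 <- code[[c2]]
    if (aa1 == "*" || aa2 == "*") {
      if (i == n_codon) next  # terminal stop codon: not part of the coding comparison
      stop("internal stop codon at codon ", i)
    }
    used <- used + 1L
    S1 <- S1 + codon_syn_sites(c1, code)
    S2 <- S2 + codon_syn_sites(c2, code)
    d <- codon_pair_diffs(c1, c2, code)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  if (used == 0L) stop("no comparable codons")
  S <- (S1 + S2) / 2
  N <- 3 * used - S
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p, what) {
    if (p >= 0.75)
      stop(structure(class = c("retroscan_saturation", "error", "condition"),
                     list(message = paste0(what, " proportion ", signif(p, 3),
                                           " >= 3/4: Jukes-Cantor correction saturated"),
                          call = sys.call(-1L))))
    -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- jc(ps, "synonymous")
  Ka <- jc(pn, "nonsynonymous")
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 Ks = Ks, Ka = Ka,
                 ka_ks = if (Ks > 0) Ka / Ks else NA_real_),
            class = "pairwise_rates")
}

#' @export
print.pairwise_rates <- function(x, ...) {
  cat(sprintf("pairwise_rates: S=%.2f N=%.2f Sd=%.2f Nd=%.2f Ks=%.4f Ka=%.4f Ka/Ks=%s\n",
              x$S, x$N, x$Sd, x$Nd, x$Ks, x$Ka,
              if (is.na(x$ka_ks)) "NA" else sprintf("%.3f", x$ka_ks)))
  invisible(x)
}

#' Single-linkage clustering of paralog pairs by Ks
#'
#' Groups family members into duplication events: two genes fall into the
#' same event when they are connected by a chain of pairs with
#' `Ks <= cutoff` (single linkage, as computed by `hclust`). Pairs absent
#' from the table are treated as infinitely distant. Each multi-member
#' cluster is dated by its smallest Ks (the most recent duplication in the
#' chain).
#'
#' @param ks_pairs `data.frame` with columns `gene_a`, `gene_b`, `ks`.
#' @param cutoff Ks threshold joining two genes into one event.
#' @param gene_ids Optional full gene universe (adds singletons for genes
#'   with no pair in the table).
#' @param params [clock_params()] used to date each cluster.
#' @return A list with `membership` (data.frame gene_id, cluster) and
#'   `clusters` (data.frame cluster, n_genes, min_ks, age_my).
#' @export
ks_single_linkage <- function(ks_pairs, cutoff, gene_ids = NULL,
                              params = clock_params()) {
  stopifnot(cutoff >= 0)
  ids <- sort(unique(c(gene_ids, ks_pairs$gene_a, ks_pairs$gene_b)))
  n <- length(ids)
  if (n == 0L)
    return(list(membership = data.frame(gene_id = character(), cluster = integer()),
                clusters = data.frame(cluster = integer(), n_genes = integer(),
                                      min_ks = numeric(), age_my = numeric())))
  big <- max(c(ks_pairs$ks, cutoff), na.rm = TRUE) * 2 + 1
  dm <- matrix(big, n, n, dimnames = list(ids, ids))
  diag(dm) <- 0
  for (i in seq_len(nrow(ks_pairs))) {
    a <- ks_pairs$gene_a[i]; b <- ks_pairs$gene_b[i]; k <- ks_pairs$ks[i]
    if (is.na(k)) next
    dm[a, b] <- min(dm[a, b], k)
    dm[b, a] <- dm[a, b]
  }
  cl <- if (n == 1L) setNames(1L, ids) else
    cutree(hclust(as.dist(dm), method = "single"), h = cutoff)
  membership <- data.frame(gene_id = ids, cluster = as.integer(cl[ids]),
                           row.names = NULL, stringsAsFactors = FALSE)
  clusters <- do.call(rbind, lapply(sort(unique(membership$cluster)), function(k) {
    members <- membership$gene_id[membership$cluster == k]
    inpair <- ks_pairs$gene_a %in% members & ks_pairs$gene_b %in% members &
      !is.na(ks_pairs$ks) & ks_pairs$ks <= cutoff
    mk <- if (any(inpair)) min(ks_pairs$ks[inpair]) else NA_real_
    data.frame(cluster = k, n_genes = length(members), min_ks = mk,
               age_my = if (is.na(mk)) NA_real_ else duplication_time(mk, params) / 1e6)
  }))
  list(membership = membership, clusters = clusters)
}
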