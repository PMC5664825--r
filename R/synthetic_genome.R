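#' Simulation configuration
#'
#' Parameters of the synthetic genome: chromosome layout, parent-gene
#' structure, retroduplication events (ages, autonomy, partial-element
#' degradation), the retro signatures planted at each insertion, decoy
#' classes exercising every curation rule, and the mutation model. The
#' defaults describe a compact genome that carries the same structures the
#' detection pipeline assumes in real data: multi-exon parents, intron-less
#' retrocopies between paired LTRs, solo/partial LTR fragments, DNA-transposon
#' decoys, poly(A) tails and target-site duplications.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome (nt).
#' @param n_parent_genes Number of ordinary multi-exon parent genes.
#' @param exons_per_parent Range (lo, hi) of exons per parent.
#' @param exon_codons Range of codons per exon.
#' @param intron_range Range of intron lengths (nt; introns open GT, close AG).
#' @param n_retro_events Number of planted retroduplication events (in
#'   addition to the multi-gene-element events implied by `n_decoys`).
#' @param fraction_autonomous Fraction of events whose element keeps a long
#'   internal ORF (gag/pol-like coding potential).
#' @param fraction_partial_elements Fraction of events whose element is
#'   degraded to overlapping LTR fragments (only the repeat table sees it).
#' @param target_ages_my Insertion ages (million years) recycled over events;
#'   each LTR of an element evolves independently at the intergenic rate so
#'   the expected LTR-pair distance is `2 r t`.
#' @param mutation_rate Per-site substitutions applied to each retrocopy CDS
#'   (divergence accumulated since duplication).
#' @param ts_tv_ratio Transition:transversion ratio of the mutation model.
#' @param polyA_length Length of the poly(A) tract appended 3' of each
#'   retrocopy.
#' @param tsd_length Length of the target-site duplication flanking each
#'   element.
#' @param ltr_length LTR length (nt).
#' @param orf_length Length of the pol-like ORF in autonomous elements (nt).
#' @param n_decoys Named list: `te_conflict` (elements whose gene is
#'   substantially covered by a DNA/hAT annotation), `orphan_multiexon`
#'   (multi-exon in-element genes with no parent anywhere),
#'   `multi_gene_element` (two genes in one element; the three discrimination
#'   branches are cycled), `solo_ltr` (gene-less LTR fragments).
#' @param families Family labels cycled over parent genes.
#' @param gap_range Intergenic gap range between planted blocks (nt).
#' @param spacer_range Spacer range inside element internal regions (nt).
#' @param seed Integer seed; the whole genome is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chromosome_length = 300000L,
                       n_parent_genes = 24L,
                       exons_per_parent = c(2L, 8L),
                       exon_codons = c(50L, 150L),
                       intron_range = c(80L, 300L),
                       n_retro_events = 20L,
                       fraction_autonomous = 0.5,
                       fraction_partial_elements = 0.2,
                       target_ages_my = c(0.5, 1, 1.5),
                       mutation_rate = 0.01,
                       ts_tv_ratio = 2,
                       polyA_length = 15L,
                       tsd_length = 5L,
                       ltr_length = 1000L,
                       orf_length = 3000L,
                       n_decoys = list(te_conflict = 1L, orphan_multiexon = 1L,
                                       multi_gene_element = 3L, solo_ltr = 2L),
                       families = c("CNL-G1", "CNL-G2"),
                       gap_range = c(500L, 2000L),
                       spacer_range = c(200L, 500L),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chromosomes >= 1L, cfg$chromosome_length > 0L,
            cfg$n_parent_genes >= 0L, cfg$n_retro_events >= 0L,
            cfg$fraction_autonomous >= 0, cfg$fraction_autonomous <= 1,
            cfg$fraction_partial_elements >= 0, cfg$fraction_partial_elements <= 1,
            all(cfg$target_ages_my >= 0), cfg$mutation_rate >= 0,
            cfg$ts_tv_ratio > 0, cfg$polyA_length >= 0L, cfg$tsd_length >= 0L,
            cfg$ltr_length > 0L)
  structure(cfg, class = "sim_config")
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# ATG + random non-stop codons + TAA; no internal stop by construction.
rand_cds <- function(n_codons) {
  stopifnot(n_codons >= 3L)
  all_codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  sense <- setdiff(all_codons, STOP_CODONS)
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""), "TAA")
}

rand_intron <- function(range) {
  n <- sample(seq(range[1L], range[2L]), 1L)
  paste0("GT", rand_dna(max(n - 4L, 0L)), "AG")
}

rand_between <- function(range) sample(seq(range[1L], range[2L]), 1L)

# K2P per-site outcome probabilities at branch length d (expected
# substitutions/site) and transition:transversion ratio R.
k2p_site_probs <- function(d, ts_tv_ratio) {
  R <- ts_tv_ratio
  bt <- d / (2 * (R + 1))
  at <- d * R / (R + 1)
  e4b <- exp(-4 * bt)
  e2ab <- exp(-2 * (at + bt))
  p_ts <- 0.25 + 0.25 * e4b - 0.5 * e2ab
  p_tv_each <- 0.25 * (1 - e4b)
  c(same = 1 - p_ts - 2 * p_tv_each, ts = p_ts, tv_each = p_tv_each)
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

#' Evolve a sequence under a Kimura two-parameter substitution model
#'
#' Each site independently draws its end state from the exact K2P transition
#' probabilities at branch length `rate` (expected substitutions per site)
#' with the given transition:transversion ratio, so distance estimators see
#' an unbiased process including multiple-hit behaviour.
#'
#' @param seq Nucleotide string.
#' @param rate Expected substitutions per site along the branch.
#' @param ts_tv_ratio Transition:transversion ratio (default 2).
#' @param seed Optional seed applied locally; by default the current RNG
#'   stream is used (callers seed once for a whole simulation).
#' @return The mutated sequence string.
#' @export
evolve_sequence <- function(seq, rate, ts_tv_ratio = 2, seed = NULL) {
  stopifnot(rate >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (rate == 0) return(seq)
  x <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  pr <- k2p_site_probs(rate, ts_tv_ratio)
  u <- runif(length(x))
  acgt <- x %in% BASES
  do_ts <- acgt & u < pr[["ts"]]
  do_tv1 <- acgt & u >= pr[["ts"]] & u < pr[["ts"]] + pr[["tv_each"]]
  do_tv2 <- acgt & u >= pr[["ts"]] + pr[["tv_each"]] &
    u < pr[["ts"]] + 2 * pr[["tv_each"]]
  x[do_ts] <- TRANSITION_OF[x[do_ts]]
  x[do_tv1] <- vapply(x[do_tv1], function(b) TRANSVERSIONS_OF[[b]][1L], "")
  x[do_tv2] <- vapply(x[do_tv2], function(b) TRANSVERSIONS_OF[[b]][2L], "")
  paste(x, collapse = "")
}

# --- block builders (all coordinates relative, 1-based) -----------------

new_block <- function(seq) {
  list(seq = seq, genes = list(), repeats = NULL, elements = list(),
       truth = NULL)
}

block_parent_gene <- function(gid, exon_codons_vec, family, cfg) {
  cds <- rand_cds(sum(exon_codons_vec))
  parts <- character(); exs <- integer(); exe <- integer()
  pos <- 0L; cpos <- 0L
  for (i in seq_along(exon_codons_vec)) {
    w <- 3L * exon_codons_vec[i]
    exon_seq <- substr(cds, cpos + 1L, cpos + w)
    cpos <- cpos + w
    parts <- c(parts, exon_seq)
    exs <- c(exs, pos + 1L); exe <- c(exe, pos + w)
    pos <- pos + w
    if (i < length(exon_codons_vec)) {
      intr <- rand_intron(cfg$intron_range)
      parts <- c(parts, intr)
      pos <- pos + nchar(intr)
    }
  }
  b <- new_block(paste(parts, collapse = ""))
  b$genes[[gid]] <- list(gene_id = gid, start = 1L, end = pos, strand = "+",
                         exons = data.frame(start = exs, end = exe),
                         family = family)
  b$cds <- cds
  b
}

# An in-element gene chunk: CDS (possibly split into exons with plain random
# introns), optionally reverse-complemented with its poly(A).
gene_chunk <- function(gid, cds, strand, family, cfg, n_exons = 1L,
                       exon_nt = NULL, polyA = TRUE) {
  tail_seq <- if (polyA) paste(rep("A", cfg$polyA_length), collapse = "") else ""
  if (n_exons == 1L) {
    if (strand == "+") {
      seq <- paste0(cds, tail_seq)
      exons <- data.frame(start = 1L, end = nchar(cds))
      gstart <- 1L; gend <- nchar(cds)
    } else {
      seq <- revcomp(paste0(cds, tail_seq))
      gstart <- nchar(tail_seq) + 1L
      gend <- nchar(seq)
      exons <- data.frame(start = gstart, end = gend)
    }
  } else {
    stopifnot(strand == "+", !is.null(exon_nt), sum(exon_nt) == nchar(cds))
    parts <- character(); exs <- integer(); exe <- integer()
    pos <- 0L; cpos <- 0L
    for (i in seq_along(exon_nt)) {
      exon_seq <- substr(cds, cpos + 1L, cpos + exon_nt[i]); cpos <- cpos + exon_nt[i]
      parts <- c(parts, exon_seq)
      exs <- c(exs, pos + 1L); exe <- c(exe, pos + exon_nt[i]); pos <- pos + exon_nt[i]
      if (i < length(exon_nt)) {
        intr <- rand_intron(cfg$intron_range)
        parts <- c(parts, intr); pos <- pos + nchar(intr)
      }
    }
    seq <- paste0(paste(parts, collapse = ""), tail_seq)
    gstart <- 1L; gend <- pos
    exons <- data.frame(start = exs, end = exe)
  }
  list(seq = seq, gene = list(gene_id = gid, start = gstart, end = gend,
                              strand = strand, exons = exons, family = family))
}

rand_tsd <- function(n) {
  if (n == 0L) return("")
  repeat {
    t <- rand_dna(n)
    if (length(unique(strsplit(t, "")[[1L]])) > 1L) return(t)
  }
}

# Element block: TSD + 5'LTR + internal(spacer, gene chunk(s), [orf], spacer)
# + 3'LTR + TSD. Returns relative coordinates for everything.
block_element <- function(eid, chunks, age_my, autonomous, partial, cfg,
                          params = clock_params()) {
  ltr0 <- rand_dna(cfg$ltr_length)
  d <- params$r_intergenic * age_my * 1e6
  ltr5 <- evolve_sequence(ltr0, d, cfg$ts_tv_ratio)
  ltr3 <- evolve_sequence(ltr0, d, cfg$ts_tv_ratio)
  tsd <- rand_tsd(cfg$tsd_length)

  inner_parts <- list(rand_dna(rand_between(cfg$spacer_range)))
  gene_offsets <- list()
  pos <- nchar(inner_parts[[1L]])
  for (ch in chunks) {
    gene_offsets[[ch$gene$gene_id]] <- list(chunk = ch, offset = pos)
    inner_parts <- c(inner_parts, ch$seq)
    pos <- pos + nchar(ch$seq)
    sp <- rand_dna(rand_between(cfg$spacer_range))
    inner_parts <- c(inner_parts, sp)
    pos <- pos + nchar(sp)
  }
  if (autonomous) {
    orf <- rand_cds(cfg$orf_length %/% 3L)
    inner_parts <- c(inner_parts, orf, rand_dna(rand_between(cfg$spacer_range)))
  }
  internal <- paste(unlist(inner_parts), collapse = "")
  elem_seq <- paste0(ltr5, internal, ltr3)
  seq <- paste0(tsd, elem_seq, tsd)

  t0 <- nchar(tsd)
  ltr5_s <- t0 + 1L; ltr5_e <- t0 + nchar(ltr5)
  int_s <- ltr5_e + 1L
  ltr3_s <- int_s + nchar(internal); ltr3_e <- ltr3_s + nchar(ltr3) - 1L
  b <- new_block(seq)
  b$elements[[eid]] <- list(
    element_id = eid, ltr5_s = ltr5_s, ltr5_e = ltr5_e,
    ltr3_s = ltr3_s, ltr3_e = ltr3_e,
    tsd_1 = if (nchar(tsd)) c(1L, t0) else NULL,
    tsd_2 = if (nchar(tsd)) c(ltr3_e + 1L, ltr3_e + t0) else NULL,
    emitted = !partial)
  for (gid in names(gene_offsets)) {
    go <- gene_offsets[[gid]]
    g <- go$chunk$gene
    shift <- int_s - 1L + go$offset
    g$start <- g$start + shift; g$end <- g$end + shift
    g$exons$start <- g$exons$start + shift; g$exons$end <- g$exons$end + shift
    b$genes[[gid]] <- g
  }
  elem_w <- ltr3_e - ltr5_s + 1L
  if (partial) {
    mid <- ltr5_s + elem_w %/% 2L
    b$repeats <- data.frame(start = c(ltr5_s, mid - 100L),
                            end = c(mid + 100L, ltr3_e),
                            name = "Gypsy-frag", class = "LTR/Gypsy",
                            stringsAsFactors = FALSE)
  } else {
    b$repeats <- data.frame(start = c(ltr5_s, int_s, ltr3_s),
                            end = c(ltr5_e, ltr3_s - 1L, ltr3_e),
                            name = c("Gypsy-LTR", "Gypsy-int", "Gypsy-LTR"),
                            class = "LTR/Gypsy", stringsAsFactors = FALSE)
  }
  b
}

offset_block <- function(b, seq_id, at) {
  # at = 0-based offset of the block within the chromosome
  for (gid in names(b$genes)) {
    g <- b$genes[[gid]]
    g$seq_id <- seq_id
    g$start <- g$start + at; g$end <- g$end + at
    g$exons$start <- g$exons$start + at; g$exons$end <- g$exons$end + at
    b$genes[[gid]] <- g
  }
  for (eid in names(b$elements)) {
    e <- b$elements[[eid]]
    e$seq_id <- seq_id
    for (f in c("ltr5_s", "ltr5_e", "ltr3_s", "ltr3_e")) e[[f]] <- e[[f]] + at
    if (!is.null(e$tsd_1)) { e$tsd_1 <- e$tsd_1 + at; e$tsd_2 <- e$tsd_2 + at }
    b$elements[[eid]] <- e
  }
  if (!is.null(b$repeats)) {
    b$repeats$seq_id <- seq_id
    b$repeats$start <- b$repeats$start + at
    b$repeats$end <- b$repeats$end + at
  }
  b
}

#' Generate a synthetic genome with a planted truth table
#'
#' Builds random-background chromosomes carrying multi-exon parent genes,
#' retroduplication events (intron-less copies of parent CDS with poly(A)
#' tails and target-site duplications, inserted between LTR pairs whose
#' divergence matches each event's target age), decoy structures exercising
#' every curation rule, and solo LTR fragments; and emits the matching
#' annotations exactly as the upstream annotators would see them (gene
#' models, a repeat table, full-length element records) plus a truth table
#' for recovery scoring. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `retro_sim`: list with `bundle`
#'   (an [annotation_bundle()]), `truth` (`data.frame`) and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  cfg <- config
  blocks <- list()
  truth <- list()
  parent_cds <- list()
  parent_fam <- list()

  fam_of <- function(i) cfg$families[((i - 1L) %% length(cfg$families)) + 1L]

  # ordinary parents
  for (i in seq_len(cfg$n_parent_genes)) {
    gid <- sprintf("P%03d", i)
    nex <- sample(seq(cfg$exons_per_parent[1L], cfg$exons_per_parent[2L]), 1L)
    codons <- sample(seq(cfg$exon_codons[1L], cfg$exon_codons[2L]), nex, replace = TRUE)
    b <- block_parent_gene(gid, codons, fam_of(i), cfg)
    parent_cds[[gid]] <- b$cds
    parent_fam[[gid]] <- fam_of(i)
    blocks[[length(blocks) + 1L]] <- b
  }

  n_mg <- if (is.null(cfg$n_decoys$multi_gene_element)) 0L else cfg$n_decoys$multi_gene_element
  # dedicated parents for the multi-gene-element branches
  mg_branches <- c("equal_counts", "dominant_exon", "smallest_count")
  mg_specs <- list(
    equal_counts  = list(retro = list(codons = 450L, exons = 4L),
                         decoy = list(codons = 300L, exons = 3L, split = 1L)),
    dominant_exon = list(retro = list(codons = 500L, exons = 4L),
                         decoy = list(codons = 240L, exons = 4L, split = 2L)),
    smallest_count = list(retro = list(codons = 400L, exons = 4L),
                          decoy = list(codons = 450L, exons = 5L, split = 3L)))
  mg_parent_ids <- list()
  if (n_mg > 0L) {
    for (j in seq_len(n_mg)) {
      branch <- mg_branches[((j - 1L) %% 3L) + 1L]
      spec <- mg_specs[[branch]]
      fam <- fam_of(j)
      ids <- c(retro = sprintf("PMR%02d", j), decoy = sprintf("PMD%02d", j))
      for (role in c("retro", "decoy")) {
        nc <- spec[[role]]$codons; nex <- spec[[role]]$exons
        per <- rep(nc %/% nex, nex); per[nex] <- per[nex] + nc %% nex
        b <- block_parent_gene(ids[[role]], per, fam, cfg)
        parent_cds[[ids[[role]]]] <- b$cds
        parent_fam[[ids[[role]]]] <- fam
        blocks[[length(blocks) + 1L]] <- b
      }
      mg_parent_ids[[j]] <- ids
    }
  }

  # regular retro events
  n_ev <- cfg$n_retro_events
  ages <- rep_len(cfg$target_ages_my, max(n_ev, 1L))
  autonomous <- rep(FALSE, n_ev)
  if (n_ev > 0L && cfg$fraction_autonomous > 0)
    autonomous[sample(n_ev, round(cfg$fraction_autonomous * n_ev))] <- TRUE
  partial <- rep(FALSE, n_ev)
  if (n_ev > 0L && cfg$fraction_partial_elements > 0)
    partial[sample(n_ev, round(cfg$fraction_partial_elements * n_ev))] <- TRUE
  reg_parents <- if (cfg$n_parent_genes > 0L)
    sprintf("P%03d", ((seq_len(max(n_ev, 1L)) - 1L) %% cfg$n_parent_genes) + 1L)
  else character()
  for (i in seq_len(n_ev)) {
    pid <- reg_parents[i]
    gid <- sprintf("R%03d", i)
    eid <- sprintf("E%03d", i)
    strand <- sample(c("+", "-"), 1L, prob = c(0.75, 0.25))
    cds_m <- evolve_sequence(parent_cds[[pid]], cfg$mutation_rate, cfg$ts_tv_ratio)
    ch <- gene_chunk(gid, cds_m, strand, parent_fam[[pid]], cfg)
    blocks[[length(blocks) + 1L]] <-
      block_element(eid, list(ch), ages[i], autonomous[i], partial[i], cfg)
    truth[[length(truth) + 1L]] <- data.frame(
      event_id = sprintf("ev%03d", i), parent_gene_id = pid, retro_gene_id = gid,
      element_id = eid, introns_lost = NA_integer_,  # filled from parent below
      autonomy = if (autonomous[i]) "autonomous" else "non_autonomous",
      planted_age_my = ages[i], polyA = TRUE, direct_repeats = TRUE,
      expected_evidence = if (partial[i]) "partial" else "full_length",
      decoy_class = NA_character_, stringsAsFactors = FALSE)
  }

  # multi-gene elements: a true retro plus a parented decoy in one element
  for (j in seq_len(n_mg)) {
    branch <- mg_branches[((j - 1L) %% 3L) + 1L]
    spec <- mg_specs[[branch]]
    ids <- mg_parent_ids[[j]]
    gid_r <- sprintf("RM%02d", j); gid_d <- sprintf("DM%02d", j)
    eid <- sprintf("EM%02d", j)
    fam <- parent_fam[[ids[["retro"]]]]
    ch_r <- gene_chunk(gid_r, parent_cds[[ids[["retro"]]]], "+", fam, cfg)
    dec_cds <- parent_cds[[ids[["decoy"]]]]
    nsplit <- spec$decoy$split
    exon_nt <- if (branch == "smallest_count") {
      w <- nchar(dec_cds); c(900L, rep((w - 900L) %/% 2L, 2L)[1L], w - 900L - (w - 900L) %/% 2L)
    } else if (nsplit == 1L) nchar(dec_cds)
    else { w <- nchar(dec_cds); per <- rep(w %/% nsplit, nsplit); per[nsplit] <- per[nsplit] + w %% nsplit; per }
    ch_d <- gene_chunk(gid_d, dec_cds, "+", fam, cfg, n_exons = nsplit,
                       exon_nt = exon_nt, polyA = FALSE)
    blocks[[length(blocks) + 1L]] <-
      block_element(eid, list(ch_r, ch_d), cfg$target_ages_my[1L], FALSE, FALSE, cfg)
    truth[[length(truth) + 1L]] <- data.frame(
      event_id = sprintf("evM%02d", j), parent_gene_id = ids[["retro"]],
      retro_gene_id = gid_r, element_id = eid, introns_lost = NA_integer_,
      autonomy = "non_autonomous", planted_age_my = cfg$target_ages_my[1L],
      polyA = TRUE, direct_repeats = TRUE, expected_evidence = "full_length",
      decoy_class = NA_character_, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      event_id = sprintf("evMd%02d", j), parent_gene_id = ids[["decoy"]],
      retro_gene_id = gid_d, element_id = eid, introns_lost = NA_integer_,
      autonomy = "non_autonomous", planted_age_my = cfg$target_ages_my[1L],
      polyA = FALSE, direct_repeats = TRUE, expected_evidence = "full_length",
      decoy_class = "multi_gene_element", stringsAsFactors = FALSE)
  }

  # TE-conflict decoys: believable retrocopy, but the gene is covered by a
  # DNA-transposon annotation, so the element prediction is distrusted
  n_te <- if (is.null(cfg$n_decoys$te_conflict)) 0L else cfg$n_decoys$te_conflict
  for (j in seq_len(n_te)) {
    pid <- sprintf("P%03d", ((j - 1L) %% max(cfg$n_parent_genes, 1L)) + 1L)
    gid <- sprintf("DT%02d", j); eid <- sprintf("ET%02d", j)
    ch <- gene_chunk(gid, parent_cds[[pid]], "+", parent_fam[[pid]], cfg)
    b <- block_element(eid, list(ch), cfg$target_ages_my[1L], FALSE, FALSE, cfg)
    g <- b$genes[[gid]]
    w <- g$end - g$start + 1L
    b$repeats <- rbind(b$repeats, data.frame(
      start = g$start, end = g$start + as.integer(0.8 * w) - 1L,
      name = "hAT-1", class = "DNA/hAT", stringsAsFactors = FALSE))
    blocks[[length(blocks) + 1L]] <- b
    truth[[length(truth) + 1L]] <- data.frame(
      event_id = sprintf("evT%02d", j), parent_gene_id = pid, retro_gene_id = gid,
      element_id = eid, introns_lost = NA_integer_, autonomy = "non_autonomous",
      planted_age_my = cfg$target_ages_my[1L], polyA = TRUE, direct_repeats = TRUE,
      expected_evidence = "full_length", decoy_class = "te_conflict",
      stringsAsFactors = FALSE)
  }

  # orphan multi-exon decoys: in-element multi-exon gene with no parent
  n_or <- if (is.null(cfg$n_decoys$orphan_multiexon)) 0L else cfg$n_decoys$orphan_multiexon
  for (j in seq_len(n_or)) {
    gid <- sprintf("DO%02d", j); eid <- sprintf("EO%02d", j)
    cds <- rand_cds(300L)
    ch <- gene_chunk(gid, cds, "+", cfg$families[1L], cfg, n_exons = 3L,
                     exon_nt = c(300L, 300L, 300L), polyA = FALSE)
    blocks[[length(blocks) + 1L]] <-
      block_element(eid, list(ch), cfg$target_ages_my[1L], FALSE, FALSE, cfg)
    truth[[length(truth) + 1L]] <- data.frame(
      event_id = sprintf("evO%02d", j), parent_gene_id = NA_character_,
      retro_gene_id = gid, element_id = eid, introns_lost = NA_integer_,
      autonomy = "non_autonomous", planted_age_my = cfg$target_ages_my[1L],
      polyA = FALSE, direct_repeats = TRUE, expected_evidence = "full_length",
      decoy_class = "orphan_multiexon", stringsAsFactors = FALSE)
  }

  # solo LTR fragments: annotation noise without genes
  n_solo <- if (is.null(cfg$n_decoys$solo_ltr)) 0L else cfg$n_decoys$solo_ltr
  for (j in seq_len(n_solo)) {
    b <- new_block(rand_dna(cfg$ltr_length))
    b$repeats <- data.frame(start = 1L, end = cfg$ltr_length,
                            name = "Gypsy-solo", class = "LTR/Gypsy",
                            stringsAsFactors = FALSE)
    blocks[[length(blocks) + 1L]] <- b
  }

  # --- placement --------------------------------------------------------
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
  parts <- setNames(rep(list(character()), cfg$n_chromosomes), chrom_names)
  cursor <- setNames(rep(0L, cfg$n_chromosomes), chrom_names)
  placed <- list()
  ci <- 0L
  for (b in blocks) {
    ci <- (ci %% cfg$n_chromosomes) + 1L
    cn <- chrom_names[ci]
    gap <- rand_between(cfg$gap_range)
    need <- gap + nchar(b$seq)
    if (cursor[cn] + need > cfg$chromosome_length)
      stop("simulated features do not fit: need ", need, " nt on ", cn,
           " but only ", cfg$chromosome_length - cursor[cn],
           " remain; increase chromosome_length or reduce event counts")
    parts[[cn]] <- c(parts[[cn]], rand_dna(gap), b$seq)
    placed[[length(placed) + 1L]] <- offset_block(b, cn, cursor[cn] + gap)
    cursor[cn] <- cursor[cn] + need
  }
  sequences <- vapply(chrom_names, function(cn) {
    pad <- cfg$chromosome_length - cursor[cn]
    paste(c(parts[[cn]], if (pad > 0L) rand_dna(pad)), collapse = "")
  }, "")

  # --- assemble the bundle ---------------------------------------------
  genes <- list()
  elements <- list()
  rep_rows <- list()
  for (b in placed) {
    for (g in b$genes) {
      gm <- gene_model(g$gene_id, g$seq_id, g$start, g$end, g$strand,
                       g$exons, family = g$family)
      gm$cds <- splice_cds(gm, sequences)
      genes[[g$gene_id]] <- gm
    }
    for (e in b$elements) {
      if (!e$emitted) next
      tsd <- if (!is.null(e$tsd_1))
        list(genomic_interval(e$seq_id, e$tsd_1[1L], e$tsd_1[2L]),
             genomic_interval(e$seq_id, e$tsd_2[1L], e$tsd_2[2L])) else NULL
      elements[[e$element_id]] <-
        ltr_element(e$element_id, e$seq_id, e$ltr5_s, e$ltr5_e,
                    e$ltr3_s, e$ltr3_e, tsd = tsd)
    }
    if (!is.null(b$repeats)) rep_rows[[length(rep_rows) + 1L]] <- b$repeats
  }
  repeats <- if (length(rep_rows)) {
    rr <- do.call(rbind, rep_rows)
    pc <- parse_repeat_class(rr$class)
    repeat_features(rr$seq_id, rr$start, rr$end, "+", rr$name,
                    pc$order, pc$superfamily)
  } else repeat_features()

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(event_id = character(), parent_gene_id = character(),
               retro_gene_id = character(), element_id = character(),
               introns_lost = integer(), autonomy = character(),
               planted_age_my = numeric(), polyA = logical(),
               direct_repeats = logical(), expected_evidence = character(),
               decoy_class = character(), stringsAsFactors = FALSE)
  if (nrow(truth_df)) {
    pex <- vapply(truth_df$parent_gene_id, function(p)
      if (is.na(p)) NA_integer_ else n_exons(genes[[p]]), 1L)
    cex <- vapply(truth_df$retro_gene_id, function(g) n_exons(genes[[g]]), 1L)
    truth_df$introns_lost <- pex - cex
  }
  rownames(truth_df) <- NULL

  bundle <- annotation_bundle(genes = genes, repeats = repeats,
                              ltr_elements = elements, sequences = sequences)
  structure(list(bundle = bundle, truth = truth_df, config = config),
            class = "retro_sim")
}

#' @export
print.retro_sim <- function(x, ...) {
  cat("retro_sim (seed ", x$config$seed, ")\n", sep = "")
  print(x$bundle)
  pos <- sum(is.na(x$truth$decoy_class))
  cat(sprintf("truth: %d planted retro events, %d decoys\n",
              pos, nrow(x$truth) - pos))
  invisible(x)
}

#' Write a simulated genome and its annotations to a directory
#'
#' Emits `genome.fasta`, `genes.gff3`, `repeats.tsv`, `ltr.gff3` and
#' `truth.tsv`. Outputs are byte-identical for identical configurations
#' (no timestamps or environment-dependent content).
#'
#' @param sim A `retro_sim` from [simulate_genome()].
#' @param outdir Output directory (created if needed).
#' @return Named vector of the file paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "retro_sim"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(outdir, "genome.fasta"),
             genes = file.path(outdir, "genes.gff3"),
             repeats = file.path(outdir, "repeats.tsv"),
             ltr = file.path(outdir, "ltr.gff3"),
             truth = file.path(outdir, "truth.tsv"))
  write_genome_fasta(sim$bundle$sequences, paths[["fasta"]])
  write_gene_models(sim$bundle$genes, paths[["genes"]])
  write_repeat_annotations(sim$bundle$repeats, paths[["repeats"]])
  write_ltr_elements(sim$bundle$ltr_elements, paths[["ltr"]])
  write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
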