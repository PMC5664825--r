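# Small builders shared by the unit tests.

gi <- function(seq_id, start, end, strand = "*") genomic_interval(seq_id, start, end, strand)

# single-exon gene whose CDS is just given (no genome needed)
toy_gene <- function(id, start, end, cds = NA_character_, seq_id = "chr1",
                     strand = "+", exons = NULL, family = NA_character_) {
  if (is.null(exons)) exons <- data.frame(start = start, end = end)
  gene_model(id, seq_id, start, end, strand, exons, cds = cds, family = family)
}

toy_element <- function(id, s, ltr_w, e, seq_id = "chr1") {
  ltr_element(id, seq_id, s, s + ltr_w - 1L, e - ltr_w + 1L, e)
}

# a compact simulation used by unit tests (fast: ~6 events)
small_sim <- function(seed, ...) {
  args <- list(
    n_chromosomes = 1L, chromosome_length = 150000L, n_parent_genes = 8L,
    n_retro_events = 6L, target_ages_my = c(0.5, 1),
    n_decoys = list(te_conflict = 1L, orphan_multiexon = 1L,
                    multi_gene_element = 0L, solo_ltr = 1L),
    seed = seed)
  args <- utils::modifyList(args, list(...))
  simulate_genome(do.call(sim_config, args))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
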