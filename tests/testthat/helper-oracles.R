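# Independent oracles used to cross-check the package's own implementations.
# These deliberately share no code with the package internals.

# -- genetic code built from scratch (standard code, hard-coded) ----------
oracle_code <- local({
  aas <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  aas
})

# NG86 by brute force: fractional synonymous sites per codon, and
# recursive enumeration of every mutational pathway between codon pairs
# (pathways through stops excluded unless all pass through one).
oracle_ng86_counts <- function(a, b) {
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- codons(a); cb <- codons(b)
  stopifnot(length(ca) == length(cb))
  syn_sites <- function(codon) {
    aa <- oracle_code[[codon]]
    s <- 0
    for (p in 1:3) for (nb in setdiff(c("A", "C", "G", "T"),
                                      substr(codon, p, p))) {
      alt <- codon; substr(alt, p, p) <- nb
      if (oracle_code[[alt]] == aa && oracle_code[[alt]] != "*") s <- s + 1 / 3
    }
    s
  }
  enumerate_paths <- function(from, to) {
    if (from == to) return(list(list(sd = 0, nd = 0, stopped = FALSE)))
    out <- list()
    for (p in which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])) {
      nxt <- from; substr(nxt, p, p) <- substr(to, p, p)
      step_syn <- oracle_code[[from]] == oracle_code[[nxt]] &&
        oracle_code[[nxt]] != "*"
      step_stop <- oracle_code[[nxt]] == "*"
      for (rest in enumerate_paths(nxt, to)) {
        out[[length(out) + 1]] <- list(
          sd = rest$sd + as.numeric(step_syn),
          nd = rest$nd + as.numeric(!step_syn),
          stopped = rest$stopped || step_stop)
      }
    }
    out
  }
  S <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (i in seq_along(ca)) {
    if (oracle_code[[ca[i]]] == "*" || oracle_code[[cb[i]]] == "*") next
    used <- used + 1
    S <- S + (syn_sites(ca[i]) + syn_sites(cb[i])) / 2
    paths <- enumerate_paths(ca[i], cb[i])
    ok <- Filter(function(p) !p$stopped, paths)
    if (!length(ok)) ok <- paths
    Sd <- Sd + mean(vapply(ok, `[[`, 0, "sd"))
    Nd <- Nd + mean(vapply(ok, `[[`, 0, "nd"))
  }
  list(S = S, N = 3 * used - S, Sd = Sd, Nd = Nd)
}

# random stop-free codon sequence and a mutated partner
oracle_random_cds_pair <- function(n_codons, n_mut) {
  bases <- c("A", "C", "G", "T")
  repeat {
    a <- paste(sample(bases, 3 * n_codons, replace = TRUE), collapse = "")
    cods <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
    if (!any(oracle_code[cods] == "*")) break
  }
  repeat {
    b <- strsplit(a, "")[[1]]
    for (p in sample(length(b), n_mut)) b[p] <- sample(setdiff(bases, b[p]), 1)
    b <- paste(b, collapse = "")
    cods <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
    if (!any(oracle_code[cods] == "*")) return(c(a, b))
  }
}

# -- union-find connected components under a distance cutoff --------------
oracle_components <- function(ids, pairs, cutoff) {
  parent <- setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  for (k in seq_len(nrow(pairs))) {
    if (is.na(pairs$ks[k]) || pairs$ks[k] > cutoff) next
    ra <- find(which(ids == pairs$gene_a[k]))
    rb <- find(which(ids == pairs$gene_b[k]))
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(seq_along(ids), function(i) find(i), 1L)
  setNames(match(roots, unique(roots)), ids)
}

# normalize a membership vector so labelings can be compared
canonical_partition <- function(membership) {
  split(names(membership), membership) |>
    lapply(sort) |>
    (\(x) x[order(vapply(x, `[[`, "", 1))])() |>
    unname()
}
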