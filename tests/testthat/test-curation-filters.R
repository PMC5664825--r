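mk <- function(id, exon_widths, at = 1000) {
  starts <- integer(); ends <- integer(); pos <- at
  for (w in exon_widths) {
    starts <- c(starts, pos); ends <- c(ends, pos + w - 1L)
    pos <- pos + w + 200L
  }
  toy_gene(id, starts[1], ends[length(ends)], cds = rand_seq(sum(exon_widths)),
           exons = data.frame(start = starts, end = ends))
}

test_that("equal exon counts select the gene with the longest exonic extent", {
  a <- mk("a", c(600, 600), at = 1000)   # 1200 nt
  b <- mk("b", c(400, 400), at = 4000)   # 800 nt
  res <- resolve_multi_gene_element(list(a, b))
  expect_equal(res$selected, "a")
  expect_equal(res$rejected, "b")
  expect_equal(res$rule, "equal_counts_longest_exonic")
})

test_that("a >1.5-fold dominant exon wins when exon counts differ", {
  single <- mk("single", 3000, at = 1000)            # one 3000-nt exon
  neigh <- mk("neigh", c(1500, 1200, 900), at = 6000)  # max exon 1500
  res <- resolve_multi_gene_element(list(neigh, single))
  expect_equal(res$selected, "single")   # 3000 > 1.5 * 1500
  expect_equal(res$rule, "dominant_exon")
})

test_that("without a dominant exon the smallest exon count wins", {
  two <- mk("two", c(700, 700), at = 1000)
  four <- mk("four", c(900, 800, 700, 600), at = 4000)  # 900 * 1.5 > 700*? no dominance
  res <- resolve_multi_gene_element(list(four, two))
  expect_equal(res$selected, "two")
  expect_equal(res$rule, "smallest_exon_count")
})

test_that("multi-gene selection is invariant under input order and honors parent status", {
  set.seed(3)
  a <- mk("a", c(600, 600)); b <- mk("b", c(400, 400), at = 4000)
  perms <- list(list(a, b), list(b, a))
  sels <- vapply(perms, function(p) resolve_multi_gene_element(p)$selected, "")
  expect_equal(unique(sels), "a")

  # the longer gene lacks a parent: it is excluded before the rules
  res <- resolve_multi_gene_element(list(a, b), parent_status = c(a = FALSE, b = TRUE))
  expect_equal(res$selected, "b")
  expect_equal(res$rejected, character(0))

  expect_error(resolve_multi_gene_element(list()), "no genes")
  one <- resolve_multi_gene_element(list(a))
  expect_equal(one$selected, "a")
  expect_equal(one$rule, "single")
})

test_that("orphan filtering rejects parentless multi-exon candidates and gates single-exon ones on signatures", {
  calls <- data.frame(
    gene_id = c("m3", "m2p", "s0", "sA"),
    exon_count = c(3L, 2L, 1L, 1L),
    parent_id = c(NA, "p1", NA, NA),
    polyA = c(FALSE, FALSE, FALSE, TRUE),
    direct_repeats = FALSE,
    verdict = NA_character_, stringsAsFactors = FALSE)
  out <- drop_orphan_multiexon(calls)
  expect_equal(out$verdict[out$gene_id == "m3"], "rejected_orphan_multiexon")
  expect_true(is.na(out$verdict[out$gene_id == "m2p"]))  # parented multi-exon retained
  expect_equal(out$verdict[out$gene_id == "s0"], "rejected_orphan_multiexon")
  expect_equal(out$verdict[out$gene_id == "sA"], "candidate_signature_only")
})

test_that("family genes partition into retro, ambiguous and normal exhaustively", {
  genes <- list(r = toy_gene("r", 1000, 2000, family = "CNL-G1"),
                amb = toy_gene("amb", 5000, 6000, family = "CNL-G1"),
                n = toy_gene("n", 9000, 10000, family = "CNL-G1"))
  calls <- data.frame(gene_id = "r", verdict = "retro", stringsAsFactors = FALSE)
  reps <- repeat_features("chr1", 4900, 5850, order = "LTR")  # 85% of amb
  part <- classify_normal_genes(genes, calls, reps)
  expect_equal(setNames(part$class, part$gene_id),
               c(amb = "ambiguous", n = "normal", r = "retro"))
})

test_that("the partition is disjoint and exhaustive on random gene sets", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(1:12, 1)
    genes <- lapply(seq_len(n), function(j)
      toy_gene(paste0("g", j), j * 3000, j * 3000 + sample(500:1500, 1),
               family = "F"))
    names(genes) <- vapply(genes, `[[`, "", "gene_id")
    k <- sample(0:n, 1)
    calls <- data.frame(gene_id = names(genes)[seq_len(k)],
                        verdict = rep("retro", k), stringsAsFactors = FALSE)
    m <- sample(0:5, 1)
    reps <- if (m > 0) {
      s <- sample(1:40000, m)
      repeat_features(rep("chr1", m), s, s + sample(500:3000, m, TRUE),
                      order = "LTR")
    } else repeat_features()
    part <- classify_normal_genes(genes, calls, reps)
    expect_equal(nrow(part), n)
    expect_equal(anyDuplicated(part$gene_id), 0)
    expect_true(all(part$class %in% c("retro", "ambiguous", "normal")))
  }
})
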