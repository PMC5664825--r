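test_that("full-length detection requires whole-gene containment and picks the smallest element", {
  genes <- list(inside = toy_gene("inside", 2000, 5000),
                straddle = toy_gene("straddle", 500, 1500))
  els <- list(big = toy_element("big", 1000, 400, 9000),
              small = toy_element("small", 1500, 300, 6000))
  cand <- detect_candidates_full_ltr(genes, els)
  expect_equal(cand$gene_id, "inside")
  expect_equal(cand$element_id, "small")
  expect_equal(cand$evidence, "full_length")
})

test_that("partial-pass detection needs full LTR coverage extending past both flanks", {
  g <- toy_gene("g", 3001, 4000)
  ok <- repeat_features(rep("chr1", 3), c(1001, 3001, 4001), c(3000, 4000, 6000),
                        name = "frag", order = "LTR", superfamily = "Gypsy")
  cand <- detect_candidates_partial_ltr(list(g), ok)
  expect_equal(cand$gene_id, "g")
  expect_equal(cand$evidence, "partial")

  seventy <- repeat_features("chr1", 3001, 3700, order = "LTR")
  expect_equal(nrow(detect_candidates_partial_ltr(list(g), seventy)), 0)

  dna <- ok; dna$order <- "DNA"
  expect_equal(nrow(detect_candidates_partial_ltr(list(g), dna)), 0)
})

test_that("TE conflicts reject DNA/RC-covered candidates but not LINE overlaps", {
  genes <- list(a = toy_gene("a", 1000, 2000), b = toy_gene("b", 5000, 6000),
                c = toy_gene("c", 8000, 9000))
  cand <- data.frame(gene_id = c("a", "b", "c"), element_id = "e",
                     evidence = "full_length", stringsAsFactors = FALSE)
  reps <- repeat_features(
    c("chr1", "chr1"), c(1000, 8000), c(1800, 8600),
    name = c("Helitron-1", "L1-2"), order = c("RC", "LINE"))
  out <- remove_te_conflicts(cand, genes, reps)
  expect_equal(out$verdict[out$gene_id == "a"], "rejected_te_conflict")  # 80% Helitron
  expect_true(is.na(out$verdict[out$gene_id == "b"]))                    # no overlap
  expect_true(is.na(out$verdict[out$gene_id == "c"]))                    # LINE only
})

test_that("parental search verifies intron loss through high-coverage local alignment", {
  set.seed(11)
  parent_cds <- paste0("ATG", paste(sample(c("GGA", "CCT", "AAA", "TCA", "GAT"),
                                           197, TRUE), collapse = ""))
  parent <- toy_gene("parent", 1000, 3000, cds = parent_cds,
                     exons = data.frame(start = seq(1000, 2500, 300),
                                        end = seq(1090, 2590, 300)))
  other <- toy_gene("other", 5000, 5600, cds = rand_seq(600),
                    exons = data.frame(start = c(5000, 5400), end = c(5200, 5600)))
  cand <- toy_gene("cand", 9000, 9000 + nchar(parent_cds) - 1, cds = parent_cds)

  pm <- find_parent(cand, list(parent = parent, other = other))
  expect_equal(pm$parent_id, "parent")
  expect_equal(pm$query_coverage, 1.0)
  expect_equal(pm$introns_lost, n_exons(parent) - 1L)

  # best alignment covering only ~90% of the query fails the >95% criterion
  cand90 <- toy_gene("cand90", 9000, 9999,
                     cds = paste0(substr(parent_cds, 1, 540), rand_seq(60)))
  expect_null(find_parent(cand90, list(parent = parent)))

  # a pool of single-exon genes can never verify intron loss
  single <- toy_gene("single", 100, 699, cds = parent_cds)
  expect_null(find_parent(cand, list(single = single)))

  # a gene is never its own parent
  expect_null(find_parent(parent, list(parent = parent)))
})

test_that("autonomy depends on a long internal ORF outside the retrocopy", {
  set.seed(5)
  orf <- paste0("ATG", paste(rep("GCT", 400), collapse = ""), "TAA")
  left <- rand_seq(1000); mid <- rand_seq(300); right <- rand_seq(1000)
  gene_seq <- rand_seq(600)
  chrom <- paste0(left, mid, gene_seq, orf, right)
  # LTRs: [1,1000] and [last 1000]
  n <- nchar(chrom)
  el <- ltr_element("e", "chr1", 1, 1000, n - 999, n)
  gene_span <- genomic_interval("chr1", 1301, 1900)
  seqs <- c(chr1 = chrom)
  expect_equal(classify_autonomy(el, seqs, exclude = gene_span), "autonomous")

  # same element without the ORF: nothing long enough remains
  chrom2 <- paste0(left, mid, gene_seq, rand_seq(nchar(orf)), right)
  expect_equal(classify_autonomy(el, c(chr1 = chrom2), exclude = gene_span),
               "non_autonomous")
  expect_equal(classify_autonomy(el, NULL), "unknown")
})

test_that("signature scan finds planted poly(A) tails and target-site duplications", {
  set.seed(21)
  tsd <- "GATTC"
  cds <- paste0("ATG", rand_seq(297))
  chrom <- paste0(rand_seq(300), tsd, rand_seq(150), cds,
                  paste(rep("A", 15), collapse = ""), rand_seq(150), tsd,
                  rand_seq(300))
  gstart <- 300 + 5 + 150 + 1
  g <- toy_gene("g", gstart, gstart + nchar(cds) - 1)
  span <- genomic_interval("chr1", 306, 305 + 150 + nchar(cds) + 15 + 150)
  sig <- retro_signature_scan(g, c(chr1 = chrom), span = span)
  expect_true(sig[["polyA"]])
  expect_true(sig[["direct_repeats"]])
})

test_that("a 9-base adenine run is below the poly(A) threshold", {
  set.seed(22)
  cds <- paste0("ATG", rand_seq(297))
  chrom <- paste0(rand_seq(200), cds, "CC", paste(rep("A", 9), collapse = ""),
                  "CC", rand_seq(200))
  g <- toy_gene("g", 201, 200 + nchar(cds))
  sig <- retro_signature_scan(g, c(chr1 = chrom))
  expect_false(sig[["polyA"]])
})

test_that("minus-strand poly(A) appears as an upstream thymine run", {
  set.seed(23)
  cds <- paste0("ATG", rand_seq(297))
  genome_part <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    paste0(cds, paste(rep("A", 15), collapse = "")))))
  chrom <- paste0(rand_seq(200), genome_part, rand_seq(200))
  g <- toy_gene("g", 216, 215 + nchar(cds), strand = "-")
  sig <- retro_signature_scan(g, c(chr1 = chrom))
  expect_true(sig[["polyA"]])
})

test_that("ordinary genes in random sequence rarely carry retro signatures", {
  set.seed(31)
  fp <- 0
  for (i in 1:40) {
    chrom <- rand_seq(1400)
    g <- toy_gene("g", 501, 900)
    sig <- retro_signature_scan(g, c(chr1 = chrom))
    fp <- fp + any(sig)
  }
  expect_lt(fp / 40, 0.2)
})
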