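write_tmp <- function(lines, ext = ".gff3") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("GFF3 gene models parse with coordinates preserved and longest CDS chosen", {
  f <- write_tmp(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t800\t.\t+\t.\tID=g1;family=CNL-G2",
    "chr1\tsrc\tmRNA\t101\t800\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=t1",
    "chr1\tsrc\tCDS\t101\t200\t.\t+\t0\tParent=t1",
    "chr1\tsrc\texon\t301\t500\t.\t+\t.\tParent=t1",
    "chr1\tsrc\tCDS\t301\t500\t.\t+\t0\tParent=t1",
    "chr1\tsrc\tmRNA\t101\t800\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\tsrc\tCDS\t101\t550\t.\t+\t0\tParent=t2"))
  genes <- read_gene_models(f)
  expect_length(genes, 1)
  g <- genes[["g1"]]
  # a GFF exon written 101..200 spans exactly those bases (width 100)
  expect_equal(g$span$start, 101)
  expect_equal(g$family, "CNL-G2")
  # t2 CDS total 450 beats t1's 300
  expect_equal(n_exons(g), 1)
  expect_equal(exonic_length(g), 450)
})

test_that("structural GFF errors are reported, overlapping-exon transcripts rejected", {
  f <- write_tmp(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t500\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=t99"))
  expect_error(read_gene_models(f), "no parent mRNA")

  f2 <- write_tmp(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t500\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1\t500\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=t1",
    "chr1\tsrc\texon\t50\t200\t.\t+\t.\tParent=t1"))
  expect_warning(expect_warning(genes <- read_gene_models(f2),
                                "overlapping exons"),
                 "no usable transcript")
  expect_length(genes, 0)
  # nothing silently dropped: the rejection is recorded
  expect_equal(attr(genes, "rejections"), "t1")
})

test_that("gene models survive a write/read round trip", {
  genes <- list(
    toy_gene("a1", 100, 700, family = "CNL-G1",
             exons = data.frame(start = c(100, 400), end = c(250, 700))),
    toy_gene("b1", 2000, 2600, strand = "-", family = "CNL-G2",
             exons = data.frame(start = c(2000, 2400), end = c(2100, 2600))))
  names(genes) <- c("a1", "b1")
  f <- tempfile(fileext = ".gff3")
  write_gene_models(genes, f)
  back <- read_gene_models(f)
  expect_setequal(names(back), names(genes))
  for (id in names(genes)) {
    expect_equal(back[[id]]$span[], genes[[id]]$span[])
    expect_equal(back[[id]]$exons, genes[[id]]$exons)
    expect_equal(back[[id]]$family, genes[[id]]$family)
  }
})

test_that("repeat tables parse from both the package TSV and .out-style formats", {
  f <- write_tmp(c("seq_id\tstart\tend\tstrand\tname\tclass",
                   "chr1\t1\t500\t+\tGypsy-1\tLTR/Gypsy",
                   "chr1\t600\t900\t+\thAT-5\tDNA/hAT"), ".tsv")
  r <- read_repeat_annotations(f)
  expect_equal(r$order, c("LTR", "DNA"))
  expect_equal(r$superfamily, c("Gypsy", "hAT"))
  expect_equal(r$start[1], 1)
  expect_equal(r$end[1], 500)

  out <- write_tmp(c(
    "   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin end (left)     repeat class/family ...",
    "",
    "  463  1.3  0.6  1.7  chr1  1  500  (99500)  +  Gypsy-1  LTR/Gypsy  1  500  (0)  1",
    "  239  9.1  0.2  0.0  chr1  700  950  (99050)  C  Helitron-2  RC/Helitron  1  251  (0)  2"), ".out")
  r2 <- read_repeat_annotations(out)
  expect_equal(r2$order, c("LTR", "RC"))
  expect_equal(r2$strand, c("+", "-"))
  expect_equal(r2$start[2], 700)
})

test_that("unknown repeat classes are retained as Unknown with a warning", {
  f <- write_tmp(c("seq_id\tstart\tend\tstrand\tname\tclass",
                   "chr1\t1\t100\t+\tweird\tXyz/Qux"), ".tsv")
  expect_warning(r <- read_repeat_annotations(f), "unknown repeat class")
  expect_equal(nrow(r), 1)  # not dropped
  expect_equal(r$order, "Unknown")
})

test_that("LTR element records need exactly two LTR children", {
  f <- write_tmp(c(
    "##gff-version 3",
    "chr1\tltrh\tLTR_retrotransposon\t1000\t9000\t.\t+\t.\tID=e1",
    "chr1\tltrh\tlong_terminal_repeat\t1000\t1400\t.\t+\t.\tParent=e1",
    "chr1\tltrh\tlong_terminal_repeat\t8600\t9000\t.\t+\t.\tParent=e1",
    "chr1\tltrh\ttarget_site_duplication\t995\t999\t.\t+\t.\tParent=e1",
    "chr1\tltrh\ttarget_site_duplication\t9001\t9005\t.\t+\t.\tParent=e1",
    "chr1\tltrh\tLTR_retrotransposon\t20000\t25000\t.\t+\t.\tID=e2",
    "chr1\tltrh\tlong_terminal_repeat\t20000\t20300\t.\t+\t.\tParent=e2"))
  expect_warning(els <- read_ltr_elements(f), "full-length elements need exactly 2")
  expect_length(els, 1)
  e <- els[["e1"]]
  ir <- internal_region(e)
  expect_equal(c(ir$start, ir$end), c(1401, 8599))
  expect_length(e$tsd, 2)
  expect_equal(attr(els, "rejections"), "e2")
})

test_that("nested LTR elements are both emitted", {
  f <- write_tmp(c(
    "##gff-version 3",
    "chr1\tltrh\tLTR_retrotransposon\t1000\t20000\t.\t+\t.\tID=outer",
    "chr1\tltrh\tlong_terminal_repeat\t1000\t1500\t.\t+\t.\tParent=outer",
    "chr1\tltrh\tlong_terminal_repeat\t19500\t20000\t.\t+\t.\tParent=outer",
    "chr1\tltrh\tLTR_retrotransposon\t5000\t9000\t.\t+\t.\tID=inner",
    "chr1\tltrh\tlong_terminal_repeat\t5000\t5300\t.\t+\t.\tParent=inner",
    "chr1\tltrh\tlong_terminal_repeat\t8700\t9000\t.\t+\t.\tParent=inner"))
  els <- read_ltr_elements(f)
  expect_setequal(names(els), c("outer", "inner"))
  # round trip
  f2 <- tempfile(fileext = ".gff3")
  write_ltr_elements(els, f2)
  back <- read_ltr_elements(f2)
  expect_setequal(names(back), names(els))
  expect_equal(back[["inner"]]$ltr3[], els[["inner"]]$ltr3[])
})

test_that("retro call reports round trip and order deterministically", {
  calls <- data.frame(
    gene_id = c("g2", "g1"), seq_id = "chr1", start = c(500L, 100L),
    end = c(900L, 400L), element_id = c("e2", "e1"),
    evidence = "full_length", parent_id = c("p2", "p1"),
    parent_coverage = c(1, 0.99), introns_lost = c(3L, 5L),
    autonomy = "non_autonomous", polyA = TRUE, direct_repeats = c(TRUE, FALSE),
    insertion_age_my = c(1.0, 0.5), verdict = "retro",
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_retro_calls(calls, f)
  back <- read_retro_calls(f)
  expect_equal(back$gene_id, c("g1", "g2"))  # coordinate order
  expect_equal(back$verdict, c("retro", "retro"))
  expect_equal(back$insertion_age_my, c(0.5, 1.0))

  f2 <- tempfile(fileext = ".tsv")
  write_retro_calls(calls[0, ], f2)
  expect_equal(length(readLines(f2)), 1)  # header only
})
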