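test_that("K2P distance matches its closed form and is symmetric", {
  expect_equal(as.numeric(k2p_distance("ACGTACGTAC", "ACGTACGTAC")), 0)
  # 10 sites, one transition (A->G), no transversions: P=0.1, Q=0
  a <- "AAAACCCCTT"; b <- "GAAACCCCTT"
  expect_equal(as.numeric(k2p_distance(a, b)), -0.5 * log(0.8), tolerance = 1e-6)
  expect_equal(as.numeric(k2p_distance(a, b)), as.numeric(k2p_distance(b, a)))
})

test_that("gap and ambiguity columns are excluded from K2P site counts", {
  k <- k2p_distance("A-CGTNACGT", "AACGTTACGT")
  expect_equal(attr(k, "sites"), 8)
  expect_equal(as.numeric(k), 0)
})

test_that("K2P saturation raises a structured error", {
  a <- paste(rep("A", 40), collapse = "")
  b <- paste(rep("G", 40), collapse = "")  # P = 1
  expect_error(k2p_distance(a, b), class = "retroscan_saturation")
})

test_that("K2P agrees with an independent reference implementation", {
  set.seed(19)
  for (i in 1:5) {
    a <- rand_seq(2000)
    b <- evolve_sequence(a, 0.08, ts_tv_ratio = 2)
    mine <- as.numeric(k2p_distance(a, b))
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(rbind(
      strsplit(tolower(a), "")[[1]], strsplit(tolower(b), "")[[1]])),
      model = "K80"))
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("simulated divergence is recovered by the K2P estimator", {
  set.seed(101)
  anc <- rand_seq(10000)
  a <- evolve_sequence(anc, 0.025, 2)
  b <- evolve_sequence(anc, 0.025, 2)
  k <- k2p_distance(a, b)
  se <- sqrt(0.05 / 10000)  # rough SE at small distances
  expect_lt(abs(as.numeric(k) - 0.05), 3 * se)
})

test_that("insertion and duplication ages are linear in distance and rate", {
  p <- clock_params()
  expect_equal(insertion_age(0.026, p), 1e6)
  expect_equal(duplication_time(0.01392, p), 1e6)
  expect_equal(insertion_age(0, p), 0)
  p2 <- clock_params(r_intergenic = 2 * p$r_intergenic,
                     r_synonymous = 2 * p$r_synonymous)
  expect_equal(insertion_age(0.026, p2), 5e5)
  expect_equal(duplication_time(0.01392, p2), 5e5)
})

test_that("identical LTRs date an element to age zero", {
  set.seed(7)
  ltr <- rand_seq(800)
  chrom <- paste0(ltr, rand_seq(3000), ltr)
  el <- ltr_element("e", "chr1", 1, 800, 3801, 4600)
  age <- ltr_insertion_time(el, c(chr1 = chrom))
  expect_equal(as.numeric(age), 0)
  expect_equal(attr(age, "K"), 0)
})

test_that("NG86 separates synonymous from nonsynonymous single changes", {
  ident <- ng86_ka_ks("ATGGGGAAA", "ATGGGGAAA")
  expect_equal(ident$Ka, 0)
  expect_equal(ident$Ks, 0)

  rest <- paste(rep("CAT", 8), collapse = "")
  base <- paste0("ATG", "GGG", rest)
  syn <- paste0("ATG", "GGA", rest)   # third-position synonymous change
  r <- ng86_ka_ks(base, syn)
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
  expect_equal(r$Nd, 0)
  expect_equal(r$Sd, 1)

  nonsyn <- paste0("ATG", "GTG", rest)  # Gly -> Val
  r2 <- ng86_ka_ks(base, nonsyn)
  expect_equal(r2$Ks, 0)
  expect_gt(r2$Ka, 0)
})

test_that("NG86 site counts always sum to the compared length", {
  set.seed(33)
  for (i in 1:10) {
    pair <- oracle_random_cds_pair(20, sample(1:8, 1))
    r <- ng86_ka_ks(pair[1], pair[2])
    expect_equal(r$S + r$N, 60)
  }
})

test_that("NG86 counts match the pathway-enumeration oracle on small pairs", {
  set.seed(44)
  for (i in 1:10) {
    pair <- oracle_random_cds_pair(12, sample(1:6, 1))
    mine <- ng86_ka_ks(pair[1], pair[2])
    orc <- oracle_ng86_counts(pair[1], pair[2])
    expect_equal(mine$S, orc$S, tolerance = 1e-9)
    expect_equal(mine$Sd, orc$Sd, tolerance = 1e-9)
    expect_equal(mine$Nd, orc$Nd, tolerance = 1e-9)
  }
})

test_that("internal stop codons are rejected, terminal stops tolerated", {
  expect_error(ng86_ka_ks("ATGTAAAAA", "ATGTACAAA"), "internal stop")
  r <- ng86_ka_ks("ATGAAATAA", "ATGAAATAA")  # terminal stop skipped
  expect_equal(r$S + r$N, 6)
})

test_that("single-linkage Ks clustering chains below the cutoff", {
  pairs <- data.frame(gene_a = c("a", "b", "a"), gene_b = c("b", "c", "c"),
                      ks = c(0.01, 0.01, 0.5))
  res <- ks_single_linkage(pairs, cutoff = 0.02)
  expect_equal(length(unique(res$membership$cluster)), 1)
  expect_equal(res$clusters$min_ks, 0.01)
  expect_equal(res$clusters$age_my, 0.01 / (2 * 6.96e-9) / 1e6)

  solo <- ks_single_linkage(data.frame(gene_a = character(),
                                       gene_b = character(), ks = numeric()),
                            cutoff = 0.1, gene_ids = "only")
  expect_equal(nrow(solo$membership), 1)
  expect_true(is.na(solo$clusters$age_my))
})

test_that("Ks clustering equals the union-find oracle on random instances", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    ids <- paste0("g", seq_len(n))
    cmb <- t(combn(ids, 2))
    keep <- runif(nrow(cmb)) < 0.4
    pairs <- data.frame(gene_a = cmb[keep, 1], gene_b = cmb[keep, 2],
                        ks = runif(sum(keep), 0, 0.2))
    cutoff <- 0.08
    mine <- ks_single_linkage(pairs, cutoff, gene_ids = ids)
    m <- setNames(mine$membership$cluster, mine$membership$gene_id)
    orc <- oracle_components(ids, pairs, cutoff)
    expect_equal(canonical_partition(m), canonical_partition(orc))
  }
})
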