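test_that("substitution classification is exhaustive and symmetric", {
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("A", "C"), "transversion")
  pairs <- utils::combn(c("A", "C", "G", "T"), 2L)
  classes <- apply(pairs, 2L, function(p) classify_substitution(p[1L], p[2L]))
  rev_classes <- apply(pairs, 2L, function(p) classify_substitution(p[2L], p[1L]))
  expect_identical(classes, rev_classes)
  expect_equal(sum(classes == "transition"), 2L)
  expect_equal(sum(classes == "transversion"), 4L)
  expect_error(classify_substitution("A", "A"), "identical")
  expect_error(classify_substitution("A", "N"), "A,C,G,T")
})

test_that("scanner classifies SNP, InDel, homopolymer and inversion events", {
  # no variation
  same <- make_aln(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"), "a")
  expect_equal(nrow(scan_alignment(same)), 0L)

  # the three planted events of the tiny fixture
  ev <- scan_alignment(tiny_aln())
  expect_equal(ev$kind, c("SNP", "InDel", "HomopolymerDiff"))
  expect_equal(ev$col_start, c(5L, 8L, 14L))
  expect_equal(ev$col_end, c(5L, 9L, 15L))
  expect_equal(ev$substitution_class, c("transversion", NA, NA))
  expect_true(ev$is_singleton[1L])
  expect_equal(unname(ev$alleles[[2L]]), c("TC", "TC", "", "TC"))

  # a 3-nt reverse-complement block is one inversion event
  inv <- make_aln(c(a = "CCGTAGATTTT", b = "CCGTTCTTTTT"), "a")
  evi <- scan_alignment(inv)
  expect_equal(evi$kind, "Inversion")
  expect_equal(c(evi$col_start, evi$col_end), c(5L, 7L))
  expect_setequal(unname(evi$alleles[[1L]]), c("AGA", "TCT"))

  # adjacent substitution columns that are not reverse complements stay SNPs
  noinv <- make_aln(c(a = "CCGTAGTTTTT", b = "CCGTGATTTTT"), "a")
  expect_equal(scan_alignment(noinv)$kind, c("SNP", "SNP"))

  # N makes a sample missing; a column with <2 observed states is invariant
  amb <- make_aln(c(a = "ACGT", b = "ANGT", c = "ACGT"), "a")
  expect_equal(nrow(scan_alignment(amb)), 0L)
})

test_that("homopolymer calls require a reference mononucleotide run", {
  # run of 5 T's, one sample shorter: homopolymer difference
  hp <- make_aln(c(a = "ACGTTTTTGCAC", b = "ACGTTT--GCAC"), "a")
  expect_equal(scan_alignment(hp)$kind, "HomopolymerDiff")
  # same gap length but mixed bases deleted: plain InDel
  mixed <- make_aln(c(a = "ACGTAGCTGCAC", b = "ACGT--CTGCAC"), "a")
  expect_equal(scan_alignment(mixed)$kind, "InDel")
  # run below the threshold: plain InDel
  short <- make_aln(c(a = "ACGTTTGCACAC", b = "ACGT-TGCACAC"), "a")
  expect_equal(scan_alignment(short)$kind, "InDel")
  # threshold is configurable
  expect_equal(scan_alignment(short, scan_config(homopolymer_min_run = 2L))$kind,
               "HomopolymerDiff")
})

test_that("event spans partition the polymorphic columns", {
  for (seed in 1:5) {
    sim <- simulate_alignment_set(sim_config(
      seed = seed, genome_length = 5000, n_genes = 2L, n_snp = 25, n_indel = 3,
      n_homopolymer = 5, n_diagnostic = 3))
    ev <- scan_alignment(sim$alignment)
    spans <- unlist(mapply(seq, ev$col_start, ev$col_end, SIMPLIFY = FALSE))
    expect_false(any(duplicated(spans)))  # disjoint
    m <- do.call(rbind, strsplit(unname(sim$alignment$seqs), ""))
    poly <- which(vapply(seq_len(ncol(m)), function(j) {
      x <- m[, j]
      any(x == "-") || length(unique(x[x != "N" & x != "-"])) >= 2L
    }, NA))
    expect_setequal(spans, poly)
  }
})

test_that("SNP matrix construction keeps SNP sites only", {
  ev <- scan_alignment(tiny_aln())
  m <- snp_matrix_from_events(ev)
  expect_equal(nrow(m), 1L)
  expect_equal(rownames(m), "c5")
  expect_equal(unname(m[1L, ]), c("A", "C", "A", "A"))

  # zero SNPs
  same <- make_aln(c(a = "ACGT", b = "ACGT"), "a")
  m0 <- snp_matrix_from_events(scan_alignment(same), sample_ids = c("a", "b"))
  expect_equal(dim(m0), c(0L, 2L))

  # a multi-allelic column is one site
  multi <- make_aln(c(a = "AAAACCCC", b = "ATAACCCC", c = "AGAACCCC"), "a")
  evm <- scan_alignment(multi)
  expect_equal(nrow(snp_matrix_from_events(evm)), 1L)
  expect_true(is.na(evm$substitution_class[1L]))
})

test_that("pairwise differences match a double-loop oracle", {
  # two samples with identical profiles are at distance zero
  two <- snp_matrix(matrix(c("A", "C", "A", "C", "C", "A"), 2L, 3L,
                           dimnames = list(c("s1", "s2"), c("x", "y", "z"))))
  expect_equal(unname(pairwise_differences(two)["x", "y"]), 0L)
  expect_equal(unname(pairwise_differences(two)["x", "z"]), 2L)

  set.seed(99)
  for (rep in 1:10) {
    m <- matrix(sample(c("A", "C", "G", "T", "?"), 60, replace = TRUE),
                10L, 6L, dimnames = list(sprintf("s%d", 1:10),
                                         sprintf("i%d", 1:6)))
    d <- pairwise_differences(snp_matrix(m, validate = FALSE))
    oracle <- matrix(0L, 6L, 6L)
    for (i in 1:6) for (j in 1:6) {
      cnt <- 0L
      for (s in 1:10)
        if (m[s, i] != "?" && m[s, j] != "?" && m[s, i] != m[s, j])
          cnt <- cnt + 1L
      oracle[i, j] <- cnt
    }
    expect_equal(unname(unclass(d)), oracle)
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0L))
    # bounded by the pair's complete-case site count
    for (i in 1:6) for (j in 1:6) {
      cc <- sum(m[, i] != "?" & m[, j] != "?")
      expect_lte(d[i, j], cc)
    }
  }
  # triangle inequality holds without missing data
  m2 <- matrix(sample(c("A", "C"), 40, replace = TRUE), 8L, 5L,
               dimnames = list(sprintf("s%d", 1:8), sprintf("i%d", 1:5)))
  d2 <- pairwise_differences(snp_matrix(m2, validate = FALSE))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(d2[i, j], d2[i, k] + d2[k, j])
})

test_that("variant summary reports fractions, singletons and GC content", {
  same <- make_aln(c(a = "GGCCGGCC", b = "GGCCGGCC"), "a")
  s0 <- summarize_variants(same, scan_alignment(same))
  expect_equal(s0$n_snp + s0$n_indel + s0$n_homopolymer + s0$n_inversion, 0L)
  expect_equal(s0$gc_content, 1.0)

  sim <- simulate_alignment_set(sim_config(seed = 13, genome_length = 6000, n_genes = 2L,
                                           n_snp = 30, n_indel = 2,
                                           n_homopolymer = 3,
                                           n_diagnostic = 3))
  ev <- scan_alignment(sim$alignment)
  s <- summarize_variants(sim$alignment, ev)
  expect_equal(s$ts_fraction + s$tv_fraction, 1)
  expect_equal(sum(s$pair_fractions), 1)
  expect_lte(s$n_singleton, s$n_snp)
  expect_equal(sum(s$unique_snps_per_sample), s$n_singleton)
  # planted classes drive the breakdown exactly
  planted_ts <- sum(sim$truth$class == "transition", na.rm = TRUE)
  expect_equal(s$ts_fraction, planted_ts / s$n_snp)
})
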