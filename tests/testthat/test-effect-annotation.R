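test_that("the default property scheme is total and matches the published classes", {
  scheme <- default_property_scheme()
  expect_length(scheme, 20L)
  expect_false(anyDuplicated(names(scheme)) > 0L)
  expect_setequal(unique(scheme), c("basic", "acid/amide", "hydrophilic",
                                    "hydrophobic", "special"))

  # the eight observed chloroplast substitutions and their class pairs
  cases <- list(
    list("R", "C", "basic", "special", TRUE),
    list("S", "A", "hydrophilic", "hydrophilic", FALSE),
    list("Q", "K", "acid/amide", "basic", TRUE),
    list("K", "Q", "basic", "acid/amide", TRUE),
    list("V", "I", "hydrophobic", "hydrophobic", FALSE),
    list("I", "L", "hydrophobic", "hydrophobic", FALSE),
    list("L", "I", "hydrophobic", "hydrophobic", FALSE),
    list("P", "S", "hydrophilic", "hydrophilic", FALSE))
  for (cs in cases) {
    got <- property_change(cs[[1L]], cs[[2L]])
    expect_equal(got$ref_property, cs[[3L]])
    expect_equal(got$alt_property, cs[[4L]])
    expect_equal(got$changed, cs[[5L]])
  }
  # identity never changes class
  for (aa in names(scheme))
    expect_false(property_change(aa, aa)$changed)
  expect_error(property_change("R", "B"), "unknown residue")
})

test_that("site location matches a brute-force interval scan", {
  ann <- validate_annotations(data.frame(
    name = c("g1", "g1_intron", "g1", "t1", "p1"),
    kind = c("gene", "intron", "gene", "tRNA", "pseudogene"),
    strand = "+",
    start = c(10L, 22L, 34L, 60L, 80L),
    end = c(21L, 33L, 39L, 70L, 95L),
    phase = 0L))
  expect_equal(locate_site(15L, ann)$context, "CDS")
  expect_equal(locate_site(25L, ann)$context, "intron")
  expect_equal(locate_site(65L, ann)$context, "tRNA")
  expect_equal(locate_site(85L, ann)$context, "pseudogene")
  expect_equal(locate_site(50L, ann)$feature, "intergenic")
  expect_error(locate_site(NA_integer_, ann), "no reference coordinate")

  set.seed(7)
  pref <- c(gene = 1L, tRNA = 2L, rRNA = 3L, pseudogene = 4L, intron = 5L)
  for (pos in sample(1:100, 100L, replace = TRUE)) {
    hit <- ann[ann$start <= pos & ann$end >= pos, , drop = FALSE]
    expected <- if (!nrow(hit)) "intergenic" else {
      k <- hit$kind[order(pref[hit$kind])][1L]
      if (k == "gene") "CDS" else k
    }
    expect_equal(locate_site(pos, ann)$context, expected)
  }
})

test_that("coding effects are called through codons, strands and exon breaks", {
  code11 <- Biostrings::getGeneticCode("11")
  # plus strand, single exon: ATG CGT GGA TAA
  aln <- make_aln(c(r = "CCATGCGTGGATAACC",
                    b = "CCATGTGTGGGTAACC"), "r")
  ann <- validate_annotations(data.frame(
    name = "g", kind = "gene", strand = "+", start = 3L, end = 14L,
    phase = 0L))
  # codon 2 CGT -> TGT: arginine to cysteine, class change
  eff <- call_effect(6L, "C", "T", "g", ann, aln)
  expect_equal(eff$codon_index, 2L)
  expect_equal(c(eff$ref_aa, eff$alt_aa), c("R", "C"))
  expect_false(eff$synonymous)
  expect_true(eff$property_changed)
  # codon 3 third position GGA -> GGG: 4-fold degenerate, synonymous
  eff2 <- call_effect(11L, "A", "G", "g", ann, aln)
  expect_equal(code11[["GGA"]], code11[["GGG"]])  # oracle: direct lookup
  expect_true(eff2$synonymous)
  expect_true(is.na(eff2$ref_property))

  # minus strand: the same CDS encoded on the complementary strand gives
  # the identical call from the flipped alignment
  flip <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]),
                            collapse = "")
  aln_m <- make_aln(c(r = flip(aln$seqs[["r"]]), b = flip(aln$seqs[["b"]])), "r")
  L <- nchar(aln$seqs[["r"]])
  ann_m <- validate_annotations(data.frame(
    name = "g", kind = "gene", strand = "-", start = L - 14L + 1L,
    end = L - 3L + 1L, phase = 0L))
  eff_m <- call_effect(L - 6L + 1L, "G", "A", "g", ann_m, aln_m)
  expect_equal(eff_m[c("codon_index", "ref_aa", "alt_aa", "synonymous",
                       "property_changed")],
               eff[c("codon_index", "ref_aa", "alt_aa", "synonymous",
                     "property_changed")])

  # codon split across an exon boundary: exon1 ATGC | intron | exon2 GTTAA
  aln_x <- make_aln(c(r = "AAATGCTTTTTGTTAAAA",
                      b = "AAATGTTTTTTGTTAAAA"), "r")
  ann_x <- validate_annotations(data.frame(
    name = c("gx", "gx", "gx_intron"),
    kind = c("gene", "gene", "intron"), strand = "+",
    start = c(3L, 12L, 7L), end = c(6L, 16L, 11L), phase = 0L))
  effx <- call_effect(6L, "C", "T", "gx", ann_x, aln_x)
  expect_equal(effx$codon_index, 2L)
  expect_equal(c(effx$ref_aa, effx$alt_aa), c("R", "C"))

  # a premature stop is reported, not an error: CGA -> TGA
  aln_s <- make_aln(c(r = "CCATGCGATAACC", b = "CCATGTGATAACC"), "r")
  ann_s <- validate_annotations(data.frame(
    name = "gs", kind = "gene", strand = "+", start = 3L, end = 11L,
    phase = 0L))
  effs <- call_effect(6L, "C", "T", "gs", ann_s, aln_s)
  expect_equal(effs$alt_aa, "*")
  expect_false(effs$synonymous)

  # incomplete terminal codon is an error naming the feature
  ann_bad <- data.frame(name = "gb", kind = "gene", strand = "+",
                        start = 3L, end = 12L, phase = 0L)
  expect_error(call_effect(6L, "C", "T", "gb", ann_bad, aln_s),
               "incomplete terminal codon.*gb")
})

test_that("effect counting is consistent and matches planted truth", {
  expect_equal(count_effects(data.frame(context = character(0),
                                        synonymous = logical(0),
                                        property_changed = logical(0))),
               list(n_coding = 0L, n_noncoding = 0L, n_nonsynonymous = 0L,
                    n_property_changed = 0L, n_in_tRNA = 0L))

  sim <- simulate_alignment_set(sim_config(seed = 21))
  ev <- scan_alignment(sim$alignment)
  eff <- annotate_effects(ev, sim$annotations, sim$alignment)
  cnt <- count_effects(eff)
  expect_lte(cnt$n_property_changed, cnt$n_nonsynonymous)
  expect_lte(cnt$n_nonsynonymous, cnt$n_coding)
  expect_equal(cnt$n_coding + cnt$n_noncoding, sum(ev$kind == "SNP"))

  # planted coding SNPs: feature, codon index and residues recovered exactly
  tt <- sim$truth
  cds <- which(tt$kind == "SNP" & !is.na(tt$feature))
  got <- eff[match(tt$col_start[cds], eff$column), ]
  expect_true(all(got$context == "CDS"))
  expect_equal(got$feature, tt$feature[cds])
  expect_equal(got$codon_index, tt$codon_index[cds])
  expect_equal(got$ref_aa, tt$ref_aa[cds])
  expect_equal(got$alt_aa, tt$alt_aa[cds])
  expect_equal(cnt$n_coding, length(cds))
})

test_that("annotated coding sequences of the synthetic genome are stop-free", {
  sim <- simulate_alignment_set(sim_config(seed = 31, genome_length = 8000, n_genes = 2L,
                                           n_snp = 10, n_indel = 1,
                                           n_homopolymer = 2, n_diagnostic = 2))
  ref <- gsub("-", "", sim$alignment$seqs[[sim$alignment$reference_id]])
  code11 <- Biostrings::getGeneticCode("11")
  for (g in unique(sim$annotations$name[sim$annotations$kind == "gene"])) {
    rows <- sim$annotations[sim$annotations$name == g &
                              sim$annotations$kind == "gene", ]
    pieces <- vapply(seq_len(nrow(rows)), function(k)
      substr(ref, rows$start[k], rows$end[k]), "")
    cds <- paste(pieces, collapse = "")
    if (rows$strand[1L] == "-")
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    codons <- substring(cds, seq(1L, nchar(cds) - 2L, 3L),
                        seq(3L, nchar(cds), 3L))
    aas <- code11[codons]
    expect_false(any(aas[-length(aas)] == "*"))
    expect_equal(unname(aas[length(aas)]), "*")
  }
})
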