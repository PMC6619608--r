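# Small in-code fixtures shared across tests.

make_aln <- function(seqs, reference_id = names(seqs)[1L], circular = FALSE) {
  genome_alignment(seqs, reference_id = reference_id, circular = circular)
}

# a tiny 4-sample alignment with one SNP (col 5), one deletion (cols 8-9)
# and one homopolymer run (AAAAA, cols 12-16, shortened in s4)
tiny_aln <- function() {
  make_aln(c(
    ref = "ACGTACGTCGAAAAAGTACG",
    s2  = "ACGTCCGTCGAAAAAGTACG",
    s3  = "ACGTACG--GAAAAAGTACG",
    s4  = "ACGTACGTCGAAA--GTACG"))
}

table5_matrix <- function() {
  read_snp_matrix(system.file("extdata", "mito_diagnostic_snps.tsv",
                              package = "larchvar"))
}

table1_samples <- function() {
  read_sample_table(system.file("extdata", "larch_samples.tsv",
                                package = "larchvar"))
}

taymyr_groups <- function(md) {
  list(Taymyr = md$sample_code[md$region == "Taymyr"],
       OmoloyKolyma = md$sample_code[md$region != "Taymyr"])
}

# brute-force Hamming distance
ham <- function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
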