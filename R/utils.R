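# Internal helpers shared across modules.

GAP <- "-"
MISSING <- "?"
DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
split_chars <- function(x) strsplit(x, "", fixed = TRUE)

#' Character matrix view of an alignment (samples x columns)
#' @noRd
aln_matrix <- function(aln) {
  m <- do.call(rbind, split_chars(aln$seqs))
  rownames(m) <- aln$sample_ids
  m
}

#' @noRd
collapse_chars <- function(m) apply(m, 1L, paste, collapse = "")

#' Reverse complement of a plain character string (gaps preserved in place,
#' then reversed with the rest).
#' @noRd
revcomp_chr <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(split_chars(comp), function(ch) paste(rev(ch), collapse = ""), "")
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic minor allele of an allele count table: lowest count wins,
#' ties broken by lexicographically smaller base being called minor.
#' @noRd
minor_allele <- function(tab) {
  tab <- tab[order(names(tab))]
  names(tab)[which.min(tab)]
}

#' Majority allele; at a full tie the lexicographically larger base is
#' called major so that minor/major never coincide on biallelic sites.
#' @noRd
major_allele <- function(tab) {
  tab <- tab[order(names(tab), decreasing = TRUE)]
  names(tab)[which.max(tab)]
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
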