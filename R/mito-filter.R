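# Robustness and anti-paralogy filtering of candidate mitochondrial SNP
# sites scored from short de-novo contigs, where many individuals lack
# coverage ("?" entries).

#' Robustness filter for SNP sites with missing data
#'
#' A site is kept when it is unambiguously observed in at least 6
#' individuals and its second allele occurs at least 3 times
#' (partial-coverage rule), or when every individual is observed and the
#' second allele occurs at least 2 times (full-coverage rule). At
#' multi-allelic sites the second-most-frequent allele is tested; further
#' alleles are ignored.
#'
#' @param matrix a \code{\link{snp_matrix}} with \code{"?"} for missing.
#' @param n_total_samples total number of individuals in the study (may
#'   exceed the matrix sample count when some individuals are absent from
#'   the matrix entirely).
#' @param min_observed,min_minor,min_minor_full rule thresholds.
#' @return data.frame with one verdict per site: \code{site_id},
#'   \code{kept}, \code{n_observed}, \code{minor_count},
#'   \code{rule_applied} in \{full-coverage-rule, partial-coverage-rule,
#'   rejected-coverage, rejected-minor\}.
#' @export
robustness_filter <- function(matrix, n_total_samples = ncol(matrix),
                              min_observed = 6L, min_minor = 3L,
                              min_minor_full = 2L) {
  if (n_total_samples < ncol(matrix))
    stopf("n_total_samples (%d) below matrix sample count (%d)",
          n_total_samples, ncol(matrix))
  verdicts <- lapply(seq_len(nrow(matrix)), function(i) {
    x <- matrix[i, ]
    obs <- x[x != MISSING]
    tab <- sort(table(obs), decreasing = TRUE)
    if (length(tab) < 2L)
      stopf("site '%s' has fewer than 2 observed allele states",
            rownames(matrix)[i])
    n_obs <- length(obs)
    minor <- as.integer(tab[2L])  # second-most-frequent allele
    full <- n_obs == n_total_samples
    if (full && minor >= min_minor_full) {
      kept <- TRUE; rule <- "full-coverage-rule"
    } else if (n_obs >= min_observed && minor >= min_minor) {
      kept <- TRUE; rule <- "partial-coverage-rule"
    } else if (n_obs < min_observed && !full) {
      kept <- FALSE; rule <- "rejected-coverage"
    } else {
      kept <- FALSE; rule <- "rejected-minor"
    }
    data.frame(site_id = rownames(matrix)[i], kept = kept,
               n_observed = n_obs, minor_count = minor, rule_applied = rule,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, verdicts)
}

#' Flag loci with signs of paralogous alignment
#'
#' A locus is flagged when at least one individual contributes two or more
#' aligned contig sequences that disagree at \code{min_mismatch} or more
#' sites: a single haploid individual cannot carry two alleles, so
#' disagreement within an individual indicates co-aligned paralogs.
#' Flagged loci should be discarded before SNP scoring.
#'
#' @param locus_alignments named list; each element is a locus given as a
#'   named list mapping individual ids to character vectors of aligned
#'   (equal-length) contig sequences.
#' @param min_mismatch sites of within-individual disagreement required.
#' @return character vector of flagged locus ids.
#' @export
flag_paralogs <- function(locus_alignments, min_mismatch = 1L) {
  flagged <- vapply(locus_alignments, function(locus) {
    for (contigs in locus) {
      if (length(contigs) < 2L) next
      chars <- do.call(rbind, split_chars(contigs))
      mism <- sum(apply(chars, 2L, function(col) {
        col <- col[col != GAP & col != "N"]
        length(unique(col)) > 1L
      }))
      if (mism >= min_mismatch) return(TRUE)
    }
    FALSE
  }, NA)
  names(locus_alignments)[flagged]
}

#' Restrict a SNP matrix to complete-case sites
#'
#' Keeps only sites with an observed allele for every sample, preserving
#' site order.
#'
#' @param matrix a \code{\link{snp_matrix}}.
#' @export
complete_case_sites <- function(matrix) {
  keep <- rowSums(unclass(matrix) == MISSING) == 0L
  out <- matrix[keep, , drop = FALSE]
  if (!inherits(out, "snp_matrix")) class(out) <- c("snp_matrix", class(out))
  for (a in c("column", "ref_position"))
    if (!is.null(attr(matrix, a))) attr(out, a) <- attr(matrix, a)[keep]
  out
}

#' Read/write per-locus contig alignments
#'
#' Each locus is one aligned FASTA in \code{dir}, named
#' \code{<locus>.fasta}; sequence ids are individual ids, with \code{.2},
#' \code{.3} ... suffixes for additional contig copies of the same
#' individual.
#'
#' @param dir directory of per-locus FASTA files.
#' @return named list of loci, each a named list mapping individual id to
#'   a character vector of aligned contig sequences (the structure consumed
#'   by \code{\link{flag_paralogs}}).
#' @export
read_locus_alignments <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fa(sta)?$", full.names = TRUE))
  out <- lapply(files, function(f) {
    set <- Biostrings::readBStringSet(f)
    seqs <- toupper(as.character(set))
    ind <- sub("\\.[0-9]+$", "", sub("\\s.*$", "", names(set)))
    split(unname(seqs), ind)
  })
  stats::setNames(out, sub("\\.fa(sta)?$", "", basename(files)))
}

#' @rdname read_locus_alignments
#' @param locus_alignments structure as returned by
#'   \code{read_locus_alignments} (or \code{\link{simulate_mito_matrix}}).
#' @export
write_locus_alignments <- function(locus_alignments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lc in names(locus_alignments)) {
    locus <- locus_alignments[[lc]]
    seqs <- unlist(lapply(names(locus), function(ind) {
      v <- locus[[ind]]
      stats::setNames(v, if (length(v) == 1L) ind
                      else c(ind, paste0(ind, ".", seq_along(v)[-1L] )))
    }))
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs),
                                file.path(dir, paste0(lc, ".fasta")))
  }
  invisible(dir)
}

#' Write filter verdicts as TSV
#' @param verdicts data.frame from \code{\link{robustness_filter}}
#' @param path output file
#' @export
write_filter_verdicts <- function(verdicts, path) {
  utils::write.table(verdicts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a SNP allele matrix as TSV
#'
#' Format: first column \code{site_id}, remaining columns one per sample,
#' entries single characters with \code{?} (or \code{-}) for missing.
#'
#' @param path TSV file.
#' @param missing_chars characters to interpret as missing on read.
#' @export
read_snp_matrix <- function(path, missing_chars = c("?", "-")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m[m %in% missing_chars] <- MISSING
  m <- toupper(m)
  snp_matrix(m)
}

#' @rdname read_snp_matrix
#' @param matrix a \code{\link{snp_matrix}} to write.
#' @export
write_snp_matrix <- function(matrix, path) {
  df <- data.frame(site_id = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
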