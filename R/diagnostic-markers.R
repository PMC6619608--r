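# Screening for group-diagnostic SNPs (alleles that perfectly partition
# predefined geographic/taxonomic groups) and evaluation of short
# conserved-flank amplicon windows for ancient-DNA assay design.

#' Find group-diagnostic SNPs
#'
#' A site is diagnostic when every observed allele in group A equals one
#' base, every observed allele in group B equals a different base, and each
#' group is observed at least \code{min_obs_per_group} times at the site.
#' Missing entries are ignored; an optional outgroup sample is excluded
#' from the partition test and only recorded to polarise the variants.
#'
#' @param matrix a \code{\link{snp_matrix}}.
#' @param groups named list of two character vectors of sample ids (the
#'   names label the groups).
#' @param min_obs_per_group minimum observations per group at a site.
#' @param outgroup optional sample id excluded from the test.
#' @return data.frame, one row per site: group alleles, per-group observed
#'   counts, outgroup allele and the \code{diagnostic} flag.
#' @export
find_diagnostic_snps <- function(matrix, groups, min_obs_per_group = 2L,
                                 outgroup = NULL) {
  stopifnot(length(groups) == 2L)
  ids <- colnames(matrix)
  unknown <- setdiff(c(unlist(groups), outgroup), ids)
  if (length(unknown))
    stopf("group/outgroup sample(s) not in matrix: %s",
          paste(unknown, collapse = ", "))
  ga <- setdiff(groups[[1L]], outgroup)
  gb <- setdiff(groups[[2L]], outgroup)
  out <- lapply(seq_len(nrow(matrix)), function(i) {
    x <- matrix[i, ]
    a <- x[ga]; a <- a[a != MISSING]
    b <- x[gb]; b <- b[b != MISSING]
    og <- if (!is.null(outgroup)) x[[outgroup]] else MISSING
    ua <- unique(a); ub <- unique(b)
    diag <- length(ua) == 1L && length(ub) == 1L && ua != ub &&
      length(a) >= min_obs_per_group && length(b) >= min_obs_per_group
    data.frame(
      site_id = rownames(matrix)[i],
      group_a_allele = if (length(ua) == 1L) ua else NA_character_,
      group_b_allele = if (length(ub) == 1L) ub else NA_character_,
      n_observed_a = length(a), n_observed_b = length(b),
      outgroup_allele = if (og != MISSING) og else NA_character_,
      diagnostic = diag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out)[2:5] <- c(
    sprintf("%s_allele", c(names(groups)[1L], names(groups)[2L])),
    sprintf("n_observed_%s", c(names(groups)[1L], names(groups)[2L])))
  attr(out, "group_names") <- names(groups)
  out
}

#' Evaluate a short-amplicon window around a site
#'
#' Searches for the shortest window of length at least \code{min_len}
#' containing the site whose two terminal stretches of \code{flank_len}
#' columns are invariant across all samples and gap-free (usable primer
#' landing sites). Among windows of equal length the most site-centred
#' placement is preferred, ties resolved leftmost. Windows are reported in
#' ungapped reference coordinates.
#'
#' @param column 1-based alignment column of the target site.
#' @param aln the \code{genome_alignment}.
#' @param flank_len conserved flank length in columns (default 20).
#' @param min_len,max_len allowed amplicon length range in nt (defaults 60
#'   and 150, the practical size range for degraded sedimentary ancient
#'   DNA that still permits melt-curve screening).
#' @return list: \code{site_column}, \code{window} (c(start, end) reference
#'   interval or NA), \code{length}, \code{left_flank_conserved},
#'   \code{right_flank_conserved}, \code{usable}, \code{reason}.
#' @export
evaluate_amplicon_window <- function(column, aln, flank_len = 20L,
                                     min_len = 60L, max_len = 150L) {
  stopifnot(flank_len >= 1L)
  m <- aln_matrix(aln)
  L <- ncol(m)
  not_usable <- function(reason, left = FALSE, right = FALSE)
    list(site_column = column, window = c(NA_integer_, NA_integer_),
         length = NA_integer_, left_flank_conserved = left,
         right_flank_conserved = right, usable = FALSE, reason = reason)
  if (column - flank_len < 1L || column + flank_len > L)
    return(not_usable("site within one flank length of the alignment end"))
  # conserved = identical across rows, gap- and N-free
  cons <- vapply(seq_len(L), function(j) {
    x <- m[, j]
    all(x == x[1L]) && x[1L] != GAP && x[1L] != "N"
  }, NA)
  ccons <- cumsum(cons)
  flank_ok <- function(from) {  # flank_len columns starting at `from`
    ccons[from + flank_len - 1L] - (if (from > 1L) ccons[from - 1L] else 0L) ==
      flank_len
  }
  best <- NULL
  for (len in min_len:max_len) {
    starts <- max(1L, column - len + 1L):min(column, L - len + 1L)
    # prefer the most centred placement
    starts <- starts[order(abs((starts + (len - 1L) / 2) - column))]
    for (s in starts) {
      e <- s + len - 1L
      if (flank_ok(s) && flank_ok(e - flank_len + 1L)) { best <- c(s, e); break }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    lf <- flank_ok(column - flank_len)
    rf <- flank_ok(column + 1L)
    return(not_usable(sprintf(
      "no window of length %d..%d with conserved %d-nt flanks", min_len,
      max_len, flank_len), left = lf, right = rf))
  }
  refpos <- map_column_to_reference(aln, best)
  list(site_column = column,
       window = as.integer(refpos),
       length = best[2L] - best[1L] + 1L,
       left_flank_conserved = TRUE, right_flank_conserved = TRUE,
       usable = TRUE, reason = "ok")
}

#' Write diagnostic calls as TSV
#' @param calls data.frame from \code{\link{find_diagnostic_snps}}
#' @param path output file
#' @export
write_diagnostic_table <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write usable amplicon windows as BED
#'
#' BED uses 0-based half-open intervals; the internal 1-based closed
#' reference windows are converted accordingly.
#'
#' @param windows list of results from
#'   \code{\link{evaluate_amplicon_window}}.
#' @param chrom chromosome/contig name for column 1.
#' @param path output file.
#' @export
write_amplicon_bed <- function(windows, chrom, path) {
  usable <- Filter(function(w) isTRUE(w$usable), windows)
  lines <- vapply(usable, function(w)
    sprintf("%s\t%d\t%d\tamplicon_c%d\t%d\t+", chrom, w$window[1L] - 1L,
            w$window[2L], w$site_column, w$length), "")
  writeLines(lines, path)
  invisible(path)
}
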