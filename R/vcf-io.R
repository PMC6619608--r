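#' Write classified variant events as VCF 4.2
#'
#' SNPs are written as single-base records at their reference position.
#' Gapped events (InDels, homopolymer differences) are left-normalised and
#' anchored on the last reference base before the event. Inversions are
#' written as multi-nucleotide records. Genotypes are haploid indices into
#' REF/ALT; missing calls are encoded \code{./.}.
#'
#' @param events a \code{variant_events} data.frame from
#'   \code{\link{scan_alignment}}.
#' @param aln the \code{genome_alignment} the events were scanned from.
#' @param path output file.
#' @export
write_variants_vcf <- function(events, aln, path) {
  samples <- aln$sample_ids
  ref_id <- aln$reference_id
  refchars <- split_chars(aln$seqs[[ref_id]])[[1L]]
  refpos <- cumsum(refchars != GAP)

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref_id, reference_length(aln)),
    "##INFO=<ID=KIND,Number=1,Type=String,Description=\"Event class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))

  records <- character(0)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    al <- events$alleles[[i]][samples]
    ref_allele <- al[[ref_id]]
    gapped <- ev$kind %in% c("InDel", "HomopolymerDiff")
    if (gapped) {
      # anchor on the last reference base before the event
      before <- ev$col_start - 1L
      if (before < 1L || refpos[before] < 1L)
        stopf("cannot anchor event at column %d: no reference base before it",
              ev$col_start)
      pos <- refpos[before]
      anchor <- refchars[max(which(refchars != GAP & seq_along(refchars) <= before))]
      obs <- al[al != MISSING]
      lift <- function(a) paste0(anchor, a)
      ref_seq <- lift(ref_allele)
      alts <- setdiff(unique(vapply(obs, lift, "")), ref_seq)
    } else {
      if (is.na(ev$ref_start))
        stopf("cannot anchor event at column %d: reference is gapped",
              ev$col_start)
      pos <- ev$ref_start
      ref_seq <- ref_allele
      if (ref_seq == MISSING || ref_seq == "" )
        stopf("reference allele unavailable for event at column %d", ev$col_start)
      alts <- setdiff(unique(al[al != MISSING]), ref_seq)
    }
    if (!length(alts)) next  # reference-only event (all others missing)
    lookup <- c(ref_seq, alts)
    key_of <- if (gapped) function(a) paste0(anchor, a) else identity
    gt <- vapply(al, function(a) {
      if (a == MISSING) return("./.")
      as.character(match(key_of(a), lookup) - 1L)
    }, "")
    records <- c(records, paste(
      c(ref_id, pos, sprintf("%s_c%d", ev$kind, ev$col_start), ref_seq,
        paste(alts, collapse = ","), ".", "PASS",
        sprintf("KIND=%s", ev$kind), "GT", gt), collapse = "\t"))
  }
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read back a larchvar VCF
#'
#' Minimal reader for the files produced by \code{\link{write_variants_vcf}}
#' (single-allele-per-sample GT records); returns fixed fields plus a
#' sites-by-samples matrix of allele strings with \code{"?"} for missing.
#'
#' @param path VCF file.
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(sub("^#", "", body[1L]), "\t", fixed = TRUE)[[1L]]
  if (length(body) < 2L)
    return(list(fixed = data.frame(), genotypes = matrix(character(0), 0, 0)))
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  m <- do.call(rbind, rows)
  colnames(m) <- hdr
  samples <- hdr[-(1:9)]
  fixed <- data.frame(CHROM = m[, "CHROM"], POS = as.integer(m[, "POS"]),
                      ID = m[, "ID"], REF = m[, "REF"], ALT = m[, "ALT"],
                      INFO = m[, "INFO"], stringsAsFactors = FALSE)
  gt <- matrix(MISSING, nrow(m), length(samples),
               dimnames = list(fixed$ID, samples))
  for (i in seq_len(nrow(m))) {
    lookup <- c(fixed$REF[i], strsplit(fixed$ALT[i], ",", fixed = TRUE)[[1L]])
    idx <- suppressWarnings(as.integer(m[i, samples]))
    gt[i, !is.na(idx)] <- lookup[idx[!is.na(idx)] + 1L]
  }
  list(fixed = fixed, genotypes = gt)
}
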