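# Feature annotations live in a plain data.frame, one row per interval
# (exon), in transcription order within a feature:
#   name, kind (gene/tRNA/rRNA/pseudogene/intron/IR/other), strand (+/-),
#   start, end (1-based closed, ungapped reference coordinates), phase.

#' Validate a feature annotation table
#'
#' Checks interval sanity: spans ordered in transcription order within each
#' feature, non-overlapping, and (for protein-coding genes) a concatenated
#' exon length that is a multiple of 3 after phase adjustment.
#'
#' @param ann data.frame with columns \code{name}, \code{kind},
#'   \code{strand}, \code{start}, \code{end}, \code{phase}.
#' @return the validated (and column-ordered) data.frame, invisibly usable.
#' @export
validate_annotations <- function(ann) {
  required <- c("name", "kind", "strand", "start", "end", "phase")
  miss <- setdiff(required, names(ann))
  if (length(miss))
    stopf("annotation table missing column(s): %s", paste(miss, collapse = ", "))
  ann <- as.data.frame(ann)[, required]
  kinds <- c("gene", "tRNA", "rRNA", "pseudogene", "intron", "IR", "other")
  if (!all(ann$kind %in% kinds))
    stopf("unknown feature kind(s): %s",
          paste(unique(setdiff(ann$kind, kinds)), collapse = ", "))
  if (!all(ann$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  if (any(ann$start > ann$end)) stopf("interval with start > end")
  if (!all(ann$phase %in% 0:2)) stopf("phase must be 0, 1 or 2")
  for (nm in unique(ann$name)) {
    rows <- ann[ann$name == nm, , drop = FALSE]
    if (nrow(rows) > 1L) {
      ord <- if (rows$strand[1L] == "+") order(rows$start) else order(-rows$start)
      if (!identical(ord, seq_len(nrow(rows))))
        stopf("intervals of '%s' not in transcription order", nm)
      ir <- IRanges::IRanges(rows$start, rows$end)
      if (any(IRanges::countOverlaps(ir, ir) > 1L))
        stopf("overlapping intervals within feature '%s'", nm)
    }
    if (rows$kind[1L] == "gene") {
      cds_len <- sum(rows$end - rows$start + 1L) - rows$phase[1L]
      if (cds_len %% 3L != 0L)
        stopf("coding length of gene '%s' not a multiple of 3 after phase", nm)
    }
  }
  ann
}

#' Read feature annotations from GFF3
#'
#' GFF3 \code{CDS} rows map to kind \code{gene}; other types are carried
#' through verbatim when they match a known kind, anything else becomes
#' \code{other}.
#'
#' @param path GFF3 file.
#' @export
read_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  g <- as.data.frame(gr)
  df <- data.frame(
    name   = as.character(g$Name),
    kind   = as.character(g$type),
    strand = as.character(g$strand),
    start  = g$start,
    end    = g$end,
    phase  = if (!is.null(g$phase)) as.integer(g$phase) else 0L,
    stringsAsFactors = FALSE)
  df$kind[df$kind == "CDS"] <- "gene"
  df$kind[df$kind == "repeat_region"] <- "IR"
  df$kind[!df$kind %in% c("gene", "tRNA", "rRNA", "pseudogene", "intron", "IR")] <- "other"
  df$phase[is.na(df$phase)] <- 0L
  # restore transcription order for minus-strand multi-exon features
  ord <- order(match(df$name, unique(df$name)),
               ifelse(df$strand == "-", -df$start, df$start))
  validate_annotations(df[ord, , drop = FALSE])
}

#' Write feature annotations as GFF3
#'
#' @param ann annotation table (see \code{\link{validate_annotations}}).
#' @param seqid sequence name to place in column 1 (the reference id).
#' @param path output file.
#' @export
write_annotations <- function(ann, seqid, path) {
  ann <- validate_annotations(ann)
  type <- ann$kind
  type[type == "gene"] <- "CDS"
  type[type == "IR"] <- "repeat_region"
  lines <- c("##gff-version 3",
             sprintf("%s\tlarchvar\t%s\t%d\t%d\t.\t%s\t%s\tID=%s;Name=%s",
                     seqid, type, ann$start, ann$end, ann$strand,
                     ifelse(type == "CDS", ann$phase, "."),
                     make.unique(ann$name, sep = ".ex"), ann$name))
  writeLines(lines, path)
  invisible(path)
}
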