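#' Construct a genome alignment object
#'
#' Container for an equal-length multiple alignment of near-identical
#' (organelle) genomes, with one row per individual and a designated
#' reference row used for all coordinate reporting.
#'
#' @param seqs named character vector of aligned sequences over
#'   \code{A,C,G,T,N,-}; names are the sample ids.
#' @param reference_id id of the reference row.
#' @param circular logical flag recording that the underlying molecule is
#'   circular. Alignment columns are treated linearly; the flag is carried
#'   through to outputs.
#' @return an object of class \code{genome_alignment} with elements
#'   \code{sample_ids}, \code{seqs}, \code{reference_id}, \code{circular}.
#' @export
genome_alignment <- function(seqs, reference_id, circular = TRUE) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stopf("sequences must carry unique sample ids as names")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stopf("aligned rows differ in length: %s",
          paste(names(seqs)[widths != widths[1L]], collapse = ", "))
  if (widths[1L] < 1L) stopf("alignment has zero columns")
  if (!reference_id %in% names(seqs))
    stopf("reference_id '%s' is not among the sample ids", reference_id)
  seqs <- toupper(seqs)
  bad <- grepl(sprintf("^[%s]+$", GAP), seqs)
  if (any(bad))
    stopf("row(s) consisting only of gaps: %s",
          paste(names(seqs)[bad], collapse = ", "))
  # demote IUPAC ambiguity codes other than N to N
  amb <- grepl("[^ACGTN-]", seqs)
  if (any(amb)) {
    warning(sprintf("ambiguity codes demoted to N in: %s",
                    paste(names(seqs)[amb], collapse = ", ")), call. = FALSE)
    seqs <- gsub("[^ACGTN-]", "N", seqs)
  }
  structure(
    list(sample_ids = names(seqs), seqs = seqs,
         reference_id = reference_id, circular = circular),
    class = "genome_alignment")
}

#' @export
print.genome_alignment <- function(x, ...) {
  cat(sprintf("genome_alignment: %d samples x %d columns (reference: %s%s)\n",
              length(x$sample_ids), nchar(x$seqs[[1L]]), x$reference_id,
              if (x$circular) ", circular" else ""))
  invisible(x)
}

#' Alignment length (number of columns)
#' @param aln a \code{genome_alignment}
#' @export
alignment_length <- function(aln) nchar(aln$seqs[[1L]])

#' Read an aligned FASTA into a genome_alignment
#'
#' Thin wrapper around \code{Biostrings::readBStringSet} that validates
#' equal row lengths, normalises case and demotes non-N ambiguity codes.
#'
#' @param path aligned FASTA file.
#' @param reference_id sample id to use as coordinate reference.
#' @param circular see \code{\link{genome_alignment}}.
#' @export
read_alignment <- function(path, reference_id, circular = TRUE) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))  # id = first token
  genome_alignment(seqs, reference_id = reference_id, circular = circular)
}

#' Write a genome_alignment as aligned FASTA
#' @param aln a \code{genome_alignment}
#' @param path output file
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::BStringSet(aln$seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Map alignment columns to ungapped reference positions
#'
#' @param aln a \code{genome_alignment}
#' @param column integer vector of 1-based alignment columns.
#' @return integer vector: the 1-based position in the ungapped reference
#'   row, or \code{NA} where the reference is gapped at that column. The
#'   mapping is monotone non-decreasing and surjective onto
#'   \code{1..ungapped length}.
#' @export
map_column_to_reference <- function(aln, column) {
  len <- alignment_length(aln)
  column <- as.integer(column)
  if (any(is.na(column)) || any(column < 1L) || any(column > len))
    stopf("column out of range 1..%d", len)
  ref <- split_chars(aln$seqs[[aln$reference_id]])[[1L]]
  pos <- cumsum(ref != GAP)
  out <- pos[column]
  out[ref[column] == GAP] <- NA_integer_
  out
}

#' Length of the ungapped reference sequence
#' @param aln a \code{genome_alignment}
#' @export
reference_length <- function(aln) {
  ref <- aln$seqs[[aln$reference_id]]
  nchar(gsub(GAP, "", ref, fixed = TRUE))
}

#' Read the sample metadata table
#'
#' Expects a TSV with header columns \code{sample_code}, \code{region},
#' \code{site}, \code{latitude}, \code{longitude}, \code{vegetation_zone},
#' \code{species_range}, \code{accession} (accession may be empty).
#'
#' @param path TSV file.
#' @return data.frame, one row per individual, input order preserved.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          check.names = FALSE, na.strings = NULL)
  required <- c("sample_code", "region", "site", "latitude", "longitude",
                "vegetation_zone", "species_range", "accession")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stopf("sample table is missing column(s): %s", paste(miss, collapse = ", "))
  df <- df[, required]
  dup <- df$sample_code[duplicated(df$sample_code)]
  if (length(dup))
    stopf("duplicate sample_code: %s", paste(unique(dup), collapse = ", "))
  for (col in c("latitude", "longitude")) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) & nzchar(df[[col]]))
    if (length(bad))
      stopf("unparseable %s in row %d (sample %s)", col, bad[1L],
            df$sample_code[bad[1L]])
    df[[col]] <- val
  }
  if (any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE))
    stopf("latitude outside [-90, 90]")
  if (any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE))
    stopf("longitude outside [-180, 180]")
  df
}

#' Write a sample metadata table
#' @param samples data.frame as returned by \code{\link{read_sample_table}}
#' @param path output TSV
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
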