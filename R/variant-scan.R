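#' Scanner configuration
#'
#' @param homopolymer_min_run minimum length of the reference mononucleotide
#'   run adjacent to a gapped event for it to be classified as a
#'   homopolymer-length difference rather than a plain InDel.
#' @param inversion_min_span minimum number of consecutive substitution
#'   columns required before a reverse-complement block is called an
#'   inversion.
#' @export
scan_config <- function(homopolymer_min_run = 4L, inversion_min_span = 2L) {
  stopifnot(homopolymer_min_run >= 1L, inversion_min_span >= 2L)
  list(homopolymer_min_run = as.integer(homopolymer_min_run),
       inversion_min_span = as.integer(inversion_min_span))
}

#' Classify a base substitution as transition or transversion
#'
#' @param base_a,base_b two distinct bases in \code{A,C,G,T}.
#' @return \code{"transition"} (purine-purine or pyrimidine-pyrimidine) or
#'   \code{"transversion"}; symmetric in its arguments.
#' @export
classify_substitution <- function(base_a, base_b) {
  if (!base_a %in% DNA_BASES || !base_b %in% DNA_BASES)
    stopf("bases must be one of A,C,G,T (got '%s','%s')", base_a, base_b)
  if (base_a == base_b) stopf("bases are identical ('%s')", base_a)
  purine <- c("A", "G")
  if ((base_a %in% purine) == (base_b %in% purine)) "transition" else "transversion"
}

#' Detect and classify variation events in a genome alignment
#'
#' Partitions the polymorphic columns of the alignment into disjoint events:
#' maximal gapped-column runs become InDels (or homopolymer-length
#' differences when the gapped bases extend a reference mononucleotide run),
#' maximal substitution-column runs whose two allele strings are reverse
#' complements become inversions, and remaining substitution columns are
#' SNPs. Classification precedence is Inversion > HomopolymerDiff > InDel >
#' SNP; a monomorphic alignment yields an empty event table.
#'
#' @param aln a \code{genome_alignment}.
#' @param config a \code{\link{scan_config}}.
#' @return data.frame of class \code{variant_events} with columns
#'   \code{kind}, \code{col_start}, \code{col_end}, \code{ref_start},
#'   \code{ref_end}, \code{substitution_class}, \code{is_singleton} and a
#'   list column \code{alleles} (named per-sample allele strings; \code{""}
#'   is a deletion, \code{"?"} missing).
#' @export
scan_alignment <- function(aln, config = scan_config()) {
  m <- aln_matrix(aln)
  L <- ncol(m)
  samples <- rownames(m)
  ref_row <- aln$seqs[[aln$reference_id]]
  refchars <- split_chars(ref_row)[[1L]]
  refpos <- cumsum(refchars != GAP)

  empty <- data.frame(kind = character(0), col_start = integer(0),
                      col_end = integer(0), ref_start = integer(0),
                      ref_end = integer(0), substitution_class = character(0),
                      is_singleton = logical(0))
  empty$alleles <- list()

  # columns worth inspecting: any row differs from row 1
  neq <- m != matrix(m[1L, ], nrow(m), L, byrow = TRUE)
  varcols <- which(colSums(neq) > 0L)
  if (!length(varcols)) { class(empty) <- c("variant_events", "data.frame"); return(empty) }

  has_gap <- varcols[vapply(varcols, function(j) any(m[, j] == GAP), NA)]
  is_sub <- function(j) {
    x <- m[, j]
    obs <- x[x != "N" & x != GAP]
    length(unique(obs)) >= 2L
  }
  subcols <- setdiff(varcols, has_gap)
  subcols <- subcols[vapply(subcols, is_sub, NA)]

  events <- list()

  runs_of <- function(cols) {
    if (!length(cols)) return(list())
    brk <- c(0L, which(diff(cols) > 1L), length(cols))
    lapply(seq_len(length(brk) - 1L),
           function(k) cols[(brk[k] + 1L):brk[k + 1L]])
  }

  block_alleles <- function(cs, ce, strip_gaps = TRUE) {
    block <- m[, cs:ce, drop = FALSE]
    al <- apply(block, 1L, paste, collapse = "")
    has_n <- grepl("N", al, fixed = TRUE)
    if (strip_gaps) al <- gsub(GAP, "", al, fixed = TRUE)
    al[has_n] <- MISSING
    names(al) <- samples
    al
  }

  ref_coord <- function(j) if (refchars[j] == GAP) NA_integer_ else refpos[j]

  # gapped events: InDel vs homopolymer-length difference
  for (run in runs_of(has_gap)) {
    cs <- run[1L]; ce <- run[length(run)]
    al <- block_alleles(cs, ce)
    blockchars <- unique(as.vector(m[, cs:ce, drop = FALSE]))
    bases <- setdiff(blockchars, c(GAP, "N"))
    kind <- "InDel"
    if (length(bases) == 1L) {
      x <- bases
      # reference mononucleotide run through/around the event
      n_run <- sum(refchars[cs:ce] == x)
      j <- cs - 1L
      while (j >= 1L && refchars[j] %in% c(x, GAP)) {
        if (refchars[j] == x) n_run <- n_run + 1L
        j <- j - 1L
      }
      j <- ce + 1L
      while (j <= L && refchars[j] %in% c(x, GAP)) {
        if (refchars[j] == x) n_run <- n_run + 1L
        j <- j + 1L
      }
      if (n_run >= config$homopolymer_min_run) kind <- "HomopolymerDiff"
    }
    events[[length(events) + 1L]] <- list(
      kind = kind, col_start = cs, col_end = ce,
      ref_start = ref_coord(cs), ref_end = ref_coord(ce),
      substitution_class = NA_character_, is_singleton = NA, alleles = al)
  }

  # substitution events: inversion blocks, otherwise per-column SNPs
  for (run in runs_of(subcols)) {
    emitted_inversion <- FALSE
    if (length(run) >= config$inversion_min_span &&
        all(diff(run) == 1L)) {
      al <- block_alleles(run[1L], run[length(run)], strip_gaps = FALSE)
      obs <- unique(al[al != MISSING])
      if (length(obs) == 2L && identical(revcomp_chr(obs[1L]), obs[2L])) {
        events[[length(events) + 1L]] <- list(
          kind = "Inversion", col_start = run[1L], col_end = run[length(run)],
          ref_start = ref_coord(run[1L]), ref_end = ref_coord(run[length(run)]),
          substitution_class = NA_character_, is_singleton = NA, alleles = al)
        emitted_inversion <- TRUE
      }
    }
    if (!emitted_inversion) {
      for (j in run) {
        x <- m[, j]
        al <- ifelse(x == "N" | x == GAP, MISSING, x)
        names(al) <- samples
        tab <- table(al[al != MISSING])
        cls <- if (length(tab) == 2L)
          classify_substitution(names(tab)[1L], names(tab)[2L])
        else NA_character_
        minor <- minor_allele(tab)
        events[[length(events) + 1L]] <- list(
          kind = "SNP", col_start = j, col_end = j,
          ref_start = ref_coord(j), ref_end = ref_coord(j),
          substitution_class = cls,
          is_singleton = sum(al == minor) == 1L, alleles = al)
      }
    }
  }

  ord <- order(vapply(events, `[[`, 0L, "col_start"))
  events <- events[ord]
  out <- data.frame(
    kind = vapply(events, `[[`, "", "kind"),
    col_start = vapply(events, `[[`, 0L, "col_start"),
    col_end = vapply(events, `[[`, 0L, "col_end"),
    ref_start = vapply(events, function(e) e$ref_start %||% NA_integer_, 0L),
    ref_end = vapply(events, function(e) e$ref_end %||% NA_integer_, 0L),
    substitution_class = vapply(events, `[[`, "", "substitution_class"),
    is_singleton = vapply(events, `[[`, NA, "is_singleton"),
    stringsAsFactors = FALSE)
  out$alleles <- lapply(events, `[[`, "alleles")
  class(out) <- c("variant_events", "data.frame")
  out
}

#' @export
print.variant_events <- function(x, ...) {
  cat(sprintf("variant_events: %d events (%s)\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$kind)), table(x$kind)),
                    collapse = ", ")))
  invisible(x)
}

#' Build a SNP allele matrix from scanned events
#'
#' Keeps SNP events only; one row (site) per SNP, one column per sample,
#' entries in \code{A,C,G,T,?}.
#'
#' @param events a \code{variant_events} data.frame.
#' @param sample_ids column names to use when there are no SNP events (the
#'   allele vectors carry the names otherwise).
#' @return a \code{\link{snp_matrix}}; site ids are \code{c<column>} and the
#'   matrix carries \code{ref_position} and \code{column} attributes.
#' @export
snp_matrix_from_events <- function(events, sample_ids = NULL) {
  snps <- events[events$kind == "SNP", , drop = FALSE]
  if (!nrow(snps)) {
    m <- matrix(character(0), 0L, length(sample_ids),
                dimnames = list(NULL, sample_ids))
    return(snp_matrix(m, validate = FALSE))
  }
  m <- do.call(rbind, snps$alleles)
  rownames(m) <- sprintf("c%d", snps$col_start)
  out <- snp_matrix(m)
  attr(out, "column") <- snps$col_start
  attr(out, "ref_position") <- snps$ref_start
  out
}

#' SNP allele matrix
#'
#' Sites-by-samples single-character matrix over \code{A,C,G,T,?}; every
#' site must segregate (at least two distinct observed alleles) unless
#' \code{validate = FALSE}.
#'
#' @param m character matrix with site rownames and sample colnames.
#' @param validate check the segregation invariant.
#' @export
snp_matrix <- function(m, validate = TRUE) {
  stopifnot(is.matrix(m))
  if (validate && nrow(m)) {
    ok <- apply(m, 1L, function(x) length(unique(x[x != MISSING])) >= 2L)
    if (!all(ok))
      stopf("site(s) with fewer than 2 observed alleles: %s",
            paste(rownames(m)[!ok], collapse = ", "))
  }
  class(m) <- c("snp_matrix", class(m))
  m
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d sites x %d samples (%.1f%% missing)\n",
              nrow(x), ncol(x),
              if (length(x)) 100 * mean(unclass(x) == MISSING) else 0))
  invisible(x)
}

#' Absolute pairwise differences between samples
#'
#' Entry (i, j) counts sites where both samples have an observed allele and
#' the alleles differ; the matrix is symmetric with zero diagonal.
#'
#' @param matrix a \code{\link{snp_matrix}}.
#' @export
pairwise_differences <- function(matrix) {
  n <- ncol(matrix)
  ids <- colnames(matrix)
  d <- base::matrix(0L, n, n, dimnames = list(ids, ids))
  if (!nrow(matrix)) return(d)
  obs <- unclass(matrix) != MISSING
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- obs[, i] & obs[, j]
    d[i, j] <- d[j, i] <- sum(both & matrix[, i] != matrix[, j])
  }
  d
}

#' Summary statistics over scanned events
#'
#' @param aln the scanned \code{genome_alignment}.
#' @param events the \code{variant_events} from \code{\link{scan_alignment}}.
#' @return list of class \code{variant_summary}: event counts, transition /
#'   transversion fractions, the six unordered substitution-pair fractions
#'   (multi-allelic sites contribute one pair per non-majority allele
#'   against the majority allele), singleton count, reference GC content and
#'   per-sample unique-SNP counts.
#' @export
summarize_variants <- function(aln, events) {
  snps <- events[events$kind == "SNP", , drop = FALSE]
  pair_names <- c("A<->G", "C<->T", "A<->C", "A<->T", "C<->G", "G<->T")
  pair_counts <- stats::setNames(integer(6), pair_names)
  n_singleton <- 0L
  unique_per_sample <- stats::setNames(integer(length(aln$sample_ids)),
                                       aln$sample_ids)
  for (i in seq_len(nrow(snps))) {
    al <- snps$alleles[[i]]
    tab <- table(al[al != MISSING])
    maj <- major_allele(tab)
    for (a in setdiff(names(tab), maj)) {
      key <- paste(sort(c(maj, a)), collapse = "<->")
      pair_counts[key] <- pair_counts[key] + 1L
    }
    minor <- minor_allele(tab)
    if (sum(al == minor) == 1L) {
      n_singleton <- n_singleton + 1L
      carrier <- names(al)[al == minor]
      unique_per_sample[carrier] <- unique_per_sample[carrier] + 1L
    }
  }
  n_pairs <- sum(pair_counts)
  pair_frac <- if (n_pairs) pair_counts / n_pairs else pair_counts * 0
  ts <- sum(pair_frac[c("A<->G", "C<->T")])
  refseq <- gsub(GAP, "", aln$seqs[[aln$reference_id]], fixed = TRUE)
  base_tab <- table(split_chars(refseq)[[1L]])
  acgt <- sum(base_tab[intersect(names(base_tab), DNA_BASES)])
  gc <- sum(base_tab[intersect(names(base_tab), c("G", "C"))]) / acgt
  structure(list(
    n_snp = nrow(snps),
    n_indel = sum(events$kind == "InDel"),
    n_homopolymer = sum(events$kind == "HomopolymerDiff"),
    n_inversion = sum(events$kind == "Inversion"),
    ts_fraction = if (n_pairs) ts else NA_real_,
    tv_fraction = if (n_pairs) 1 - ts else NA_real_,
    pair_fractions = pair_frac,
    n_singleton = n_singleton,
    gc_content = as.numeric(gc),
    unique_snps_per_sample = unique_per_sample),
    class = "variant_summary")
}

#' @export
print.variant_summary <- function(x, ...) {
  cat(sprintf(paste0("variant_summary: %d SNPs (%d singletons), %d InDels, ",
                     "%d homopolymer diffs, %d inversions\n"),
              x$n_snp, x$n_singleton, x$n_indel, x$n_homopolymer,
              x$n_inversion))
  if (!is.na(x$ts_fraction))
    cat(sprintf("  transitions %.1f%% / transversions %.1f%%; reference GC %.2f%%\n",
                100 * x$ts_fraction, 100 * x$tv_fraction, 100 * x$gc_content))
  invisible(x)
}

#' Write the per-site variant table as TSV
#'
#' @param events \code{variant_events}.
#' @param path output TSV; per-sample allele columns follow the fixed
#'   columns.
#' @export
write_variant_table <- function(events, path) {
  al <- do.call(rbind, events$alleles)
  fixed <- events[, c("kind", "col_start", "col_end", "ref_start", "ref_end",
                      "substitution_class", "is_singleton")]
  utils::write.table(cbind(fixed, al), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
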