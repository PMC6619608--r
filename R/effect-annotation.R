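# Coding-effect annotation of SNPs: feature context, codon and amino-acid
# change under the bacterial/plastid genetic code (translation table 11),
# and amino-acid property-class changes.

#' Default amino-acid property scheme
#'
#' Total mapping of the 20 residues onto five classes: basic (R, K, H),
#' acid/amide (D, E, N, Q), hydrophilic (S, T, A, P, G), hydrophobic (V, I,
#' L, M, F, W, Y) and special (C). Cysteine sits in its own class because
#' its disulfide chemistry fits neither the hydrophobic nor the hydrophilic
#' group cleanly. The scheme is a plain named vector and can be replaced
#' wholesale by the caller.
#'
#' @export
default_property_scheme <- function() {
  c(R = "basic", K = "basic", H = "basic",
    D = "acid/amide", E = "acid/amide", N = "acid/amide", Q = "acid/amide",
    S = "hydrophilic", T = "hydrophilic", A = "hydrophilic",
    P = "hydrophilic", G = "hydrophilic",
    V = "hydrophobic", I = "hydrophobic", L = "hydrophobic",
    M = "hydrophobic", F = "hydrophobic", W = "hydrophobic",
    Y = "hydrophobic",
    C = "special")
}

#' Classify an amino-acid substitution by property class
#'
#' @param ref_aa,alt_aa single-letter residues.
#' @param scheme named class vector, by default
#'   \code{\link{default_property_scheme}}.
#' @return list with \code{ref_property}, \code{alt_property} and logical
#'   \code{changed}.
#' @export
property_change <- function(ref_aa, alt_aa, scheme = default_property_scheme()) {
  for (aa in c(ref_aa, alt_aa))
    if (!aa %in% names(scheme)) stopf("unknown residue '%s'", aa)
  ref_p <- unname(scheme[[ref_aa]])
  alt_p <- unname(scheme[[alt_aa]])
  list(ref_property = ref_p, alt_property = alt_p, changed = ref_p != alt_p)
}

#' Locate a reference position in the annotation
#'
#' @param position 1-based ungapped reference coordinate.
#' @param annotations validated annotation table.
#' @return list with \code{context} (one of CDS, tRNA, rRNA, pseudogene,
#'   intron, intergenic) and \code{feature} (name or \code{"intergenic"}).
#'   When several feature kinds cover the position the most specific coding
#'   context wins (CDS, then tRNA, rRNA, pseudogene, intron).
#' @export
locate_site <- function(position, annotations) {
  if (is.na(position)) stopf("site has no reference coordinate (alignment gap)")
  ir <- IRanges::IRanges(annotations$start, annotations$end)
  hit <- IRanges::overlapsAny(ir, IRanges::IRanges(position, position))
  hits <- annotations[hit, , drop = FALSE]
  if (!nrow(hits)) return(list(context = "intergenic", feature = "intergenic"))
  pref <- c(gene = 1L, tRNA = 2L, rRNA = 3L, pseudogene = 4L, intron = 5L,
            IR = 6L, other = 7L)
  best <- hits[order(pref[hits$kind])[1L], ]
  context <- switch(best$kind, gene = "CDS", IR = "intergenic",
                    other = "intergenic", best$kind)
  feature <- if (context == "intergenic") "intergenic" else best$name
  list(context = context, feature = feature)
}

#' Spliced coding sequence of a feature from the ungapped reference
#' @noRd
spliced_cds <- function(feature_rows, refseq_chars) {
  pieces <- lapply(seq_len(nrow(feature_rows)), function(k) {
    iv <- feature_rows[k, ]
    chars <- refseq_chars[iv$start:iv$end]
    if (iv$strand == "-") rev(chartr("ACGTN", "TGCAN", chars)) else chars
  })
  cds <- unlist(pieces)
  phase <- feature_rows$phase[1L]
  if (phase > 0L) cds <- cds[-seq_len(phase)]
  cds
}

#' Map a reference position to its 0-based offset within the spliced CDS
#' @noRd
cds_offset <- function(position, feature_rows) {
  offset <- 0L
  for (k in seq_len(nrow(feature_rows))) {
    iv <- feature_rows[k, ]
    w <- iv$end - iv$start + 1L
    if (position >= iv$start && position <= iv$end) {
      within <- if (iv$strand == "+") position - iv$start else iv$end - position
      return(offset + within - feature_rows$phase[1L])
    }
    offset <- offset + w
  }
  NA_integer_
}

#' Call the coding effect of a SNP
#'
#' Assembles the codon across exon boundaries in transcription order
#' (reverse-complemented for minus-strand features), translates reference
#' and alternate codons with genetic code table 11 and classifies the
#' amino-acid change. An allele that introduces a premature stop is
#' reported (\code{alt_aa == "*"}), not an error.
#'
#' @param position 1-based ungapped reference position of the SNP.
#' @param ref_base,alt_base reference and alternate alleles (plus-strand
#'   bases, as observed in the alignment).
#' @param feature_name name of the protein-coding feature hit.
#' @param annotations validated annotation table.
#' @param aln the \code{genome_alignment} supplying the reference sequence.
#' @param scheme property scheme for non-synonymous calls.
#' @return list of class \code{effect_call}: \code{feature},
#'   \code{context}, \code{codon_index}, \code{ref_aa}, \code{alt_aa},
#'   \code{synonymous}, \code{ref_property}, \code{alt_property},
#'   \code{property_changed} (property fields are \code{NA} for synonymous
#'   calls).
#' @export
call_effect <- function(position, ref_base, alt_base, feature_name,
                        annotations, aln,
                        scheme = default_property_scheme()) {
  rows <- annotations[annotations$name == feature_name &
                        annotations$kind == "gene", , drop = FALSE]
  if (!nrow(rows)) stopf("'%s' is not an annotated protein-coding gene",
                         feature_name)
  refseq <- gsub(GAP, "", aln$seqs[[aln$reference_id]], fixed = TRUE)
  refchars <- split_chars(refseq)[[1L]]
  cds <- spliced_cds(rows, refchars)
  if (length(cds) %% 3L != 0L)
    stopf("incomplete terminal codon in feature '%s'", feature_name)
  off <- cds_offset(position, rows)
  if (is.na(off) || off < 0L)
    stopf("position %d not inside the coding part of '%s'", position,
          feature_name)
  strand <- rows$strand[1L]
  ref_b <- if (strand == "-") chartr("ACGT", "TGCA", ref_base) else ref_base
  alt_b <- if (strand == "-") chartr("ACGT", "TGCA", alt_base) else alt_base
  if (cds[off + 1L] != ref_b)
    stopf("reference allele mismatch at %d in '%s' (CDS has %s, allele %s)",
          position, feature_name, cds[off + 1L], ref_b)
  codon_index <- off %/% 3L + 1L
  codon_from <- (codon_index - 1L) * 3L + 1L
  ref_codon <- paste(cds[codon_from:(codon_from + 2L)], collapse = "")
  alt_cds <- cds
  alt_cds[off + 1L] <- alt_b
  alt_codon <- paste(alt_cds[codon_from:(codon_from + 2L)], collapse = "")
  code <- Biostrings::getGeneticCode("11")
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  syn <- identical(ref_aa, alt_aa)
  prop <- if (!syn && ref_aa %in% names(scheme) && alt_aa %in% names(scheme))
    property_change(ref_aa, alt_aa, scheme)
  else list(ref_property = NA_character_, alt_property = NA_character_,
            changed = NA)
  structure(list(feature = feature_name, context = "CDS",
                 codon_index = codon_index, ref_aa = ref_aa, alt_aa = alt_aa,
                 synonymous = syn,
                 ref_property = if (syn) NA_character_ else prop$ref_property,
                 alt_property = if (syn) NA_character_ else prop$alt_property,
                 property_changed = if (syn) NA else prop$changed),
            class = "effect_call")
}

#' Annotate all SNP events with their coding context and effect
#'
#' @param events \code{variant_events} from \code{\link{scan_alignment}}.
#' @param annotations validated annotation table.
#' @param aln the scanned \code{genome_alignment}.
#' @param scheme property scheme.
#' @return data.frame, one row per SNP event: site column/position, context,
#'   feature and (for CDS SNPs) codon index, amino-acid change, property
#'   classes. Pseudogenes are never translated; their effect fields stay
#'   \code{NA}.
#' @export
annotate_effects <- function(events, annotations, aln,
                             scheme = default_property_scheme()) {
  snps <- events[events$kind == "SNP", , drop = FALSE]
  annotations <- validate_annotations(annotations)
  ref_id <- aln$reference_id
  out <- data.frame(
    site = sprintf("c%d", snps$col_start), column = snps$col_start,
    ref_position = snps$ref_start, context = NA_character_,
    feature = NA_character_, codon_index = NA_integer_,
    ref_aa = NA_character_, alt_aa = NA_character_, synonymous = NA,
    ref_property = NA_character_, alt_property = NA_character_,
    property_changed = NA, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(snps))) {
    pos <- snps$ref_start[i]
    loc <- locate_site(pos, annotations)
    out$context[i] <- loc$context
    out$feature[i] <- loc$feature
    if (loc$context != "CDS") next
    al <- snps$alleles[[i]]
    ref_base <- al[[ref_id]]
    alt <- setdiff(unique(al[al != MISSING]), ref_base)
    if (ref_base == MISSING || !length(alt)) next
    # multi-allelic: annotate against the first alternate allele in base order
    eff <- call_effect(pos, ref_base, sort(alt)[1L], loc$feature,
                       annotations, aln, scheme)
    out$codon_index[i] <- eff$codon_index
    out$ref_aa[i] <- eff$ref_aa
    out$alt_aa[i] <- eff$alt_aa
    out$synonymous[i] <- eff$synonymous
    out$ref_property[i] <- eff$ref_property
    out$alt_property[i] <- eff$alt_property
    out$property_changed[i] <- eff$property_changed
  }
  out
}

#' Count coding-effect categories
#'
#' @param effects data.frame from \code{\link{annotate_effects}} (or any
#'   table with \code{context}, \code{synonymous}, \code{property_changed}).
#' @return list: \code{n_coding} (CDS plus structural-RNA gene hits),
#'   \code{n_noncoding}, \code{n_nonsynonymous}, \code{n_property_changed},
#'   \code{n_in_tRNA}.
#' @export
count_effects <- function(effects) {
  in_gene <- effects$context %in% c("CDS", "tRNA", "rRNA")
  nonsyn <- !is.na(effects$synonymous) & !effects$synonymous
  list(
    n_coding = sum(in_gene),
    n_noncoding = sum(!in_gene),
    n_nonsynonymous = sum(nonsyn),
    n_property_changed = sum(nonsyn & !is.na(effects$property_changed) &
                               effects$property_changed),
    n_in_tRNA = sum(effects$context == "tRNA"))
}

#' Write the effect table as TSV
#' @param effects data.frame from \code{\link{annotate_effects}}
#' @param path output file
#' @export
write_effect_table <- function(effects, path) {
  utils::write.table(effects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
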