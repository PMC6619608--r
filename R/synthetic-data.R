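# Synthetic study generator: a toy circular organelle genome alignment for
# a three-region sample of individuals, with planted SNPs (configurable
# transition mix and group-diagnostic sites), InDels, homopolymer-length
# differences and one reverse-complement (stem-loop) inversion, plus a
# mitochondrial-style allele matrix with missingness and paralog-
# contaminated loci. Every planted event is recorded in a truth table so
# downstream stages can be validated exactly.

#' Simulation configuration
#'
#' Defaults mirror the study conditions the pipeline was built around: 19
#' individuals in three regions (12/4/3), 84 SNPs with a 44% transition
#' share, 5 InDels, 17 homopolymer stretch differences, one 3-nt stem-loop
#' inversion, 8 group-diagnostic sites and a reference GC content of
#' 38.74%, on a 20 kb toy genome.
#'
#' @param seed RNG seed; identical seeds give bit-identical outputs.
#' @param n_samples number of individuals.
#' @param group_sizes named per-region counts summing to \code{n_samples};
#'   the first region plays the role of the western group.
#' @param genome_length reference length in nt.
#' @param n_snp,n_indel,n_homopolymer,n_inversion planted event counts.
#' @param transition_prob probability a planted SNP is a transition.
#' @param n_diagnostic planted group-diagnostic sites (first region vs the
#'   rest); counted among \code{n_snp} in the alignment.
#' @param gc_content reference base composition knob.
#' @param n_genes protein-coding genes (at least 2: one multi-exon, one on
#'   the reverse strand).
#' @param missing_rate per-cell missingness of the mitochondrial-style
#'   matrix.
#' @param n_mito_sites,n_complete_sites sites in the mitochondrial-style
#'   matrix and how many of them are left fully observed.
#' @param n_loci,n_paralog_loci mitochondrial loci and how many carry
#'   planted paralog contamination.
#' @export
sim_config <- function(seed = 1L, n_samples = 19L,
                       group_sizes = c(Taymyr = 12L, Omoloy = 4L, Kolyma = 3L),
                       genome_length = 20000L,
                       n_snp = 84L, n_indel = 5L, n_homopolymer = 17L,
                       n_inversion = 1L, transition_prob = 0.44,
                       n_diagnostic = 8L, gc_content = 0.3874,
                       n_genes = 6L, missing_rate = 0.2,
                       n_mito_sites = 60L, n_complete_sites = 16L,
                       n_loci = 10L, n_paralog_loci = 2L) {
  if (sum(group_sizes) != n_samples)
    stopf("group_sizes sum (%d) != n_samples (%d)", sum(group_sizes), n_samples)
  if (missing_rate >= 1) stopf("missing_rate must be < 1")
  if (n_diagnostic > n_snp) stopf("n_diagnostic cannot exceed n_snp")
  if (n_genes < 2L) stopf("need at least 2 genes")
  as.list(environment())
}

#' @noRd
rand_bases <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Random stop-free CDS of n_codons codons (ATG ... stop)
#' @noRd
rand_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(n_codons)
  codons[1L] <- "ATG"
  all_codons <- setdiff(apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES),
                              1L, paste, collapse = ""), stops)
  codons[2:(n_codons - 1L)] <- sample(all_codons, n_codons - 2L, replace = TRUE)
  codons[n_codons] <- "TAA"
  paste(codons, collapse = "")
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

#' @noRd
pick_alt <- function(ref, transition_prob) {
  if (stats::runif(1) < transition_prob) {
    c(TRANSITION_OF[[ref]], "transition")
  } else {
    tv <- setdiff(DNA_BASES, c(ref, TRANSITION_OF[[ref]]))
    c(sample(tv, 1L), "transversion")
  }
}

#' Simulate an aligned chloroplast-like genome set with planted truth
#'
#' @param config a \code{\link{sim_config}}.
#' @return list: \code{alignment} (a \code{genome_alignment}; the first
#'   sample is the reference row), \code{annotations} (feature table),
#'   \code{samples} (metadata data.frame), \code{truth} (planted event
#'   table with per-event carriers, alleles, expected class, diagnostic
#'   flag and, for coding SNPs, the expected amino-acid change), and
#'   \code{config}.
#' @export
simulate_alignment_set <- function(config = sim_config()) {
  set.seed(config$seed)
  L <- config$genome_length
  n <- config$n_samples
  sample_ids <- sprintf("S%02d", seq_len(n))
  regions <- rep(names(config$group_sizes), config$group_sizes)
  names(regions) <- sample_ids
  ref_id <- sample_ids[1L]

  genome <- rand_bases(L, config$gc_content)

  ## --- features -------------------------------------------------------
  ann <- list()
  cursor <- 151L
  add_feature <- function(name, kind, strand, spans, phase = 0L) {
    ann[[length(ann) + 1L]] <<- data.frame(
      name = name, kind = kind, strand = strand,
      start = vapply(spans, `[[`, 0L, 1L), end = vapply(spans, `[[`, 0L, 2L),
      phase = phase, stringsAsFactors = FALSE)
  }
  truth_cds <- list()  # per-gene spliced CDS + exon layout for effect truth
  for (g in seq_len(config$n_genes)) {
    n_codons <- sample(80:160, 1L)
    cds <- rand_cds(n_codons)
    cds_chars <- strsplit(cds, "")[[1L]]
    glen <- 3L * n_codons
    name <- sprintf("gene%02d", g)
    strand <- if (g == 2L) "-" else "+"
    if (g == 1L) {
      # multi-exon: split at a random interior codon-independent point
      cut <- sample(30:(glen - 30L), 1L)
      intron_len <- 61L
      e1 <- c(cursor, cursor + cut - 1L)
      e2 <- c(e1[2L] + intron_len + 1L, e1[2L] + intron_len + glen - cut)
      genome[e1[1L]:e1[2L]] <- cds_chars[1:cut]
      genome[e2[1L]:e2[2L]] <- cds_chars[(cut + 1L):glen]
      add_feature(name, "gene", "+", list(e1, e2))
      add_feature(paste0(name, "_intron"), "intron", "+",
                  list(c(e1[2L] + 1L, e2[1L] - 1L)))
      truth_cds[[name]] <- list(cds = cds_chars, strand = "+",
                                exons = list(e1, e2))
      cursor <- e2[2L] + sample(120:250, 1L)
    } else {
      span <- c(cursor, cursor + glen - 1L)
      seg <- if (strand == "-") rev(chartr("ACGT", "TGCA", cds_chars)) else cds_chars
      genome[span[1L]:span[2L]] <- seg
      add_feature(name, "gene", strand, list(span))
      truth_cds[[name]] <- list(cds = cds_chars, strand = strand,
                                exons = list(span))
      cursor <- span[2L] + sample(120:250, 1L)
    }
  }
  add_feature("trnX", "tRNA", "+", list(c(cursor, cursor + 74L)))
  cursor <- cursor + 75L + sample(80:150, 1L)
  add_feature("rrnY", "rRNA", "+", list(c(cursor, cursor + 119L)))
  cursor <- cursor + 120L + sample(80:150, 1L)
  add_feature("psiZ", "pseudogene", "+", list(c(cursor, cursor + 199L)))
  cursor <- cursor + 200L + 50L
  annotations <- do.call(rbind, ann)
  if (max(annotations$end) > L - 500L)
    stopf("genome_length too small for %d genes", config$n_genes)

  ## --- event placement ------------------------------------------------
  free <- rep(TRUE, L)
  free[1:50] <- FALSE
  free[(L - 49L):L] <- FALSE
  for (i in seq_len(nrow(annotations)))  # keep structural events off genes
    free[max(1L, annotations$start[i] - 5L):min(L, annotations$end[i] + 5L)] <- FALSE

  pick_locus <- function(width, margin) {
    cf <- cumsum(free)
    need <- width + 2L * margin
    idx <- seq_len(L - need + 1L)
    ok <- (cf[idx + need - 1L] - c(0L, cf)[idx]) == need
    starts <- idx[ok]
    if (!length(starts)) stopf("infeasible config: cannot place all events")
    s <- if (length(starts) == 1L) starts else sample(starts, 1L)
    free[s:(s + need - 1L)] <<- FALSE
    s + margin  # event start
  }

  truth <- list()
  add_truth <- function(...) truth[[length(truth) + 1L]] <<- list(...)
  carriers_of <- function(k) sort(sample(sample_ids[-1L], k))
  rand_carrier_count <- function() {
    if (stats::runif(1) < 0.7) 1L else sample(2:(n - 2L), 1L)
  }

  # homopolymer runs (written into the reference, shortened in carriers)
  for (h in seq_len(config$n_homopolymer)) {
    run_len <- sample(5:8, 1L)
    s <- pick_locus(run_len, 25L)
    x <- sample(DNA_BASES, 1L)
    genome[s:(s + run_len - 1L)] <- x
    # neighbours must differ from x so the run length is exactly run_len
    if (genome[s - 1L] == x) genome[s - 1L] <- sample(setdiff(DNA_BASES, x), 1L)
    if (genome[s + run_len] == x)
      genome[s + run_len] <- sample(setdiff(DNA_BASES, x), 1L)
    k <- sample(1:(n - 2L), 1L)
    deltas <- stats::setNames(sample(1:2, k, replace = TRUE), carriers_of(k))
    add_truth(kind = "HomopolymerDiff", start = s, width = run_len,
              base = x, deltas = deltas)
  }

  # inversion: IR arms flanking a 3-nt loop whose alleles are reverse
  # complements (stem-loop mimic)
  for (v in seq_len(config$n_inversion)) {
    s <- pick_locus(15L, 25L)
    arm <- c("G", "C", "A", "T", "C", "G")
    block <- c("A", "G", "A")
    genome[s:(s + 5L)] <- arm
    genome[(s + 6L):(s + 8L)] <- block
    genome[(s + 9L):(s + 14L)] <- rev(chartr("ACGT", "TGCA", arm))
    k <- sample(2:(n - 2L), 1L)
    add_truth(kind = "Inversion", start = s + 6L, width = 3L,
              ref_allele = "AGA", alt_allele = "TCT",
              carriers = carriers_of(k))
  }

  # InDels: the first is an insertion (absent from the reference), the
  # rest are deletions; segments always contain >= 2 distinct bases so
  # they can never read as homopolymer extensions
  mixed_segment <- function(w) {
    seg <- rand_bases(w, config$gc_content)
    if (length(unique(seg)) == 1L)
      seg[w] <- sample(setdiff(DNA_BASES, seg[1L]), 1L)
    seg
  }
  ins <- NULL
  for (d in seq_len(config$n_indel)) {
    w <- sample(2:6, 1L)
    s <- pick_locus(w, 25L)
    k <- sample(1:(n - 2L), 1L)
    if (d == 1L) {
      seg <- mixed_segment(w)
      ins <- list(after = s - 1L, seg = seg, carriers = carriers_of(k))
      add_truth(kind = "InDel", start = s, width = w, insertion = TRUE,
                segment = paste(seg, collapse = ""), carriers = ins$carriers)
    } else {
      seg <- mixed_segment(w)
      genome[s:(s + w - 1L)] <- seg
      if (genome[s - 1L] == seg[1L])
        genome[s - 1L] <- sample(setdiff(DNA_BASES, seg[1L]), 1L)
      if (genome[s + w] == seg[w])
        genome[s + w] <- sample(setdiff(DNA_BASES, seg[w]), 1L)
      add_truth(kind = "InDel", start = s, width = w, insertion = FALSE,
                segment = paste(seg, collapse = ""), carriers = carriers_of(k))
    }
  }

  # coding SNPs: place inside gene exons (never the start/stop codon)
  n_cds_snp <- min(round(config$n_snp * 27 / 84), config$n_snp)
  cds_positions <- integer(0)
  for (ci in seq_len(n_cds_snp)) {
    gname <- sample(names(truth_cds), 1L)
    info <- truth_cds[[gname]]
    clen <- length(info$cds)
    off <- sample(4:(clen - 4L), 1L)  # 1-based offset in spliced CDS
    # map CDS offset to genomic position
    rem <- off
    pos <- NA_integer_
    for (ex in info$exons) {
      w <- ex[2L] - ex[1L] + 1L
      if (rem <= w) {
        pos <- if (info$strand == "+") ex[1L] + rem - 1L else ex[2L] - rem + 1L
        break
      }
      rem <- rem - w
    }
    # keep coding SNP columns isolated so adjacent substitution columns
    # can never masquerade as an inversion block
    if (any(abs(cds_positions - pos) <= 3L)) next
    cds_positions <- c(cds_positions, pos)
    ref_cds_base <- info$cds[off]
    ref_genomic <- genome[pos]
    alt <- pick_alt(ref_genomic, config$transition_prob)
    alt_genomic <- alt[1L]
    alt_cds_base <- if (info$strand == "-")
      chartr("ACGT", "TGCA", alt_genomic) else alt_genomic
    codon_index <- (off - 1L) %/% 3L + 1L
    cfrom <- (codon_index - 1L) * 3L + 1L
    ref_codon <- paste(info$cds[cfrom:(cfrom + 2L)], collapse = "")
    alt_cds <- info$cds
    alt_cds[off] <- alt_cds_base
    alt_codon <- paste(alt_cds[cfrom:(cfrom + 2L)], collapse = "")
    code <- Biostrings::getGeneticCode("11")
    k <- rand_carrier_count()
    add_truth(kind = "SNP", start = pos, width = 1L,
              ref_allele = ref_genomic, alt_allele = alt_genomic,
              class = alt[2L], carriers = carriers_of(k), diagnostic = FALSE,
              feature = gname, codon_index = codon_index,
              ref_aa = unname(code[ref_codon]), alt_aa = unname(code[alt_codon]))
  }
  n_cds_placed <- length(cds_positions)

  # remaining SNPs in intergenic space; the first n_diagnostic of them are
  # group-diagnostic with wide conserved flanks for amplicon design
  group_a <- sample_ids[regions == names(config$group_sizes)[1L]]
  group_rest <- setdiff(sample_ids, group_a)
  n_plain <- config$n_snp - n_cds_placed
  for (sn in seq_len(n_plain)) {
    diagnostic <- sn <= config$n_diagnostic
    s <- pick_locus(1L, if (diagnostic) 90L else 20L)
    ref_b <- genome[s]
    alt <- pick_alt(ref_b, config$transition_prob)
    if (diagnostic) {
      carriers <- group_rest  # reference sits in group A and keeps ref_b
    } else {
      carriers <- carriers_of(rand_carrier_count())
    }
    add_truth(kind = "SNP", start = s, width = 1L, ref_allele = ref_b,
              alt_allele = alt[1L], class = alt[2L], carriers = carriers,
              diagnostic = diagnostic, feature = NA_character_,
              codon_index = NA_integer_, ref_aa = NA_character_,
              alt_aa = NA_character_)
  }

  ## --- build the aligned matrix ---------------------------------------
  ins_len <- if (!is.null(ins)) length(ins$seg) else 0L
  to_col <- if (is.null(ins)) identity else
    function(p) p + (p > ins$after) * ins_len
  La <- L + ins_len
  refrow <- character(La)
  refrow[to_col(seq_len(L))] <- genome
  if (ins_len) refrow[(ins$after + 1L):(ins$after + ins_len)] <- GAP
  m <- matrix(rep(refrow, each = n), nrow = n, dimnames = list(sample_ids, NULL))

  truth_rows <- list()
  for (ev in truth) {
    cs <- to_col(ev$start)
    if (ev$kind == "SNP") {
      m[ev$carriers, cs] <- ev$alt_allele
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        kind = "SNP", col_start = cs, col_end = cs, ref_start = ev$start,
        ref_end = ev$start, ref_allele = ev$ref_allele,
        alt_allele = ev$alt_allele, class = ev$class,
        n_carriers = length(ev$carriers),
        carriers = paste(ev$carriers, collapse = ","),
        diagnostic = ev$diagnostic, feature = ev$feature,
        codon_index = ev$codon_index, ref_aa = ev$ref_aa,
        alt_aa = ev$alt_aa, stringsAsFactors = FALSE)
    } else if (ev$kind == "Inversion") {
      ce <- cs + ev$width - 1L
      m[ev$carriers, cs:ce] <- matrix(rep(strsplit(ev$alt_allele, "")[[1L]],
                                          each = length(ev$carriers)),
                                      nrow = length(ev$carriers))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        kind = "Inversion", col_start = cs, col_end = ce,
        ref_start = ev$start, ref_end = ev$start + ev$width - 1L,
        ref_allele = ev$ref_allele, alt_allele = ev$alt_allele,
        class = NA_character_, n_carriers = length(ev$carriers),
        carriers = paste(ev$carriers, collapse = ","), diagnostic = FALSE,
        feature = NA_character_, codon_index = NA_integer_,
        ref_aa = NA_character_, alt_aa = NA_character_,
        stringsAsFactors = FALSE)
    } else if (ev$kind == "HomopolymerDiff") {
      run_cols <- cs:(cs + ev$width - 1L)
      max_delta <- max(ev$deltas)
      for (cid in names(ev$deltas)) {
        dlt <- ev$deltas[[cid]]
        m[cid, run_cols[(ev$width - dlt + 1L):ev$width]] <- GAP
      }
      ecs <- run_cols[ev$width - max_delta + 1L]
      ece <- run_cols[ev$width]
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        kind = "HomopolymerDiff", col_start = ecs, col_end = ece,
        ref_start = ev$start + ev$width - max_delta,
        ref_end = ev$start + ev$width - 1L,
        ref_allele = strrep(ev$base, max_delta), alt_allele = "",
        class = NA_character_, n_carriers = length(ev$deltas),
        carriers = paste(names(ev$deltas), collapse = ","),
        diagnostic = FALSE, feature = NA_character_,
        codon_index = NA_integer_, ref_aa = NA_character_,
        alt_aa = NA_character_, stringsAsFactors = FALSE)
    } else if (ev$kind == "InDel" && isTRUE(ev$insertion)) {
      cols <- (ev$after %||% 0L)
      cs <- ins$after + 1L; ce <- ins$after + ins_len
      m[ins$carriers, cs:ce] <- matrix(rep(ins$seg, each = length(ins$carriers)),
                                       nrow = length(ins$carriers))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        kind = "InDel", col_start = cs, col_end = ce,
        ref_start = NA_integer_, ref_end = NA_integer_,
        ref_allele = "", alt_allele = paste(ins$seg, collapse = ""),
        class = NA_character_, n_carriers = length(ins$carriers),
        carriers = paste(ins$carriers, collapse = ","), diagnostic = FALSE,
        feature = NA_character_, codon_index = NA_integer_,
        ref_aa = NA_character_, alt_aa = NA_character_,
        stringsAsFactors = FALSE)
    } else {  # deletion
      ce <- cs + ev$width - 1L
      m[ev$carriers, cs:ce] <- GAP
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        kind = "InDel", col_start = cs, col_end = ce, ref_start = ev$start,
        ref_end = ev$start + ev$width - 1L, ref_allele = ev$segment,
        alt_allele = "", class = NA_character_,
        n_carriers = length(ev$carriers),
        carriers = paste(ev$carriers, collapse = ","), diagnostic = FALSE,
        feature = NA_character_, codon_index = NA_integer_,
        ref_aa = NA_character_, alt_aa = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  truth_tab <- do.call(rbind, truth_rows)
  truth_tab <- truth_tab[order(truth_tab$col_start), , drop = FALSE]
  rownames(truth_tab) <- NULL

  seqs <- stats::setNames(collapse_chars(m), sample_ids)
  aln <- genome_alignment(seqs, reference_id = ref_id, circular = TRUE)

  samples <- synth_sample_table(sample_ids, regions, config)

  list(alignment = aln, annotations = validate_annotations(annotations),
       samples = samples, truth = truth_tab, config = config)
}

#' @noRd
synth_sample_table <- function(sample_ids, regions, config) {
  region_base <- list(
    c(lat = 72.3, lon = 103.5), c(lat = 70.6, lon = 132.8),
    c(lat = 68.9, lon = 161.2))
  rn <- names(config$group_sizes)
  base <- stats::setNames(region_base[seq_along(rn)], rn)
  lat <- vapply(regions, function(r) base[[r]][["lat"]], 0) +
    round(stats::runif(length(regions), -0.4, 0.4), 5L)
  lon <- vapply(regions, function(r) base[[r]][["lon"]], 0) +
    round(stats::runif(length(regions), -0.8, 0.8), 5L)
  data.frame(
    sample_code = sample_ids, region = unname(regions),
    site = sprintf("%s%02d", substr(regions, 1L, 2L),
                   stats::ave(seq_along(regions), regions, FUN = seq_along)),
    latitude = lat, longitude = lon,
    vegetation_zone = sample(c("forest line", "dense forest",
                               "single-tree stands"),
                             length(sample_ids), replace = TRUE),
    species_range = ifelse(regions == rn[1L], "L. gmelinii", "L. cajanderi"),
    accession = "", stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a mitochondrial-style SNP matrix with missing data
#'
#' Sites are grouped into loci (\code{L<locus>_s<site>} ids). Planted
#' diagnostic sites perfectly partition the first region against the rest
#' among observed entries and always retain at least two observations per
#' group; a fixed number of sites is left fully observed (complete-case),
#' every other site carries at least one missing entry. An outgroup column
#' (\code{OUTG}) carries a third state at diagnostic sites. Paralog-
#' contaminated loci contain one individual with two divergent aligned
#' contig copies.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list: \code{matrix} (\code{\link{snp_matrix}} incl. the outgroup
#'   column), \code{locus_alignments} (per-locus per-individual contig
#'   sets), \code{truth} (diagnostic/complete/paralog ids and per-site
#'   expected robustness verdicts), \code{groups}, \code{outgroup}.
#' @export
simulate_mito_matrix <- function(config = sim_config()) {
  set.seed(config$seed + 10007L)
  n <- config$n_samples
  sample_ids <- sprintf("S%02d", seq_len(n))
  regions <- rep(names(config$group_sizes), config$group_sizes)
  names(regions) <- sample_ids
  group_a <- sample_ids[regions == names(config$group_sizes)[1L]]
  group_rest <- setdiff(sample_ids, group_a)
  outgroup <- "OUTG"
  ns <- config$n_mito_sites
  if (config$n_diagnostic + config$n_complete_sites > ns)
    stopf("n_mito_sites too small for diagnostic + complete sites")

  loci <- sprintf("L%02d", seq_len(config$n_loci))
  site_locus <- sort(sample(rep_len(loci, ns)))
  site_ids <- sprintf("%s_s%03d", site_locus, seq_len(ns))

  # roles: diagnostic sites, protected complete-case sites, the rest
  idx <- sample(ns)
  diag_idx <- idx[seq_len(config$n_diagnostic)]
  complete_idx <- idx[config$n_diagnostic + seq_len(config$n_complete_sites)]

  m <- matrix(MISSING, ns, n + 1L, dimnames = list(site_ids,
                                                   c(sample_ids, outgroup)))
  keep_obs <- matrix(FALSE, ns, n + 1L, dimnames = dimnames(m))
  expected_kept <- logical(ns)
  for (i in seq_len(ns)) {
    ref_b <- sample(DNA_BASES, 1L)
    alt <- pick_alt(ref_b, config$transition_prob)[1L]
    if (i %in% diag_idx) {
      m[i, group_a] <- ref_b
      m[i, group_rest] <- alt
      m[i, outgroup] <- sample(setdiff(DNA_BASES, c(ref_b, alt)), 1L)
      # keep the partition testable under masking
      keep_obs[i, sample(group_a, 2L)] <- TRUE
      keep_obs[i, sample(group_rest, 2L)] <- TRUE
    } else {
      k <- sample(2:(n - 2L), 1L)
      carriers <- sample(sample_ids, k)
      m[i, sample_ids] <- ref_b
      m[i, carriers] <- alt
      m[i, outgroup] <- ref_b
      # keep the site segregating under masking
      keep_obs[i, sample(carriers, min(2L, k))] <- TRUE
      keep_obs[i, sample(setdiff(sample_ids, carriers), 2L)] <- TRUE
    }
  }

  # missingness mask (individuals only; the outgroup row stays as drawn)
  if (config$missing_rate > 0) {
    for (i in seq_len(ns)) {
      if (i %in% complete_idx) next
      maskable <- sample_ids[!keep_obs[i, sample_ids]]
      masked <- maskable[stats::runif(length(maskable)) < config$missing_rate]
      if (!length(masked)) masked <- sample(maskable, 1L)  # never fully observed
      m[i, masked] <- MISSING
    }
  }

  # expected robustness verdicts from the planted counts
  for (i in seq_len(ns)) {
    x <- m[i, sample_ids]
    obs <- x[x != MISSING]
    tab <- sort(table(obs), decreasing = TRUE)
    n_obs <- length(obs)
    minor <- if (length(tab) >= 2L) as.integer(tab[2L]) else 0L
    expected_kept[i] <- (n_obs == n && minor >= 2L) ||
      (n_obs >= 6L && minor >= 3L)
  }

  # locus alignments; paralog loci get one individual with two divergent
  # contig copies, one clean locus gets duplicate identical contigs
  paralog_loci <- sort(sample(loci, config$n_paralog_loci))
  locus_alignments <- stats::setNames(lapply(loci, function(lc) {
    base_seq <- paste(rand_bases(120L, config$gc_content), collapse = "")
    per_ind <- stats::setNames(lapply(sample_ids, function(s) base_seq),
                               sample_ids)
    if (lc %in% paralog_loci) {
      who <- sample(sample_ids, 1L)
      chars <- strsplit(base_seq, "")[[1L]]
      at <- sample(120L, 3L)
      for (p in at) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
      per_ind[[who]] <- c(base_seq, paste(chars, collapse = ""))
    } else if (lc == loci[1L]) {
      who <- sample(sample_ids, 1L)
      per_ind[[who]] <- c(base_seq, base_seq)  # agreeing duplicates
    }
    per_ind
  }), loci)

  truth <- list(
    diagnostic_sites = sort(site_ids[diag_idx]),
    complete_sites = sort(site_ids[complete_idx]),
    paralog_loci = paralog_loci,
    expected_kept = stats::setNames(expected_kept, site_ids))
  list(matrix = snp_matrix(m), locus_alignments = locus_alignments,
       truth = truth,
       groups = stats::setNames(list(group_a, group_rest),
                                c(names(config$group_sizes)[1L], "East")),
       outgroup = outgroup)
}

#' Write a simulated alignment bundle to disk
#'
#' Writes the aligned FASTA, GFF3 annotations, metadata TSV and the truth
#' table (JSON) into a directory using the same formats the pipeline
#' consumes.
#'
#' @param sim result of \code{\link{simulate_alignment_set}}.
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(sim$alignment, file.path(dir, "alignment.fasta"))
  write_annotations(sim$annotations, sim$alignment$reference_id,
                    file.path(dir, "annotations.gff3"))
  write_sample_table(sim$samples, file.path(dir, "samples.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null")
  invisible(dir)
}
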