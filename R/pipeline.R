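# End-to-end orchestration: read inputs, scan or ingest variants, filter
# (mitochondrial mode), annotate effects (chloroplast mode), screen for
# diagnostic markers, build the haplotype network, and write a
# machine-readable JSON run report plus all per-stage tables.

#' Build a run configuration
#'
#' @param mode \code{"chloroplast"} (alignment scanning + effect
#'   annotation) or \code{"mitochondrial"} (pre-scored allele matrix with
#'   paralog and robustness filtering).
#' @param alignment_path aligned FASTA (chloroplast mode).
#' @param reference_id reference row id (chloroplast mode).
#' @param annotations_path GFF3 feature annotations (chloroplast mode,
#'   optional).
#' @param metadata_path sample metadata TSV.
#' @param matrix_path SNP-matrix TSV (mitochondrial mode).
#' @param group_by metadata column defining the diagnostic partition
#'   (\code{"region"} or \code{"species_range"}).
#' @param group_a label within \code{group_by} forming group A; all other
#'   samples form group B.
#' @param outgroup optional sample id excluded from the partition test.
#' @param out_dir output directory.
#' @param homopolymer_min_run,inversion_min_span scanner thresholds.
#' @param flank_len,amplicon_min,amplicon_max amplicon-window thresholds.
#' @param min_obs_per_group diagnostic screen threshold.
#' @param confidence statistical-parsimony confidence level.
#' @param connection_length override for the sequence length used by the
#'   connection limit (defaults to the alignment length, or 1e5 for a bare
#'   matrix).
#' @export
run_config <- function(mode = c("chloroplast", "mitochondrial"),
                       alignment_path = NULL, reference_id = NULL,
                       annotations_path = NULL, metadata_path = NULL,
                       matrix_path = NULL, loci_dir = NULL,
                       group_by = "region",
                       group_a = NULL, outgroup = NULL, out_dir = tempdir(),
                       homopolymer_min_run = 4L, inversion_min_span = 2L,
                       flank_len = 20L, amplicon_min = 60L,
                       amplicon_max = 150L, min_obs_per_group = 2L,
                       confidence = 0.95, connection_length = NULL) {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  for (p in c("alignment_path", "annotations_path", "metadata_path",
              "matrix_path"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stopf("%s does not exist: %s", p, cfg[[p]])
  stopifnot(confidence > 0, confidence < 1, min_obs_per_group >= 1L)
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys are \code{\link{run_config}} arguments.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (scan or ingest, filter, annotate, screen,
#' reduce to complete cases, collapse, network) and writes every stage's
#' table plus a JSON report into \code{config$out_dir}. Stage-level counts
#' (sites in/kept/rejected) are conserved and logged to stderr.
#'
#' @param config a \code{\link{run_config}}.
#' @return the run report (list), invisibly also written as
#'   \code{report.json}.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message(sprintf(...))
  report <- list(schema = "larchvar-report/1", mode = config$mode)

  metadata <- if (!is.null(config$metadata_path))
    read_sample_table(config$metadata_path) else NULL

  if (config$mode == "chloroplast") {
    aln <- read_alignment(config$alignment_path, config$reference_id)
    log_msg("alignment: %d samples x %d columns", length(aln$sample_ids),
            alignment_length(aln))
    events <- scan_alignment(aln, scan_config(config$homopolymer_min_run,
                                              config$inversion_min_span))
    log_msg("scan: %d events", nrow(events))
    smry <- summarize_variants(aln, events)
    report$variants <- smry[c("n_snp", "n_indel", "n_homopolymer",
                              "n_inversion", "n_singleton", "ts_fraction",
                              "tv_fraction", "gc_content")]
    if (nrow(events)) {
      write_variant_table(events, file.path(config$out_dir, "variants.tsv"))
      write_variants_vcf(events, aln, file.path(config$out_dir, "variants.vcf"))
    }
    if (!is.null(config$annotations_path)) {
      annotations <- read_annotations(config$annotations_path)
      effects <- annotate_effects(events, annotations, aln)
      write_effect_table(effects, file.path(config$out_dir, "effects.tsv"))
      report$effects <- count_effects(effects)
      log_msg("effects: %d coding / %d non-coding SNPs",
              report$effects$n_coding, report$effects$n_noncoding)
    }
    matrix <- snp_matrix_from_events(events, sample_ids = aln$sample_ids)
    conn_len <- config$connection_length %||% alignment_length(aln)
  } else {
    matrix <- read_snp_matrix(config$matrix_path)
    log_msg("matrix: %d sites x %d samples", nrow(matrix), ncol(matrix))
    if (!is.null(config$loci_dir)) {
      loci <- read_locus_alignments(config$loci_dir)
      flagged <- flag_paralogs(loci)
      drop <- if (length(flagged))
        grepl(paste0("^(", paste(flagged, collapse = "|"), ")_"),
              rownames(matrix))
      else rep(FALSE, nrow(matrix))
      report$paralogs <- list(loci_flagged = as.list(flagged),
                              sites_dropped = sum(drop))
      log_msg("paralog flagging: %d loci flagged, %d sites dropped",
              length(flagged), sum(drop))
      if (any(drop)) {
        matrix <- matrix[!drop, , drop = FALSE]
        class(matrix) <- c("snp_matrix", "matrix", "array")
      }
    }
    n_in <- nrow(matrix)
    test_cols <- setdiff(colnames(matrix), config$outgroup)
    verdicts <- robustness_filter(matrix[, test_cols, drop = FALSE],
                                  n_total_samples = length(test_cols))
    write_filter_verdicts(verdicts, file.path(config$out_dir, "verdicts.tsv"))
    matrix <- matrix[verdicts$kept, , drop = FALSE]
    class(matrix) <- c("snp_matrix", "matrix", "array")
    report$filter <- list(sites_in = n_in, sites_kept = sum(verdicts$kept),
                          sites_rejected = sum(!verdicts$kept))
    log_msg("robustness filter: %d in = %d kept + %d rejected", n_in,
            report$filter$sites_kept, report$filter$sites_rejected)
    write_snp_matrix(matrix, file.path(config$out_dir, "filtered_matrix.tsv"))
    conn_len <- config$connection_length %||% 100000L
  }

  # diagnostic screen
  if (!is.null(metadata) && !is.null(config$group_a) && nrow(matrix)) {
    in_matrix <- intersect(metadata$sample_code, colnames(matrix))
    md <- metadata[metadata$sample_code %in% in_matrix, ]
    a_ids <- md$sample_code[md[[config$group_by]] == config$group_a]
    b_ids <- setdiff(in_matrix, c(a_ids, config$outgroup))
    groups <- stats::setNames(list(a_ids, b_ids),
                              c(config$group_a, "rest"))
    calls <- find_diagnostic_snps(matrix, groups,
                                  min_obs_per_group = config$min_obs_per_group,
                                  outgroup = config$outgroup)
    write_diagnostic_table(calls, file.path(config$out_dir, "diagnostics.tsv"))
    report$diagnostics <- list(n_sites_screened = nrow(calls),
                               n_diagnostic = sum(calls$diagnostic),
                               diagnostic_sites = calls$site_id[calls$diagnostic])
    log_msg("diagnostic screen: %d of %d sites", sum(calls$diagnostic),
            nrow(calls))
    if (config$mode == "chloroplast" && any(calls$diagnostic)) {
      cols <- attr(matrix, "column")[calls$diagnostic]
      windows <- lapply(cols, function(cl)
        evaluate_amplicon_window(cl, aln, config$flank_len,
                                 config$amplicon_min, config$amplicon_max))
      write_amplicon_bed(windows, config$reference_id,
                         file.path(config$out_dir, "amplicons.bed"))
      report$amplicons <- list(n_usable = sum(vapply(windows, `[[`, NA,
                                                     "usable")))
    }
  }

  # haplotype network on complete-case sites
  exclude <- config$outgroup
  net_matrix <- matrix[, setdiff(colnames(matrix), exclude), drop = FALSE]
  class(net_matrix) <- c("snp_matrix", "matrix", "array")
  cc <- complete_case_sites(net_matrix)
  report$network_input <- list(sites_total = nrow(net_matrix),
                               sites_complete = nrow(cc))
  haps <- collapse_haplotypes(cc)
  limit <- connection_limit(conn_len, config$confidence)
  net <- build_network(haps, limit)
  write_haplotype_table(haps, file.path(config$out_dir, "haplotypes.tsv"))
  if (!is.null(metadata)) {
    region_of <- stats::setNames(metadata$region, metadata$sample_code)
    export_network(net, region_of[colnames(cc)],
                   file.path(config$out_dir, "network.graphml"))
  }
  report$network <- list(
    n_haplotypes = sum(net$nodes$observed),
    n_inferred = sum(!net$nodes$observed), n_edges = nrow(net$edges),
    n_components = if (length(net$components)) max(net$components) else 0L,
    connection_limit = limit)
  log_msg("network: %d haplotypes, %d edges, limit %d",
          report$network$n_haplotypes, report$network$n_edges, limit)

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
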