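# Statistical-parsimony (TCS-style) haplotype networks: collapse identical
# individuals into haplotypes, derive a connection limit from the
# probability of parsimony, and connect haplotypes by unit-mutation edges,
# inserting inferred intermediate haplotypes and retaining loops.

#' Collapse individuals into haplotypes
#'
#' Individuals with identical allele profiles across all sites merge into
#' one haplotype; multiplicities sum to the number of individuals. Requires
#' a complete-case matrix (no missing entries): with partial profiles,
#' identity between individuals is undefined. Use
#' \code{\link{complete_case_sites}} first.
#'
#' @param matrix a complete-case \code{\link{snp_matrix}}.
#' @return data.frame: \code{hap_id} (\code{H1}, \code{H2}, ... in order of
#'   first member appearance), \code{profile}, \code{multiplicity},
#'   \code{observed}, and a list column \code{members}.
#' @export
collapse_haplotypes <- function(matrix) {
  if (any(matrix == MISSING))
    stopf("matrix has missing entries; restrict with complete_case_sites() first")
  samples <- colnames(matrix)
  profiles <- apply(unclass(matrix), 2L, paste, collapse = "")
  if (!nrow(matrix)) profiles <- stats::setNames(rep("", length(samples)), samples)
  uniq <- unique(profiles)  # order of first appearance
  haps <- data.frame(
    hap_id = sprintf("H%02d", seq_along(uniq)), profile = uniq,
    multiplicity = vapply(uniq, function(p) sum(profiles == p), 0L),
    observed = TRUE, stringsAsFactors = FALSE, row.names = NULL)
  haps$members <- lapply(uniq, function(p) samples[profiles == p])
  haps
}

#' Probability of parsimony for j mutational steps
#'
#' Probability that \code{j} mutations falling independently and uniformly
#' over \code{m} sites all strike distinct sites, i.e. that the observed
#' differences between two haplotypes reflect single mutations with no
#' superimposed (multiple) hits:
#' \deqn{P(j, m) = \prod_{i=0}^{j-1} (1 - i/m).}
#'
#' @param j number of mutational steps.
#' @param m sequence length (number of sites of the underlying molecule).
#' @export
parsimony_probability <- function(j, m) {
  stopifnot(j >= 0L, m >= 1L)
  if (j > m) return(0)
  prod(1 - (seq_len(j) - 1L) / m)
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps \code{j} whose probability of
#' parsimony (\code{\link{parsimony_probability}}) still meets the
#' confidence level. Non-decreasing in \code{sequence_length},
#' non-increasing in \code{confidence}; always at least 1 (single-step
#' connections are parsimonious by construction).
#'
#' @param sequence_length number of aligned sites of the underlying
#'   molecule (not the SNP count).
#' @param confidence required probability of parsimony (default 0.95).
#' @export
connection_limit <- function(sequence_length, confidence = 0.95) {
  stopifnot(sequence_length >= 1L, confidence > 0, confidence < 1)
  p <- 1
  j <- 1L
  while (j < sequence_length) {
    p_next <- p * (1 - j / sequence_length)  # P(j + 1, m)
    if (p_next < confidence) break
    p <- p_next
    j <- j + 1L
  }
  j
}

#' @noRd
hamming <- function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])

#' Build a statistical-parsimony haplotype network
#'
#' Iterates the candidate step distance d from 1 to \code{limit}; at each
#' d, every pair of observed haplotypes at profile distance d that is not
#' yet connected through the network by a path of at most d edges is joined
#' by a path of d unit-mutation edges, inserting d - 1 intermediate
#' haplotypes. A required intermediate profile that matches an existing
#' node (observed or inferred) reuses that node — this reuse is what
#' creates loops (alternative genealogical pathways). Pairs farther apart
#' than \code{limit} stay in separate components.
#'
#' Determinism: pairs at equal distance are processed in lexicographic
#' (hap_id_a, hap_id_b) order and intermediate profiles mutate the
#' differing sites in ascending site order.
#'
#' @param haplotypes data.frame from \code{\link{collapse_haplotypes}}.
#' @param limit connection limit in mutational steps.
#' @return object of class \code{haplo_network}: \code{nodes} (haplotype
#'   table including inferred intermediates with multiplicity 0),
#'   \code{edges} (two-column data.frame, each edge one mutational step),
#'   \code{limit}, \code{components} (named membership vector).
#' @export
build_network <- function(haplotypes, limit) {
  stopifnot(limit >= 1L)
  nodes <- haplotypes[order(haplotypes$hap_id), , drop = FALSE]
  profiles <- stats::setNames(nodes$profile, nodes$hap_id)
  adj <- stats::setNames(vector("list", length(profiles)), names(profiles))
  edges <- list()
  n_inferred <- 0L

  add_edge <- function(a, b) {
    if (b %in% adj[[a]]) return(invisible())
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
    edges[[length(edges) + 1L]] <<- sort(c(a, b))
  }
  node_for_profile <- function(p) {
    hit <- names(profiles)[profiles == p]
    if (length(hit)) return(hit[1L])
    n_inferred <<- n_inferred + 1L
    id <- sprintf("I%02d", n_inferred)
    profiles[[id]] <<- p
    adj[[id]] <<- character(0)
    id
  }
  # path length (in edges) between two nodes, capped; Inf if farther apart
  bfs_dist <- function(a, b, cap) {
    if (a == b) return(0L)
    frontier <- a
    seen <- a
    depth <- 0L
    while (length(frontier) && depth < cap) {
      depth <- depth + 1L
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      if (b %in% nxt) return(depth)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    Inf
  }

  obs_ids <- nodes$hap_id
  if (length(obs_ids) >= 2L && nchar(nodes$profile[1L]) > 0L) {
    pairs <- utils::combn(obs_ids, 2L)
    dmat <- apply(pairs, 2L, function(p)
      hamming(profiles[[p[1L]]], profiles[[p[2L]]]))
    for (d in seq_len(limit)) {
      for (k in which(dmat == d)) {
        a <- pairs[1L, k]; b <- pairs[2L, k]
        if (is.finite(bfs_dist(a, b, d))) next
        pa <- strsplit(profiles[[a]], "")[[1L]]
        pb <- strsplit(profiles[[b]], "")[[1L]]
        diff_sites <- which(pa != pb)  # ascending site order
        cur <- a
        prof <- pa
        for (s in diff_sites[-length(diff_sites)]) {
          prof[s] <- pb[s]
          nxt <- node_for_profile(paste(prof, collapse = ""))
          add_edge(cur, nxt)
          cur <- nxt
        }
        add_edge(cur, b)
      }
    }
  }

  all_ids <- names(profiles)
  inferred <- !all_ids %in% nodes$hap_id
  node_tab <- data.frame(
    hap_id = all_ids, profile = unname(profiles),
    multiplicity = ifelse(inferred, 0L,
                          nodes$multiplicity[match(all_ids, nodes$hap_id)]),
    observed = !inferred, stringsAsFactors = FALSE)
  node_tab$members <- lapply(seq_along(all_ids), function(i) {
    if (inferred[i]) character(0)
    else nodes$members[[match(all_ids[i], nodes$hap_id)]]
  })
  edge_tab <- if (length(edges))
    data.frame(from = vapply(edges, `[[`, "", 1L),
               to = vapply(edges, `[[`, "", 2L), stringsAsFactors = FALSE)
  else data.frame(from = character(0), to = character(0))

  # connected components
  comp <- stats::setNames(rep(NA_integer_, length(all_ids)), all_ids)
  cid <- 0L
  for (v in all_ids) {
    if (!is.na(comp[[v]])) next
    cid <- cid + 1L
    frontier <- v
    comp[frontier] <- cid
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier])), names(comp)[!is.na(comp)])
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  structure(list(nodes = node_tab, edges = edge_tab, limit = limit,
                 components = comp),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf(paste0("haplo_network: %d observed + %d inferred haplotypes, ",
                     "%d edges, %d component(s), limit %d steps\n"),
              sum(x$nodes$observed), sum(!x$nodes$observed), nrow(x$edges),
              if (length(x$components)) max(x$components) else 0L, x$limit))
  invisible(x)
}

#' Convert a haplotype network to an igraph object
#'
#' @param network a \code{haplo_network}.
#' @param node_metadata optional named vector mapping sample ids to group
#'   labels; adds one \code{n_<group>} count attribute per group.
#' @export
as_igraph_network <- function(network, node_metadata = NULL) {
  nd <- network$nodes
  vattr <- data.frame(name = nd$hap_id, multiplicity = nd$multiplicity,
                      observed = nd$observed, profile = nd$profile,
                      stringsAsFactors = FALSE)
  if (!is.null(node_metadata)) {
    unknown <- setdiff(unlist(nd$members), names(node_metadata))
    if (length(unknown))
      stopf("sample(s) missing from metadata: %s",
            paste(unknown, collapse = ", "))
    for (g in sort(unique(node_metadata))) {
      vattr[[paste0("n_", g)]] <- vapply(nd$members, function(mem)
        sum(node_metadata[mem] == g), 0L)
    }
  }
  g <- igraph::graph_from_data_frame(
    cbind(network$edges, steps = rep(1L, nrow(network$edges))),
    directed = FALSE, vertices = vattr)
  g
}

#' Export a haplotype network as GraphML and a Nexus network block
#'
#' @param network a \code{haplo_network}.
#' @param node_metadata named vector mapping sample id to group label.
#' @param path output GraphML file; a companion \code{.nex} file with a
#'   simple network block is written next to it.
#' @export
export_network <- function(network, node_metadata, path) {
  g <- as_igraph_network(network, node_metadata)
  igraph::write_graph(g, path, format = "graphml")
  nex <- sub("\\.[^.]*$", ".nex", path)
  if (identical(nex, path)) nex <- paste0(path, ".nex")
  nd <- network$nodes
  lines <- c(
    "#NEXUS", "BEGIN NETWORK;",
    sprintf("DIMENSIONS NVERTICES=%d NEDGES=%d;", nrow(nd),
            nrow(network$edges)),
    "VERTICES",
    sprintf("  %s multiplicity=%d observed=%s,", nd$hap_id,
            nd$multiplicity, tolower(nd$observed)),
    ";", "EDGES",
    if (nrow(network$edges))
      sprintf("  %s -- %s steps=1,", network$edges$from, network$edges$to)
    else character(0),
    ";", "END;")
  writeLines(lines, nex)
  invisible(path)
}

#' Write the haplotype membership table as TSV
#' @param haplotypes data.frame from \code{\link{collapse_haplotypes}}
#' @param path output file
#' @export
write_haplotype_table <- function(haplotypes, path) {
  df <- data.frame(
    hap_id = haplotypes$hap_id, multiplicity = haplotypes$multiplicity,
    observed = haplotypes$observed,
    members = vapply(haplotypes$members, paste, "", collapse = ","),
    profile = haplotypes$profile, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
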