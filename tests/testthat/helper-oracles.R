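# Independent brute-force reference implementations used by both the unit
# and the end-to-end suites.

# exhaustive per-site diagnostic screen
diag_oracle <- function(m, ga, gb, min_obs) {
  vapply(seq_len(nrow(m)), function(i) {
    a <- m[i, ga]; a <- a[a != "?"]
    b <- m[i, gb]; b <- b[b != "?"]
    length(a) >= min_obs && length(b) >= min_obs &&
      length(unique(a)) == 1L && length(unique(b)) == 1L &&
      unique(a) != unique(b)
  }, NA)
}

# Brute-force network construction: same connection policy as
# build_network but implemented over an explicit distance matrix with
# Floyd-Warshall path updates rather than incremental BFS.
oracle_network <- function(haps, limit) {
  profs <- stats::setNames(haps$profile, haps$hap_id)
  edges <- character(0)
  graph_dist <- function() {
    ids <- names(profs)
    n <- length(ids)
    D <- matrix(Inf, n, n, dimnames = list(ids, ids))
    diag(D) <- 0
    for (e in edges) {
      ab <- strsplit(e, "|", fixed = TRUE)[[1L]]
      D[ab[1L], ab[2L]] <- D[ab[2L], ab[1L]] <- 1
    }
    for (k in ids) for (i in ids) for (j in ids)
      if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
    D
  }
  obs <- sort(haps$hap_id)
  n_inf <- 0L
  for (d in seq_len(limit)) {
    for (a in obs) for (b in obs) {
      if (a >= b) next
      if (ham(profs[[a]], profs[[b]]) != d) next
      if (graph_dist()[a, b] <= d) next
      pa <- strsplit(profs[[a]], "")[[1L]]
      pb <- strsplit(profs[[b]], "")[[1L]]
      cur <- a
      for (s in which(pa != pb)) {
        pa[s] <- pb[s]
        p <- paste(pa, collapse = "")
        nxt <- if (p %in% profs) names(profs)[match(p, profs)] else {
          n_inf <- n_inf + 1L
          id <- sprintf("I%02d", n_inf)
          profs[[id]] <- p
          id
        }
        e <- paste(sort(c(cur, nxt)), collapse = "|")
        if (!e %in% edges) edges <- c(edges, e)
        cur <- nxt
      }
    }
  }
  list(profiles = sort(unname(profs)),
       edges = sort(unname(vapply(edges, function(e) {
         ab <- strsplit(e, "|", fixed = TRUE)[[1L]]
         paste(sort(unname(profs[ab])), collapse = "|")
       }, ""))))
}

# profile-level signature of a built network, comparable across node
# labelling schemes
net_signature <- function(net) {
  profs <- stats::setNames(net$nodes$profile, net$nodes$hap_id)
  list(profiles = sort(unname(profs)),
       edges = sort(unname(vapply(seq_len(nrow(net$edges)), function(i)
         paste(sort(c(profs[[net$edges$from[i]]], profs[[net$edges$to[i]]])),
               collapse = "|"), ""))))
}

fake_haps <- function(profiles) {
  df <- data.frame(hap_id = sprintf("H%02d", seq_along(profiles)),
                   profile = profiles, multiplicity = 1L, observed = TRUE,
                   stringsAsFactors = FALSE)
  df$members <- as.list(sprintf("s%d", seq_along(profiles)))
  df
}
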