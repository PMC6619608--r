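test_that("individuals collapse into haplotypes by profile identity", {
  ms <- simulate_mito_matrix(sim_config(seed = 2))
  cc <- complete_case_sites(ms$matrix)
  cc <- cc[, setdiff(colnames(cc), ms$outgroup), drop = FALSE]
  class(cc) <- c("snp_matrix", "matrix", "array")
  haps <- collapse_haplotypes(cc)
  expect_equal(sum(haps$multiplicity), ncol(cc))
  expect_false(anyDuplicated(haps$profile) > 0L)
  # grouping oracle: split sample ids by profile string
  profs <- apply(unclass(cc), 2L, paste, collapse = "")
  oracle <- unname(split(colnames(cc), profs)[unique(profs)])
  expect_identical(haps$members, oracle)
  # missing data is refused
  expect_error(collapse_haplotypes(ms$matrix), "complete_case_sites")

  # two identical individuals merge
  m <- snp_matrix(matrix(c("A", "A", "C", "A", "C", "C"), 2L, 3L,
                         dimnames = list(c("s1", "s2"),
                                         c("x", "y", "z"))),
                  validate = FALSE)
  h <- collapse_haplotypes(m)
  expect_equal(nrow(h), 3L)
  m[, "y"] <- m[, "x"]
  h2 <- collapse_haplotypes(m)
  expect_equal(nrow(h2), 2L)
  expect_equal(h2$multiplicity[h2$hap_id == "H01"], 2L)
})

test_that("parsimony probability follows the no-multiple-hit form", {
  expect_equal(parsimony_probability(1L, 100L), 1)
  expect_equal(parsimony_probability(2L, 100L), 1 - 1 / 100)
  expect_equal(parsimony_probability(3L, 4L), (3 / 4) * (2 / 4))
  expect_equal(parsimony_probability(5L, 4L), 0)

  # Monte Carlo cross-check: drop j mutations uniformly on m sites and
  # count collision-free outcomes
  set.seed(123)
  j <- 5L; m <- 100L
  hits <- replicate(20000, !anyDuplicated(sample.int(m, j, replace = TRUE)))
  p_hat <- mean(hits)
  p <- parsimony_probability(j, m)
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / 20000))
})

test_that("connection limit is monotone and collapses to 1 at high confidence", {
  for (L in c(50L, 100L, 500L, 1000L))
    expect_lte(connection_limit(L, 0.95), connection_limit(2L * L, 0.95))
  lims <- vapply(c(0.5, 0.9, 0.95, 0.99), function(cf)
    connection_limit(500L, cf), 0L)
  expect_true(all(diff(lims) <= 0L))
  expect_equal(connection_limit(20L, 0.999), 1L)
  # definition check: limit is the largest j with P(j) >= confidence
  for (L in c(100L, 500L, 1000L)) {
    j <- connection_limit(L, 0.95)
    expect_gte(parsimony_probability(j, L), 0.95)
    expect_lt(parsimony_probability(j + 1L, L), 0.95)
  }
})

test_that("network construction handles simple and median topologies", {
  # two haplotypes one step apart: a single edge, no intermediates
  net <- build_network(fake_haps(c("AAA", "AAC")), 5L)
  expect_equal(nrow(net$nodes), 2L)
  expect_equal(nrow(net$edges), 1L)

  # three haplotypes pairwise two steps apart sharing a median: the median
  # is inferred once and has degree 3
  net3 <- build_network(fake_haps(c("CAA", "ACA", "AAC")), 5L)
  expect_equal(sum(!net3$nodes$observed), 1L)
  med <- net3$nodes$hap_id[!net3$nodes$observed]
  expect_equal(net3$nodes$profile[!net3$nodes$observed], "AAA")
  expect_equal(sum(net3$edges$from == med | net3$edges$to == med), 3L)

  # pairs beyond the limit stay in separate components
  far <- build_network(fake_haps(c("AAAAA", "CCCCC")), 2L)
  expect_equal(max(far$components), 2L)
  expect_equal(nrow(far$edges), 0L)
  # with limit >= max distance the network is connected
  near <- build_network(fake_haps(c("AAAAA", "CCCCC")), 5L)
  expect_equal(max(near$components), 1L)
})

test_that("network equals the brute-force construction on small fixtures", {
  fixtures <- list(
    star = c("AAAA", "CAAA", "ACAA", "AACA", "AAAC"),
    loop = c("AA", "CA", "AC", "CC"),
    chain = c("AAA", "CAA", "CCA", "CCC"),
    two_comp = c("AAAAAAAAAA", "CAAAAAAAAA", "CCCCCCCCCC"),
    mixed = c("ACACA", "ACACC", "ACCCA", "CCACA", "ACGCA", "TCACA"))
  for (nm in names(fixtures)) {
    haps <- fake_haps(fixtures[[nm]])
    limit <- 3L
    net <- build_network(haps, limit)
    expect_identical(net_signature(net), oracle_network(haps, limit),
                     label = nm)
  }
})

test_that("network invariants hold on simulated data", {
  ms <- simulate_mito_matrix(sim_config(seed = 7))
  cc <- complete_case_sites(ms$matrix)
  cc <- cc[, setdiff(colnames(cc), ms$outgroup), drop = FALSE]
  class(cc) <- c("snp_matrix", "matrix", "array")
  haps <- collapse_haplotypes(cc)
  net <- build_network(haps, connection_limit(100000L, 0.95))

  # conservation of individuals
  expect_equal(sum(net$nodes$multiplicity), ncol(cc))
  # every edge joins profiles at Hamming distance exactly 1
  profs <- stats::setNames(net$nodes$profile, net$nodes$hap_id)
  for (i in seq_len(nrow(net$edges)))
    expect_equal(ham(profs[[net$edges$from[i]]], profs[[net$edges$to[i]]]), 1L)
  # no self or duplicate edges
  keys <- apply(net$edges, 1L, function(e) paste(sort(e), collapse = "|"))
  expect_false(any(net$edges$from == net$edges$to))
  expect_false(anyDuplicated(keys) > 0L)
  # every inferred node lies on a shortest path between two observed nodes
  obs_p <- net$nodes$profile[net$nodes$observed]
  for (p in net$nodes$profile[!net$nodes$observed]) {
    on_path <- any(vapply(seq_along(obs_p), function(i)
      any(vapply(seq_along(obs_p), function(j)
        i != j && ham(obs_p[i], p) + ham(p, obs_p[j]) ==
          ham(obs_p[i], obs_p[j]), NA)), NA))
    expect_true(on_path)
  }
  # determinism
  net2 <- build_network(haps, net$limit)
  expect_identical(net$nodes, net2$nodes)
  expect_identical(net$edges, net2$edges)
})

test_that("network export writes GraphML/Nexus and preserves structure", {
  haps <- fake_haps(c("AA", "AC", "CC"))
  haps$members <- list("s1", "s2", "s3")
  haps$multiplicity <- c(1L, 1L, 1L)
  net <- build_network(haps, 3L)
  meta <- c(s1 = "west", s2 = "west", s3 = "east")
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, meta, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("graphml$", "nex", path)))
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(sort(igraph::V(g)$name), sort(net$nodes$hap_id))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_equal(sum(igraph::V(g)$n_west), 2L)
  expect_error(export_network(net, c(s1 = "west"), path), "missing from metadata")

  # single node network
  one <- build_network(fake_haps("A"), 1L)
  path1 <- withr::local_tempfile(fileext = ".graphml")
  export_network(one, c(s1 = "west"), path1)
  g1 <- igraph::read_graph(path1, format = "graphml")
  expect_equal(igraph::vcount(g1), 1L)
  expect_equal(igraph::ecount(g1), 0L)

  # per-region member counts over a full simulated run sum to 19
  sim <- simulate_mito_matrix(sim_config(seed = 4))
  cc <- complete_case_sites(sim$matrix)
  cc <- cc[, setdiff(colnames(cc), sim$outgroup), drop = FALSE]
  class(cc) <- c("snp_matrix", "matrix", "array")
  net19 <- build_network(collapse_haplotypes(cc), 30L)
  region <- stats::setNames(
    rep(c("Taymyr", "East"), c(12L, 7L)), colnames(cc))
  g19 <- as_igraph_network(net19, region)
  expect_equal(sum(igraph::V(g19)$n_Taymyr) + sum(igraph::V(g19)$n_East), 19L)
})
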