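path_net <- function(ids) {
  interaction_network(
    nodes = data.frame(id = ids, kind = "protein", stringsAsFactors = FALSE),
    edges = data.frame(from = ids[-length(ids)], to = ids[-1],
                       stringsAsFactors = FALSE)
  )
}

star_net <- function(n_leaves) {
  ids <- c("hub", sprintf("leaf%d", seq_len(n_leaves)))
  interaction_network(
    nodes = data.frame(id = ids, kind = "protein", stringsAsFactors = FALSE),
    edges = data.frame(from = "hub", to = ids[-1], stringsAsFactors = FALSE)
  )
}

complete_net <- function(n) {
  ids <- sprintf("k%d", seq_len(n))
  pairs <- combn(ids, 2)
  interaction_network(
    nodes = data.frame(id = ids, kind = "protein", stringsAsFactors = FALSE),
    edges = data.frame(from = pairs[1, ], to = pairs[2, ],
                       stringsAsFactors = FALSE)
  )
}

test_that("network construction enforces simple undirected structure", {
  net <- interaction_network(
    nodes = data.frame(id = c("a", "b", "c"), kind = "protein"),
    edges = data.frame(from = c("a", "b", "a", "c"), to = c("b", "a", "a", "b"))
  )
  expect_equal(n_edges(net), 2)  # duplicate a-b collapsed, self-loop dropped
  expect_error(interaction_network(
    nodes = data.frame(id = "a", kind = "x"),
    edges = data.frame(from = "a", to = "zzz")), "not declared")
  expect_error(interaction_network(
    nodes = data.frame(id = c("a", "a"), kind = "x"), NULL), "duplicate")
})

test_that("bipartite compound-target networks contain only cross edges", {
  net <- build_bipartite(list(c1 = c("A", "B"), c2 = "B"))
  expect_equal(n_nodes(net), 4)
  expect_equal(n_edges(net), 3)
  kind <- setNames(net$nodes$kind, net$nodes$id)
  expect_true(all(kind[net$edges$from] != kind[net$edges$to]))
  empty <- build_bipartite(list())
  expect_equal(n_nodes(empty), 0)
  # node/edge counts match brute force on a random mapping
  set.seed(1)
  mapping <- lapply(setNames(1:10, paste0("c", 1:10)),
                    function(i) sample(LETTERS[1:8], sample(1:4, 1)))
  net2 <- build_bipartite(mapping)
  expect_equal(n_nodes(net2), 10 + length(unique(unlist(mapping))))
  expect_equal(n_edges(net2), length(unique(unlist(lapply(names(mapping),
    function(cid) paste(cid, mapping[[cid]]))))))
})

test_that("PPI construction expands neighbours and keeps orphan seeds", {
  edges <- data.frame(from = c("A", "B"), to = c("B", "C"))
  net <- build_ppi("A", edges, expand_neighbors = TRUE)
  expect_setequal(net$nodes$id, c("A", "B"))
  expect_equal(n_edges(net), 1)
  net0 <- build_ppi("A", edges, expand_neighbors = FALSE)
  expect_equal(net0$nodes$id, "A")
  expect_equal(n_edges(net0), 0)
  expect_warning(net1 <- build_ppi(c("A", "ZZ"), edges), "isolated")
  expect_true("ZZ" %in% net1$nodes$id)
  # matches brute force on a random graph and seed set
  set.seed(7)
  a <- random_graph_adj(12, 0.3)
  el <- which(upper.tri(a) & a == 1L, arr.ind = TRUE)
  edges <- data.frame(from = rownames(a)[el[, 1]], to = colnames(a)[el[, 2]])
  seeds <- sample(rownames(a), 4)
  got <- suppressWarnings(build_ppi(seeds, edges, expand_neighbors = TRUE))
  nbrs <- unique(c(seeds, unlist(lapply(seeds, function(s)
    rownames(a)[a[s, ] == 1L]))))
  expect_setequal(got$nodes$id, nbrs)
  keep <- edges$from %in% nbrs & edges$to %in% nbrs
  expect_equal(n_edges(got), sum(keep))
})

test_that("network intersection is commutative, idempotent and subset-bounded", {
  set.seed(5)
  a <- adj_to_network(random_graph_adj(10, 0.4))
  b <- adj_to_network(random_graph_adj(10, 0.4))
  ab <- intersect_networks(a, b)
  ba <- intersect_networks(b, a)
  expect_identical(ab$edges, ba$edges)
  expect_identical(intersect_networks(a, a)$edges, a$edges)
  expect_true(all(ab$nodes$id %in% a$nodes$id))
  expect_true(all(ab$nodes$id %in% b$nodes$id))
  key <- function(n) paste(n$edges$from, n$edges$to)
  expect_true(all(key(ab) %in% intersect(key(a), key(b))))
  expect_equal(sort(key(ab)), sort(intersect(key(a), key(b))))
  # disjoint networks intersect to nothing
  c1 <- path_net(c("x1", "x2", "x3"))
  c2 <- path_net(c("y1", "y2", "y3"))
  expect_equal(n_nodes(intersect_networks(c1, c2)), 0)
  # merge mode unions
  mg <- intersect_networks(c1, c2, mode = "merge")
  expect_equal(n_nodes(mg), 6)
  expect_equal(n_edges(mg), 4)
})

test_that("centralities match hand-derivable cases", {
  ct <- centralities(path_net(c("A", "B", "C")))
  expect_equal(ct$bc[ct$node == "B"], 1)
  expect_equal(ct$bc[ct$node != "B"], c(0, 0))

  k4 <- centralities(complete_net(4))
  expect_equal(k4$cc, rep(1, 4))

  star <- centralities(star_net(4))
  expect_equal(star$dc[star$node == "hub"], 4)
  expect_equal(star$nc[star$node == "hub"], 1)
  expect_equal(star$nc[star$node != "hub"], rep(4, 4))

  expect_error(centralities(interaction_network(
    data.frame(id = character(0), kind = character(0)), NULL)), "empty")
})

test_that("degree column sums to twice the edge count on random graphs", {
  set.seed(11)
  for (i in 1:10) {
    net <- adj_to_network(random_graph_adj(sample(3:9, 1)))
    ct <- centralities(net)
    expect_equal(sum(ct$dc), 2 * n_edges(net))
  }
})

test_that("median-threshold hub extraction behaves on canonical graphs", {
  # star: leaves carry the medians; only the centre strictly exceeds them
  ct <- centralities(star_net(6))
  expect_equal(extract_hubs(ct)$hubs, "hub")
  # regular graph: every centrality equals the median, strict > empties the set
  ct4 <- centralities(complete_net(4))
  expect_equal(extract_hubs(ct4)$hubs, character(0))
  expect_equal(sort(extract_hubs(ct4, strict = FALSE)$hubs), sort(ct4$node))
  # report echoes the medians used
  med <- attr(ct, "medians")
  expect_equal(extract_hubs(ct)$cutoffs, med[c("dc", "bc", "cc")])
})

test_that("hub set shrinks or stays equal as any cutoff increases", {
  spec <- sim_spec(seed = 2, ppi_nodes = 80, ppi_attach_edges = 3)
  ct <- centralities(gen_ppi(spec))
  base <- extract_hubs(ct)$hubs
  for (args in list(list(dc_cutoff = attr(ct, "medians")["dc"] + 2),
                    list(bc_cutoff = attr(ct, "medians")["bc"] * 4),
                    list(cc_cutoff = attr(ct, "medians")["cc"] * 1.1))) {
    tighter <- do.call(extract_hubs, c(list(ct), args))$hubs
    expect_true(all(tighter %in% base))
  }
  # planted high-degree nodes dominate the hub set of a scale-free graph
  planted <- attr(gen_ppi(spec), "planted_hubs")
  expect_true(all(planted %in% base))
})

test_that("edge lists read 2-column and SIF dialects", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC"), f)
  expect_equal(read_edge_list(f), data.frame(from = c("A", "B"), to = c("B", "C")))
  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tpp\tB", "B\tpp\tC"), sif)
  expect_equal(read_edge_list(sif), data.frame(from = c("A", "B"), to = c("B", "C")))
})
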