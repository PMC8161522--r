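test_that("edge loading filters, deduplicates and rescales", {
  tab <- data.frame(node_a = c("a", "b", "c", "d", "e"),
                    node_b = c("b", "c", "d", "e", "a"),
                    confidence = c(0.2, 0.39, 0.4, 0.7, 0.9))
  out <- load_edges(tab, 0.4)
  expect_equal(nrow(out), 3)           # threshold inclusive at 0.4
  expect_true(all(out$confidence >= 0.4))
  # duplicates collapse keeping max confidence
  dup <- data.frame(node_a = c("a", "b"), node_b = c("b", "a"),
                    confidence = c(0.5, 0.8))
  out2 <- load_edges(dup, 0.4)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$confidence, 0.8)
  # 0-1000 scale auto-detected: identical network to the rescaled copy
  tab1000 <- tab; tab1000$confidence <- tab$confidence * 1000
  expect_equal(load_edges(tab1000, 0.4), out)
  # file round trip with malformed row detection
  p <- tempfile(fileext = ".tsv")
  utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(load_edges(p, 0.4), out)
  bad <- tab; bad$confidence[2] <- NA
  expect_error(load_edges(bad, 0.4), "malformed")
  expect_error(load_edges(tab, 0.99), "no edges remain")
})

test_that("minppinet: connected seeds need no connectors, gaps get the shortest bridge", {
  edges <- data.frame(node_a = c("a", "b", "c"), node_b = c("b", "c", "d"),
                      confidence = 0.9)
  net <- build_minppinet(edges, c("a", "b", "c"))
  expect_length(net$connectors, 0)
  expect_setequal(igraph::V(net$graph)$name, c("a", "b", "c"))
  # seeds {a, c} with only a-b, b-c: b is the unique connector
  edges2 <- data.frame(node_a = c("a", "b"), node_b = c("b", "c"),
                       confidence = 0.9)
  net2 <- build_minppinet(edges2, c("a", "c"))
  expect_equal(net2$connectors, "b")
  expect_true(igraph::is_connected(net2$graph))
  expect_identical(igraph::V(net2$graph)$role[
    igraph::V(net2$graph)$name == "b"], "connector")
  # unreachable seeds reported, not dropped silently
  edges3 <- rbind(edges2, data.frame(node_a = "x", node_b = "y",
                                     confidence = 0.9))
  net3 <- build_minppinet(edges3, c("a", "c", "x", "zz"))
  expect_setequal(net3$unreachable_seeds, c("x", "zz"))
  expect_error(build_minppinet(edges2, c("q", "r")), "seeds present")
})

test_that("shortest-path ties break by confidence then lexicographic id", {
  # two 2-step routes a-b-c / a-d-c; b route has higher confidence
  edges <- data.frame(node_a = c("a", "b", "a", "d"),
                      node_b = c("b", "c", "d", "c"),
                      confidence = c(0.9, 0.9, 0.5, 0.5))
  net <- build_minppinet(edges, c("a", "c"))
  expect_equal(net$connectors, "b")
  # equal confidence: lexicographically smaller path wins
  edges$confidence <- 0.7
  net2 <- build_minppinet(edges, c("a", "c"))
  expect_equal(net2$connectors, "b")
})

test_that("every retained connector is load-bearing (exhaustive deletion)", {
  for (s in 1:5) {
    ppi <- simulate_ppi(150, edges_per_node = 2, seed = s)
    set.seed(s)
    seeds <- sample(ppi$edges$node_a, 12)
    net <- build_minppinet(ppi$edges, seeds)
    expect_true(igraph::is_connected(net$graph))
    expect_true(all(net$seeds %in% igraph::V(net$graph)$name))
    for (cn in net$connectors) {
      rest <- igraph::delete_vertices(net$graph, cn)
      comp <- igraph::components(rest)
      seed_comps <- unique(comp$membership[net$seeds])
      expect_gt(length(seed_comps), 1)  # removal strands a seed
    }
  }
})

test_that("betweenness matches hand values and the exhaustive oracle", {
  path3 <- build_minppinet(data.frame(node_a = c("a", "b"),
                                      node_b = c("b", "c"), confidence = 1),
                           c("a", "c"))
  hb <- betweenness_hubs(path3)
  expect_equal(hb$betweenness[hb$node == "b"], 1)
  expect_equal(sum(hb$betweenness[hb$node != "b"]), 0)
  # star: centre 1, leaves 0
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- letters[1:6]
  bw <- igraph::betweenness(star, normalized = TRUE)
  expect_equal(unname(bw), c(1, rep(0, 5)))
  # oracle equivalence on all small graphs and random 6-7 node graphs
  for (g in all_graphs(4)) {
    if (!igraph::is_connected(g)) next
    expect_equal(unname(igraph::betweenness(g, normalized = TRUE)),
                 oracle_betweenness(g), tolerance = 1e-12)
  }
  set.seed(23)
  for (i in 1:30) {
    g <- random_connected_graph(sample(6:7, 1))
    expect_equal(unname(igraph::betweenness(g, normalized = TRUE)),
                 oracle_betweenness(g), tolerance = 1e-12)
  }
  expect_error(betweenness_hubs(structure(list(
    graph = igraph::make_empty_graph(5, directed = FALSE) ,
    seeds = character(0), connectors = character(0)),
    class = "ppi_network")), "disconnected|>= 3")
})

test_that("hub control metrics match hand enumeration", {
  edges <- data.frame(node_a = c("a", "b", "c", "d"),
                      node_b = c("b", "c", "d", "e"), confidence = 1)
  net <- build_minppinet(edges, c("a", "b", "c", "d", "e"))
  ctrl <- hub_control_metrics(net, "a")
  expect_equal(ctrl$n_level1, 1)
  expect_equal(ctrl$n_level2, 2)            # closure {b, c}
  expect_equal(ctrl$pct_nodes_controlled, 50)  # 2 of the other 4 nodes
  # star centre reaches everything in one step
  star_edges <- data.frame(node_a = "hub", node_b = paste0("l", 1:5),
                           confidence = 1)
  snet <- build_minppinet(star_edges, c("hub", paste0("l", 1:5)))
  sctrl <- hub_control_metrics(snet, "hub")
  expect_equal(sctrl$pct_nodes_controlled, 100)
  sub <- hub_subnetwork(net, "a")
  expect_setequal(igraph::V(sub$graph)$name, c("a", "b", "c"))
  expect_error(hub_control_metrics(net, "zz"), "not in network")
})

test_that("degree-preserving null: invariants, enumeration agreement, planted signal", {
  ppi <- simulate_ppi(80, seed = 30, n_seed_clique = 6)
  net <- build_minppinet(ppi$edges, ppi$seeds)
  # conserved metric has empirical p = 1
  r <- degree_preserving_null(net, metric = "sum_degrees",
                              n_replicates = 50, seed = 1)
  expect_equal(r$empirical_p, 1, tolerance = 1e-12)
  # degree multiset preserved in every replicate (explicit per-replicate check)
  r2 <- degree_preserving_null(net, n_replicates = 100, seed = 2,
                               check_degrees = TRUE)
  expect_true(r2$degrees_preserved)
  expect_true(r2$empirical_p > 0 && r2$empirical_p <= 1)
  # determinism
  r3 <- degree_preserving_null(net, n_replicates = 100, seed = 2)
  expect_equal(r2$empirical_p, r3$empirical_p)
  # 4-cycle, triangle count: every simple degree-preserving graph on that
  # degree sequence, enumerated by brute force, agrees with the swap null
  cyc <- igraph::make_ring(4)
  igraph::V(cyc)$name <- letters[1:4]
  enum_counts <- vapply(Filter(function(g)
    identical(sort(igraph::degree(g)), rep(2, 4)) && igraph::is_connected(g),
    all_graphs(4)), function(g)
      length(igraph::triangles(g)) / 3, 0)
  expect_true(all(enum_counts == 0))  # no triangles on 2-regular 4-graphs
  rc <- degree_preserving_null(cyc, metric = "global_clustering",
                               n_replicates = 50, seed = 3,
                               seeds = letters[1:4], check_degrees = TRUE)
  expect_equal(rc$null_mean, 0)
  expect_error(degree_preserving_null(igraph::make_graph(c(1, 2),
                                                         directed = FALSE),
                                      seeds = "1"), "too small")
})

test_that("a planted seed clique is detected against the degree-preserving null", {
  # the null runs on the full interactome: the question is whether the seed
  # wiring is denser than chance given every node's degree
  ppi <- simulate_ppi(300, edges_per_node = 2, seed = 40, n_seed_clique = 10)
  r <- degree_preserving_null(ppi$graph, metric = "seed_internal_edges",
                              seeds = ppi$seeds,
                              n_replicates = 500, seed = 4)
  expect_equal(r$observed, 45)
  expect_lte(r$empirical_p, 0.01)
})

test_that("regulatory overlay assigns one class per edge with precedence", {
  edges <- data.frame(node_a = c("a", "b", "c"), node_b = c("b", "c", "a"),
                      confidence = 0.9)
  net <- build_minppinet(edges, c("a", "b", "c"))
  # empty table: everything predicted
  net0 <- annotate_regulatory(net, NULL)
  expect_true(all(igraph::E(net0$graph)$interaction_class == "predicted"))
  reg <- data.frame(source = c("a", "a", "b", "x"),
                    target = c("b", "b", "c", "y"),
                    class = c("complex", "activation", "inhibition",
                              "activation"))
  net1 <- annotate_regulatory(net, reg)
  cls <- igraph::E(net1$graph)$interaction_class
  eid <- igraph::get_edge_ids(net1$graph, c("a", "b"))
  expect_equal(cls[eid], "activation")  # activation outranks complex
  expect_equal(net1$n_skipped, 1)
  # partition: class counts sum to edge count
  expect_equal(sum(table(cls)), igraph::ecount(net1$graph))
})

test_that("topology diagnostics find small worlds and scale-free tails", {
  set.seed(50)
  ws <- igraph::sample_smallworld(1, 100, 4, 0.1)
  ws <- igraph::simplify(ws)
  igraph::V(ws)$name <- paste0("n", 1:100)
  d <- topology_diagnostics(ws, n_null = 30, seed = 5)
  expect_gt(d$sigma, 1)
  pa <- simulate_ppi(400, edges_per_node = 2, seed = 51)
  dpa <- topology_diagnostics(pa$graph, n_null = 10, seed = 6, xmin = 2)
  expect_gt(dpa$powerlaw_alpha, 2)
  expect_lt(dpa$powerlaw_alpha, 4)
  # complete graph: clustering 1 and the dense-graph caveat
  K <- igraph::make_full_graph(10)
  igraph::V(K)$name <- letters[1:10]
  dk <- topology_diagnostics(K, n_null = 5, seed = 7)
  expect_equal(dk$clustering, 1)
  expect_true(dk$dense_graph)
})

test_that("network exports write SIF and GraphML", {
  ppi <- simulate_ppi(30, seed = 60, n_seed_clique = 4)
  net <- build_minppinet(ppi$edges, ppi$seeds)
  sif <- tempfile(fileext = ".sif"); gml <- tempfile(fileext = ".graphml")
  write_sif(net, sif); write_graphml(net, gml)
  expect_equal(length(readLines(sif)), igraph::ecount(net$graph))
  expect_true(file.size(gml) > 0)
})
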