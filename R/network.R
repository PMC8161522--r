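#' Load and filter a confidence-scored interaction edge table
#'
#' Reads a STRING-style edge table (two id columns and a confidence score),
#' rescales 0-1000 scores to 0-1 automatically, drops self-loops, keeps
#' edges with confidence at or above `min_confidence` (boundary inclusive),
#' and collapses duplicate undirected edges keeping the maximum confidence.
#'
#' @param x path to a TSV with columns `node_a`, `node_b`, `confidence`
#'   (header optional if exactly three columns), or a `data.frame`.
#' @param min_confidence confidence threshold (default 0.4, the usual
#'   "medium confidence" cut).
#' @return `data.frame` with `node_a`, `node_b`, `confidence` in `[0, 1]`.
#' @export
load_edges <- function(x, min_confidence = 0.4) {
  if (is.character(x)) {
    first <- strsplit(readLines(x, n = 1), "\t")[[1]]
    header <- suppressWarnings(is.na(as.numeric(first[3])))
    tab <- utils::read.delim(x, header = header, stringsAsFactors = FALSE)
    if (!header) names(tab)[1:3] <- c("node_a", "node_b", "confidence")
  } else tab <- as.data.frame(x)
  need <- c("node_a", "node_b", "confidence")
  if (ncol(tab) < 3) stop("edge table needs >= 3 columns", call. = FALSE)
  if (!all(need %in% names(tab))) names(tab)[1:3] <- need
  bad <- which(is.na(tab$node_a) | is.na(tab$node_b) |
                 !is.finite(suppressWarnings(as.numeric(tab$confidence))))
  if (length(bad))
    stop("malformed edge row(s) at line(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  tab$confidence <- as.numeric(tab$confidence)
  if (max(tab$confidence) > 1) tab$confidence <- tab$confidence / 1000
  if (any(tab$confidence < 0 | tab$confidence > 1))
    stop("confidence scores outside [0, 1] after rescaling", call. = FALSE)
  tab <- tab[tab$node_a != tab$node_b, , drop = FALSE]
  tab <- tab[tab$confidence >= min_confidence, , drop = FALSE]
  if (!nrow(tab))
    stop("no edges remain after confidence filtering", call. = FALSE)
  a <- pmin(tab$node_a, tab$node_b); b <- pmax(tab$node_a, tab$node_b)
  key <- paste(a, b, sep = "\r")
  conf <- tapply(tab$confidence, key, max)
  ids <- strsplit(names(conf), "\r", fixed = TRUE)
  out <- data.frame(node_a = vapply(ids, `[`, "", 1),
                    node_b = vapply(ids, `[`, "", 2),
                    confidence = as.numeric(conf),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$node_a, out$node_b), ]
}

edges_to_graph <- function(edges) {
  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                     directed = FALSE)
  igraph::E(g)$confidence <- edges$confidence
  g
}

#' Build the minimum connected seed PPI network (MinPPINet)
#'
#' Starts from the subgraph induced on the seed genes and, while more than
#' one component remains, adds the globally shortest path (in the full
#' filtered interactome) joining two components, marking interior path
#' nodes as connectors -- a greedy Steiner-tree heuristic for the "minimum
#' fully connected" seed network. Ties between equally short paths are
#' broken by summed `1 - confidence`, then lexicographic node ids. A final
#' pruning pass removes any connector whose deletion leaves all seeds
#' mutually reachable, so every retained connector is load-bearing. Seeds
#' absent from the edge universe or unreachable from the main seed body are
#' reported, not silently dropped.
#'
#' @param edges filtered edge table from [load_edges()] (or equivalent).
#' @param seeds character vector of seed gene ids (>= 2 present in the
#'   edge universe).
#' @return Object of class `ppi_network`: `graph` (igraph, node attribute
#'   `role` = `seed`/`connector`, edge attribute `confidence`), `seeds`,
#'   `connectors`, `unreachable_seeds`.
#' @export
build_minppinet <- function(edges, seeds) {
  g <- edges_to_graph(edges)
  vs <- igraph::V(g)$name
  present <- intersect(seeds, vs)
  if (length(present) < 2)
    stop("fewer than 2 seeds present in the edge universe", call. = FALSE)
  # seeds in different components of the full graph can never be joined:
  # keep the component holding the most seeds (ties: lexicographic)
  comp <- igraph::components(g)
  seed_comp <- comp$membership[present]
  tab <- table(seed_comp)
  main <- as.integer(names(tab)[order(-tab, names(tab))][1])
  unreachable <- sort(c(setdiff(seeds, vs), present[seed_comp != main]))
  body <- present[seed_comp == main]
  g_main <- igraph::induced_subgraph(g, names(comp$membership)[comp$membership == main])

  nodes <- body
  repeat {
    sub <- igraph::induced_subgraph(g_main, nodes)
    cc <- igraph::components(sub)
    if (cc$no <= 1) break
    best <- NULL
    membership <- cc$membership[nodes]
    for (ci in seq_len(cc$no - 1)) for (cj in (ci + 1):cc$no) {
      a <- nodes[membership == ci]; b <- nodes[membership == cj]
      d <- igraph::distances(g_main, v = a, to = b)
      dmin <- min(d)
      if (!is.finite(dmin)) next
      hits <- which(d == dmin, arr.ind = TRUE)
      for (h in seq_len(nrow(hits))) {
        sp <- igraph::all_shortest_paths(g_main, from = a[hits[h, 1]],
                                         to = b[hits[h, 2]])$vpaths
        for (p in sp) {
          pn <- igraph::V(g_main)$name[p]
          w <- path_cost(g_main, pn)
          cand <- list(len = dmin, cost = w, key = paste(pn, collapse = "|"),
                       path = pn)
          if (is.null(best) ||
              cand$len < best$len ||
              (cand$len == best$len && cand$cost < best$cost) ||
              (cand$len == best$len && cand$cost == best$cost &&
                 cand$key < best$key)) best <- cand
        }
      }
    }
    if (is.null(best))
      stop("seed components cannot be joined", call. = FALSE)  # unreachable
    nodes <- union(nodes, best$path)
  }

  net <- igraph::induced_subgraph(g_main, nodes)
  connectors <- setdiff(igraph::V(net)$name, body)
  # prune removable connectors (deterministic lexicographic order)
  repeat {
    removable <- NULL
    for (cn in sort(connectors)) {
      rest <- igraph::delete_vertices(net, cn)
      cc <- igraph::components(rest)
      if (length(unique(cc$membership[body])) == 1L) { removable <- cn; break }
    }
    if (is.null(removable)) break
    net <- igraph::delete_vertices(net, removable)
    connectors <- setdiff(connectors, removable)
    # drop connectors stranded away from the seed component
    cc <- igraph::components(net)
    keep_comp <- cc$membership[body[1]]
    stranded <- igraph::V(net)$name[cc$membership != keep_comp]
    if (length(stranded)) {
      net <- igraph::delete_vertices(net, stranded)
      connectors <- setdiff(connectors, stranded)
    }
  }
  igraph::V(net)$role <- ifelse(igraph::V(net)$name %in% body,
                                "seed", "connector")
  structure(list(graph = net, seeds = sort(body),
                 connectors = sort(connectors),
                 unreachable_seeds = unreachable),
            class = "ppi_network")
}

path_cost <- function(g, path_nodes) {
  if (length(path_nodes) < 2) return(0)
  ids <- igraph::get_edge_ids(g, rbind(path_nodes[-length(path_nodes)],
                                       path_nodes[-1]))
  sum(1 - igraph::E(g)$confidence[ids])
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("Seed PPI network: %d nodes (%d seeds, %d connectors), %d edges\n",
              igraph::vcount(x$graph), length(x$seeds), length(x$connectors),
              igraph::ecount(x$graph)))
  if (length(x$unreachable_seeds))
    cat("unreachable seeds:", paste(x$unreachable_seeds, collapse = ", "), "\n")
  invisible(x)
}

#' Overlay regulatory edge classes on a network
#'
#' Assigns each undirected network edge one interaction class from a
#' directed regulatory edge table. Edges with no annotation are
#' `predicted`. When several annotations apply, precedence is
#' activation/inhibition/expression/repression over `complex` over
#' `predicted`; within the top tier the first annotation encountered wins
#' and the conflict is logged.
#'
#' @param net `ppi_network` from [build_minppinet()].
#' @param reg_table `data.frame` with columns `source`, `target`, `class`
#'   (values among `activation`, `inhibition`, `expression`, `repression`,
#'   `complex`).
#' @return The network with edge attribute `interaction_class`, plus
#'   attributes `conflicts` (log of multiply-annotated edges) and
#'   `n_skipped` (annotations whose ids are absent from the network).
#' @export
annotate_regulatory <- function(net, reg_table) {
  stopifnot(inherits(net, "ppi_network"))
  g <- net$graph
  cls <- rep("predicted", igraph::ecount(g))
  conflicts <- character(0)
  n_skipped <- 0L
  rank <- c(activation = 1, inhibition = 1, expression = 1, repression = 1,
            complex = 2, predicted = 3)
  if (!is.null(reg_table) && nrow(reg_table)) {
    vs <- igraph::V(g)$name
    for (i in seq_len(nrow(reg_table))) {
      s <- reg_table$source[i]; t <- reg_table$target[i]
      k <- reg_table$class[i]
      if (!(s %in% vs) || !(t %in% vs)) { n_skipped <- n_skipped + 1L; next }
      eid <- igraph::get_edge_ids(g, c(s, t))
      if (eid == 0) { n_skipped <- n_skipped + 1L; next }
      if (cls[eid] == "predicted" || rank[k] < rank[cls[eid]]) {
        cls[eid] <- k
      } else if (cls[eid] != k) {
        conflicts <- c(conflicts,
                       sprintf("%s--%s: kept %s, ignored %s", s, t, cls[eid], k))
      }
    }
  }
  igraph::E(g)$interaction_class <- cls
  net$graph <- g
  net$conflicts <- conflicts
  net$n_skipped <- n_skipped
  net
}

#' Betweenness centrality hub report
#'
#' Exact unweighted shortest-path betweenness, normalized to `[0, 1]`,
#' with first- and second-level interactor counts and 2-step control
#' percentages for the top `top_k` nodes. Order is decreasing betweenness,
#' ties broken by node id.
#'
#' @param net `ppi_network` (must be connected).
#' @param top_k number of hubs reported (default all nodes).
#' @return `data.frame`: `node`, `role`, `betweenness`, `n_level1`,
#'   `n_level2`, `pct_nodes_controlled`, `pct_seeds_controlled`.
#' @export
betweenness_hubs <- function(net, top_k = Inf) {
  stopifnot(inherits(net, "ppi_network"))
  g <- net$graph
  if (igraph::vcount(g) < 3) stop("need >= 3 nodes", call. = FALSE)
  if (!igraph::is_connected(g))
    stop("network is disconnected; rebuild it with build_minppinet()",
         call. = FALSE)
  bw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  nm <- igraph::V(g)$name
  ord <- order(-bw, nm)
  n <- min(top_k, length(nm))
  rows <- lapply(ord[seq_len(n)], function(i) {
    ctrl <- hub_control_metrics(net, nm[i])
    data.frame(node = nm[i], role = igraph::V(g)$role[i],
               betweenness = unname(bw[i]),
               n_level1 = ctrl$n_level1, n_level2 = ctrl$n_level2,
               pct_nodes_controlled = ctrl$pct_nodes_controlled,
               pct_seeds_controlled = ctrl$pct_seeds_controlled,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-step hub control metrics
#'
#' The 2-step closure of a hub is the hub, its neighbours (level 1) and
#' their neighbours (level 2). Control percentages are
#' `100 * |closure without the hub| / |other network nodes|` and the same
#' restricted to seeds.
#'
#' @param net `ppi_network`.
#' @param hub node id.
#' @param depth neighbourhood depth (default 2).
#' @return List: `n_level1`, `n_level2`, `pct_nodes_controlled`,
#'   `pct_seeds_controlled`.
#' @export
hub_control_metrics <- function(net, hub, depth = 2) {
  g <- net$graph
  if (!(hub %in% igraph::V(g)$name)) stop("hub not in network", call. = FALSE)
  nm <- igraph::V(g)$name
  lvl1 <- setdiff(igraph::V(g)$name[
    unlist(igraph::ego(g, order = 1, nodes = hub))], hub)
  closure <- setdiff(igraph::V(g)$name[
    unlist(igraph::ego(g, order = depth, nodes = hub))], hub)
  others <- setdiff(nm, hub)
  seeds_others <- setdiff(net$seeds, hub)
  list(
    n_level1 = length(lvl1),
    n_level2 = length(closure),
    pct_nodes_controlled = 100 * length(closure) / length(others),
    pct_seeds_controlled = if (length(seeds_others))
      100 * length(intersect(closure, seeds_others)) / length(seeds_others)
    else NA_real_
  )
}

#' Extract a hub sub-network (hub plus its interactors to a given depth)
#'
#' Returns the subgraph induced on the hub, its neighbours and (for
#' `depth = 2`) their neighbours, i.e. including edges among the level-2
#' nodes.
#'
#' @inheritParams hub_control_metrics
#' @return A `ppi_network` restricted to the closure.
#' @export
hub_subnetwork <- function(net, hub, depth = 2) {
  g <- net$graph
  if (!(hub %in% igraph::V(g)$name)) stop("hub not in network", call. = FALSE)
  keep <- igraph::V(g)$name[unlist(igraph::ego(g, order = depth, nodes = hub))]
  sub <- igraph::induced_subgraph(g, keep)
  structure(list(graph = sub,
                 seeds = intersect(net$seeds, keep),
                 connectors = intersect(net$connectors, keep),
                 unreachable_seeds = character(0)),
            class = "ppi_network")
}

null_metric_fun <- function(metric, seeds) {
  switch(metric,
    seed_internal_edges = function(g)
      igraph::ecount(igraph::induced_subgraph(g, intersect(seeds,
                                                           igraph::V(g)$name))),
    global_clustering = function(g) igraph::transitivity(g, type = "global"),
    mean_seed_distance = function(g) {
      s <- intersect(seeds, igraph::V(g)$name)
      d <- igraph::distances(g, v = s, to = s)
      mean(d[upper.tri(d)][is.finite(d[upper.tri(d)])])
    },
    sum_degrees = function(g) sum(igraph::degree(g)),
    stop("unknown null metric: ", metric, call. = FALSE)
  )
}

#' Degree-preserving null model for a connectivity statistic
#'
#' Each replicate rewires the observed graph by degree-preserving double
#' edge swaps (`10 * |E|` rewiring trials by default; no loops or multiple
#' edges created), so every replicate has exactly the observed degree
#' sequence. The empirical p-value uses the `(1 + #{null >= observed}) /
#' (n + 1)` correction and therefore never reaches 0: with finitely many
#' replicates a saturated statistic is reported as `p < 1/(n+1)`, not as an
#' asymptotic value.
#'
#' @param net `ppi_network` (or bare igraph).
#' @param metric `"seed_internal_edges"` (default; edges among seed nodes),
#'   `"global_clustering"`, `"mean_seed_distance"` or `"sum_degrees"`
#'   (invariant, for calibration).
#' @param n_replicates number of random networks (default 100000; scale
#'   down for exploration).
#' @param seed integer seed; identical seeds give identical p-values.
#' @param seeds seed node ids (taken from `net` when it is a
#'   `ppi_network`).
#' @param niter_factor rewiring trials per replicate as a multiple of the
#'   edge count.
#' @param check_degrees verify the degree multiset of every replicate
#'   (always true in spirit; the explicit check is for auditing).
#' @param alternative `"greater"` (default) or `"less"`.
#' @return List of class `null_model_result`: `metric`, `observed`,
#'   `null_mean`, `null_sd`, `empirical_p`, `n_replicates`,
#'   `degrees_preserved`.
#' @export
degree_preserving_null <- function(net, metric = "seed_internal_edges",
                                   n_replicates = 100000L, seed = 1L,
                                   seeds = NULL, niter_factor = 10,
                                   check_degrees = FALSE,
                                   alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (inherits(net, "ppi_network")) {
    if (is.null(seeds)) seeds <- net$seeds
    g <- net$graph
  } else g <- net
  if (igraph::any_multiple(g) || igraph::any_loop(g))
    stop("network must be simple", call. = FALSE)
  if (igraph::ecount(g) < 2)
    stop("graph too small to swap: no valid degree-preserving swap exists",
         call. = FALSE)
  fn <- null_metric_fun(metric, seeds)
  observed <- fn(g)
  niter <- ceiling(niter_factor * igraph::ecount(g))
  deg0 <- sort(igraph::degree(g))
  null_vals <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      r <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                    niter = niter))
      if (check_degrees && !identical(sort(igraph::degree(r)), deg0))
        stop("replicate degree sequence mismatch", call. = FALSE)
      fn(r)
    }, 0)
  })
  n_ge <- if (alternative == "greater") sum(null_vals >= observed)
          else sum(null_vals <= observed)
  structure(list(metric = metric, observed = observed,
                 null_mean = mean(null_vals), null_sd = stats::sd(null_vals),
                 empirical_p = (1 + n_ge) / (n_replicates + 1),
                 n_replicates = n_replicates,
                 degrees_preserved = TRUE,
                 alternative = alternative),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf(
    "Degree-preserving null (%d replicates), metric %s:\n  observed %.4g, null %.4g +/- %.4g, empirical p (%s) = %.3g\n",
    x$n_replicates, x$metric, x$observed, x$null_mean, x$null_sd,
    x$alternative, x$empirical_p))
  invisible(x)
}

#' Network topology diagnostics: small-world index and degree tail
#'
#' Computes the small-world coefficient
#' `sigma = (C / C_rand) / (L / L_rand)` where `C` is the global clustering
#' coefficient, `L` the mean shortest-path length, and the `_rand` values
#' are means over degree-preserving rewired replicates; and fits a
#' maximum-likelihood power law to the degree distribution.
#'
#' @param net `ppi_network` or igraph (connected, >= 20 nodes advised).
#' @param n_null rewired replicates for the reference values.
#' @param seed integer seed.
#' @param xmin minimum degree for the power-law tail fit.
#' @return List of class `topology_diagnostics`: `clustering`,
#'   `path_length`, `c_rand`, `l_rand`, `sigma`, `powerlaw_alpha`,
#'   `powerlaw_ks_p`, `dense_graph` (caveat flag for edge density > 0.5,
#'   where the small-world index is uninformative).
#' @export
topology_diagnostics <- function(net, n_null = 50L, seed = 1L, xmin = NULL) {
  g <- if (inherits(net, "ppi_network")) net$graph else net
  cobs <- igraph::transitivity(g, type = "global")
  lobs <- igraph::mean_distance(g)
  niter <- ceiling(10 * igraph::ecount(g))
  rnd <- with_seed(seed, {
    lapply(seq_len(n_null), function(i) {
      r <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                    niter = niter))
      c(igraph::transitivity(r, type = "global"), igraph::mean_distance(r))
    })
  })
  cr <- mean(vapply(rnd, `[`, 0, 1), na.rm = TRUE)
  lr <- mean(vapply(rnd, `[`, 0, 2), na.rm = TRUE)
  sigma <- if (is.finite(cr) && cr > 0) (cobs / cr) / (lobs / lr) else NA_real_
  deg <- igraph::degree(g)
  pl <- tryCatch(igraph::fit_power_law(deg, xmin = xmin),
                 error = function(e) NULL)
  dens <- igraph::edge_density(g)
  structure(list(clustering = cobs, path_length = lobs,
                 c_rand = cr, l_rand = lr, sigma = sigma,
                 powerlaw_alpha = if (!is.null(pl)) pl$alpha else NA_real_,
                 powerlaw_ks_p = if (!is.null(pl) && !is.null(pl$KS.p))
                   pl$KS.p else NA_real_,
                 dense_graph = dens > 0.5),
            class = "topology_diagnostics")
}

#' @export
print.topology_diagnostics <- function(x, ...) {
  cat(sprintf("C = %.3f (rand %.3f), L = %.2f (rand %.2f), sigma = %.2f\n",
              x$clustering, x$c_rand, x$path_length, x$l_rand, x$sigma))
  cat(sprintf("degree tail power-law alpha = %.2f%s\n", x$powerlaw_alpha,
              if (isTRUE(x$dense_graph)) " [dense graph: interpret with care]"
              else ""))
  invisible(x)
}

#' Export a network as SIF (simple interaction format)
#' @param net `ppi_network`.
#' @param path output path.
#' @export
write_sif <- function(net, path) {
  g <- net$graph
  el <- igraph::as_edgelist(g)
  cls <- if (!is.null(igraph::E(g)$interaction_class))
    igraph::E(g)$interaction_class else rep("pp", nrow(el))
  writeLines(paste(el[, 1], cls, el[, 2], sep = "\t"), path)
}

#' Export a network as GraphML
#' @param net `ppi_network`.
#' @param path output path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
}
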