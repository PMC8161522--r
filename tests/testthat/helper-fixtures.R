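# Shared fixture builders: everything is generated in code at test time.

toy_genome <- function(n = 10, n_chrom = 1, seed = 42) {
  generate_genome(n, n_chrom, seed = seed)
}

# expression matrix with an exact additive log2 shift for selected genes
shifted_matrix <- function(m = 50, n_c = 3, n_t = 3, shift_genes = integer(0),
                           shift = 1, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(m * (n_c + n_t), 8, noise_sd), nrow = m,
              dimnames = list(sprintf("g%03d", 1:m),
                              c(paste0("c", 1:n_c), paste0("t", 1:n_t))))
  x[shift_genes, (n_c + 1):(n_c + n_t)] <-
    x[shift_genes, (n_c + 1):(n_c + n_t)] + shift
  x
}

toy_groups <- function(n_c, n_t) {
  factor(rep(c("control", "trisomic"), c(n_c, n_t)),
         levels = c("control", "trisomic"))
}

# independent sort-based oracle for the FCROS rank statistic
oracle_rbar <- function(fc) {
  m <- nrow(fc)
  ranks <- matrix(0, m, ncol(fc))
  for (j in seq_len(ncol(fc))) {
    # explicit sort-based ranking with average ties
    v <- fc[, j]
    ord <- order(v)
    r <- numeric(m)
    i <- 1
    while (i <= m) {
      run <- which(v[ord] == v[ord[i]])
      r[ord[run]] <- mean(run)
      i <- max(run) + 1
    }
    ranks[, j] <- r / m
  }
  rowMeans(ranks)
}

# exhaustive betweenness oracle: enumerate all shortest paths per pair
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- igraph::all_shortest_paths(g, from = s, to = t)$vpaths
    if (!length(paths)) next
    for (p in paths) {
      inner <- setdiff(as.integer(p), c(s, t))
      b[inner] <- b[inner] + 1 / length(paths)
    }
  }
  if (n > 2) b / ((n - 1) * (n - 2) / 2) else b
}

# all labeled graphs on n nodes as edge subsets; returns list of igraphs
all_graphs <- function(n) {
  pairs <- t(combn(n, 2))
  n_e <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^n_e - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n_e) - 1)) != 0)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (length(sel))
      g <- igraph::add_edges(g, t(pairs[sel, , drop = FALSE]))
    out[[length(out) + 1]] <- g
  }
  out
}

random_connected_graph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) return(g)
  }
}

# direct pairwise-variation geNorm formula (independent of genorm_select)
oracle_genorm_m <- function(q) {
  nc <- ncol(q)
  sapply(seq_len(nc), function(j)
    mean(sapply(setdiff(seq_len(nc), j), function(k)
      sd(log2(q[, j] / q[, k])))))
}
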