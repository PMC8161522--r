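test_that("gene classification follows the TEG bookkeeping rules", {
  genome <- data.frame(gene_id = sprintf("g%02d", 1:10), chrom = "chr1",
                       start = seq(100, 1000, by = 100),
                       end = seq(150, 1050, by = 100))
  # interval covering genes 3-5
  mdl <- trisomy_model("m", data.frame(chrom = "chr1", start = 300, end = 520))
  cls <- classify_genes(genome, mdl, expressed = genome$gene_id,
                        degs = c("g04", "g09"))
  expect_equal(sum(cls$teg), 3)
  expect_equal(sum(cls$differential_teg), 1)
  # genes outside every interval are never TEGs
  expect_false(any(cls$teg[!cls$in_trisomic_region]))
  # invariants: differential_teg => teg => expressed
  expect_true(all(cls$teg[cls$differential_teg]))
  expect_true(all(cls$expressed[cls$teg]))
  cf <- compensation_fraction(cls)
  expect_equal(cf$pct_differential, 33)
  expect_equal(cf$pct_compensated, 67)
  expect_error(classify_genes(genome, mdl, genome$gene_id, degs = "nope"),
               "absent from annotation")
})

test_that("a single-gene model with its gene differential is 100% differential", {
  genome <- toy_genome(20)
  g5 <- genome[5, ]
  mdl <- trisomy_model("tg", data.frame(chrom = g5$chrom, start = g5$start,
                                        end = g5$end))
  cls <- classify_genes(genome, mdl, expressed = genome$gene_id,
                        degs = g5$gene_id)
  cf <- compensation_fraction(cls)
  expect_equal(cf$n_teg, 1)
  expect_equal(cf$pct_differential, 100)
  expect_equal(cf$pct_compensated, 0)
})

test_that("compensation arithmetic reproduces the published panel summary", {
  teg <- c(155, 21, 130, 127, 87, 40, 1, 40)
  diff <- c(66, 13, 64, 54, 39, 18, 1, 28)
  pct <- mapply(function(n, d) compensation_fraction(n, d)$pct_differential,
                teg, diff)
  expect_equal(pct, c(43, 62, 49, 43, 45, 45, 100, 70))
  comp <- mapply(function(n, d) compensation_fraction(n, d)$pct_compensated,
                 teg[1:7], diff[1:7])
  expect_equal(comp, c(57, 38, 51, 57, 55, 55, 0))
  # edge cases
  expect_equal(compensation_fraction(10, 0)$pct_compensated, 100)
  expect_error(compensation_fraction(0, 0), "no trisomic expressed genes")
  expect_error(compensation_fraction(5, 6), "exceed")
})

test_that("estimated compensation recovers the generator parameter", {
  genome <- generate_genome(20000, 1, seed = 14)
  mdl <- trisomy_model("m", data.frame(chrom = "chr1",
                                       start = genome$start[1],
                                       end = genome$end[250]))
  des <- expression_design()
  for (s in 1:3) {
    sim <- simulate_expression(genome, mdl, des, seed = s)
    fit <- fcros(sim)
    cls <- classify_genes(genome, mdl, expressed_genes(sim), call_degs(fit))
    est <- compensation_fraction(cls)$pct_compensated
    realized <- 100 * sum(sim$truth$label == "cis_compensated") /
      sum(sim$truth$label %in% c("cis", "cis_compensated"))
    expect_lt(abs(est - realized), 5)
  }
})

test_that("fold-change correlation matrix behaves like a correlation", {
  genome <- generate_genome(4000, 2, seed = 15)
  panel <- generate_model_panel(genome)
  des <- expression_design(n_trans_effects = 80, shared_program_fraction = 1)
  fits <- lapply(panel[c("DpFull", "DpMid", "DpDist")], function(m)
    fcros(simulate_expression(genome, m, des, seed = 16,
                              reference = panel$DpFull)))
  cmp <- cross_model_fc_correlation(fits)
  expect_equal(diag(cmp$percent), rep(100, 3), ignore_attr = TRUE)
  expect_equal(cmp$r, t(cmp$r))
  expect_true(all(cmp$r >= -1 & cmp$r <= 1))
  expect_gte(min(eigen(cmp$r, symmetric = TRUE)$values), -1e-8)
  expect_error(cross_model_fc_correlation(fits[1]), ">= 2 models")
})

test_that("independent effect programs give near-zero correlation, shared ones scale with the fraction", {
  genome <- generate_genome(10000, 2, seed = 17)
  g1 <- genome[genome$chrom == "chr1", ]
  g2 <- genome[genome$chrom == "chr2", ]
  mk <- function(nm, g) trisomy_model(nm, data.frame(chrom = g$chrom[1],
                                                     start = g$start[1],
                                                     end = g$end[100]))
  m1 <- mk("m1", g1); m2 <- mk("m2", g2)  # disjoint intervals
  corr_at <- function(frac) {
    des <- expression_design(n_trans_effects = 200,
                             shared_program_fraction = frac)
    f1 <- fcros(simulate_expression(genome, m1, des, seed = 18))
    f2 <- fcros(simulate_expression(genome, m2, des, seed = 18))
    # universe: all genes outside both cis regions (trans landscape)
    uni <- setdiff(genome$gene_id, c(cis_genes(genome, m1),
                                     cis_genes(genome, m2)))
    cross_model_fc_correlation(list(a = f1, b = f2), universe = uni)$r[1, 2]
  }
  r <- vapply(c(0, 0.5, 1), corr_at, 0)
  expect_lt(abs(r[1]), 0.05)
  expect_true(all(diff(r) > 0))  # monotone in the shared fraction
})

test_that("deg overlap enumerates the Venn partition consistently", {
  ov <- deg_overlap(list(A = "a", B = "b"))
  expect_equal(ov$pairwise["A", "B"], 0)
  ov2 <- deg_overlap(list(A = c("a", "b", "c"), B = c("b", "c", "d"),
                          C = "c"))
  expect_equal(unname(ov2$partition[["A&B&C"]]), 1)
  expect_equal(unname(ov2$partition[["A&B"]]), 1)   # {b}
  expect_equal(ov2$union_size, 4)
  # inclusion-exclusion on random sets: partition sums to the union
  set.seed(19)
  sets <- lapply(1:4, function(i) sample(letters, sample(5:15, 1)))
  names(sets) <- paste0("S", 1:4)
  ov3 <- deg_overlap(sets)
  expect_equal(sum(ov3$partition), ov3$union_size)
  expect_equal(ov3$union_size, length(Reduce(union, sets)))
})

test_that("sample embeddings separate planted groups and stay put on noise", {
  genome <- generate_genome(500, 1, seed = 20)
  mdl <- trisomy_model("m", data.frame(chrom = "chr1", start = genome$start[1],
                                       end = genome$end[100]))
  sim <- simulate_expression(genome, mdl,
                             expression_design(compensation_prob = 0,
                                               n_trans_effects = 0), seed = 21)
  degs <- call_degs(fcros(sim))$gene_id
  for (meth in c("pca", "spectral")) {
    emb <- sample_embedding(sim$values, sim$groups, genes = degs,
                            method = meth, k = 3)
    expect_gt(emb$silhouette, 0.5)
    emb2 <- sample_embedding(sim$values, sim$groups, genes = degs,
                             method = meth, k = 3)
    expect_identical(emb$coords, emb2$coords)  # deterministic
  }
  # identical samples + jitter: no real separation
  set.seed(22)
  x <- matrix(8, 100, 10) + rnorm(1000, 0, 0.01)
  rownames(x) <- sprintf("g%03d", 1:100)
  colnames(x) <- sprintf("s%02d", 1:10)
  emb0 <- sample_embedding(x, rep(c("a", "b"), each = 5))
  expect_lt(abs(emb0$silhouette), 0.25)
  expect_error(sample_embedding(x[, 1:3], rep("a", 3)), ">= 4 samples")
  expect_error(sample_embedding(x[, 1:4], rep(c("a", "b"), 2),
                                n_components = 4), "components")
})
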