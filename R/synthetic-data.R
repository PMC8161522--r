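#' Generate a synthetic genome annotation
#'
#' Builds a gene annotation table with `n_genes` genes spread as evenly as
#' possible over `n_chromosomes` chromosomes, with non-overlapping,
#' strictly increasing coordinates on each chromosome. The table is the
#' substrate for defining duplicated (trisomic) intervals and for the
#' expression simulator.
#'
#' @param n_genes total number of genes (>= `n_chromosomes`).
#' @param n_chromosomes number of chromosomes.
#' @param seed integer seed; the same seed always yields the identical
#'   annotation.
#' @param gene_length,gap mean gene length and intergenic gap in base pairs.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   one row per gene, sorted by chromosome then start.
#' @examples
#' g <- generate_genome(10, 2, seed = 1)
#' table(g$chrom)
#' @export
generate_genome <- function(n_genes, n_chromosomes, seed,
                            gene_length = 20000, gap = 30000) {
  stopifnot_scalar_count(n_genes, "n_genes")
  stopifnot_scalar_count(n_chromosomes, "n_chromosomes")
  if (n_genes < n_chromosomes)
    stop("`n_genes` must be >= `n_chromosomes`", call. = FALSE)
  with_seed(seed, {
    chrom_of <- sort(rep_len(seq_len(n_chromosomes), n_genes))
    width <- pmax(200L, round(stats::rexp(n_genes, 1 / gene_length)))
    spacing <- pmax(1L, round(stats::rexp(n_genes, 1 / gap)))
    ann <- do.call(rbind, lapply(split(seq_len(n_genes), chrom_of), function(idx) {
      start <- cumsum(c(1L, (width[idx] + spacing[idx])[-length(idx)]))
      data.frame(idx = idx, start = start, end = start + width[idx] - 1L)
    }))
    ann <- ann[order(ann$idx), ]
    data.frame(
      gene_id = sprintf("g%0*d", nchar(n_genes), seq_len(n_genes)),
      chrom = paste0("chr", chrom_of),
      start = ann$start,
      end = ann$end,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
}

#' Define a trisomy model (segmental duplication line)
#'
#' A trisomy model is a named set of duplicated genomic intervals carried at
#' `copy_number` copies, optionally with additional non-syntenic intervals
#' (emulating lines whose extra chromosome carries genes outside the region
#' of interest, as in Ts65Dn's centromeric Mmu17 segment).
#'
#' @param name model name.
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`.
#' @param copy_number integer >= 2; 3 for a standard segmental duplication.
#' @param nonsyntenic optional `data.frame` of extra duplicated intervals.
#' @return An object of class `trisomy_model`.
#' @export
trisomy_model <- function(name, intervals, copy_number = 3L, nonsyntenic = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  check_iv <- function(iv, what) {
    if (!is.data.frame(iv) || !all(c("chrom", "start", "end") %in% names(iv)))
      stop(sprintf("%s must have columns chrom, start, end", what), call. = FALSE)
    if (any(iv$end < iv$start)) stop("degenerate interval (end < start)", call. = FALSE)
    iv[, c("chrom", "start", "end")]
  }
  intervals <- check_iv(intervals, "`intervals`")
  if (!is.null(nonsyntenic)) nonsyntenic <- check_iv(nonsyntenic, "`nonsyntenic`")
  if (copy_number < 2) stop("`copy_number` must be >= 2", call. = FALSE)
  structure(list(name = name, intervals = intervals,
                 copy_number = as.integer(copy_number),
                 nonsyntenic = nonsyntenic),
            class = "trisomy_model")
}

#' @export
print.trisomy_model <- function(x, ...) {
  cat("Trisomy model", x$name, "-", nrow(x$intervals), "duplicated interval(s),",
      x$copy_number, "copies\n")
  invisible(x)
}

# All duplicated intervals of a model (syntenic + non-syntenic).
model_intervals <- function(model, include_nonsyntenic = TRUE) {
  iv <- model$intervals
  if (include_nonsyntenic && !is.null(model$nonsyntenic))
    iv <- rbind(iv, model$nonsyntenic)
  iv
}

#' Genes lying inside a model's duplicated intervals
#'
#' Membership rule, used consistently across the package: a gene belongs to
#' an interval iff its start coordinate lies within the closed interval
#' (1-based, inclusive).
#'
#' @param genome annotation from [generate_genome()] (or same columns).
#' @param model a [trisomy_model()].
#' @param include_nonsyntenic include the model's non-syntenic intervals.
#' @return Character vector of cis gene ids.
#' @export
cis_genes <- function(genome, model, include_nonsyntenic = TRUE) {
  iv <- model_intervals(model, include_nonsyntenic)
  unknown <- setdiff(iv$chrom, genome$chrom)
  if (length(unknown))
    stop("model intervals reference unknown chromosome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  hit <- rep(FALSE, nrow(genome))
  for (i in seq_len(nrow(iv)))
    hit <- hit | (genome$chrom == iv$chrom[i] &
                  genome$start >= iv$start[i] & genome$start <= iv$end[i])
  genome$gene_id[hit]
}

#' Generate a panel of overlapping trisomy models
#'
#' Produces the canonical panel geometry of segmental-duplication studies: a
#' full-span model containing several sub-span models, a compound model
#' equal to the union of two disjoint sub-spans, a single-gene transgenic
#' model, and a variant of the compound model that additionally carries a
#' non-syntenic duplicated segment on another chromosome.
#'
#' @param genome annotation table.
#' @param chrom chromosome carrying the syntenic region (default first).
#' @param layout optional list of named interval specifications as gene-index
#'   ranges `list(name = c(from, to))` into the chromosome's gene order;
#'   indices must be valid. When `NULL` a default nested layout is used.
#' @return Named list of [trisomy_model()] objects.
#' @export
generate_model_panel <- function(genome, chrom = NULL, layout = NULL) {
  if (is.null(chrom)) chrom <- genome$chrom[1]
  g <- genome[genome$chrom == chrom, ]
  g <- g[order(g$start), ]
  n <- nrow(g)
  if (n < 10) stop("need >= 10 genes on the target chromosome", call. = FALSE)
  idx <- function(frac) max(1L, min(n, round(frac * n)))
  if (is.null(layout)) {
    layout <- list(
      DpFull = c(1L, n),                       # full syntenic span
      DpProx = c(1L, idx(0.25)),               # proximal sub-span
      DpMid  = c(idx(0.30), idx(0.60)),        # middle sub-span
      DpDist = c(idx(0.65), n),                # distal sub-span
      TgOne  = c(idx(0.80), idx(0.80))         # single-gene transgenic
    )
  }
  for (nm in names(layout)) {
    rg <- layout[[nm]]
    if (any(rg < 1L) || any(rg > n) || rg[1] > rg[2])
      stop("layout `", nm, "` outside genome bounds", call. = FALSE)
  }
  span <- function(rg) data.frame(chrom = chrom,
                                  start = g$start[rg[1]], end = g$end[rg[2]])
  models <- lapply(names(layout), function(nm) trisomy_model(nm, span(layout[[nm]])))
  names(models) <- names(layout)
  # compound model: union of two disjoint sub-spans (Dp5/Dp1-like)
  if (all(c("DpMid", "DpDist") %in% names(models))) {
    models$DpCompound <- trisomy_model(
      "DpCompound", rbind(models$DpMid$intervals, models$DpDist$intervals))
    # compound plus a non-syntenic segment on another chromosome (Ts65Dn-like)
    other <- setdiff(unique(genome$chrom), chrom)
    if (length(other)) {
      go <- genome[genome$chrom == other[1], ]
      go <- go[order(go$start), ]
      k <- max(1L, min(nrow(go), round(0.2 * nrow(go))))
      models$TsLike <- trisomy_model(
        "TsLike", rbind(models$DpMid$intervals, models$DpDist$intervals),
        nonsyntenic = data.frame(chrom = other[1], start = go$start[1],
                                 end = go$end[k]))
    }
  }
  models
}

#' Expression simulation design
#'
#' Holds the per-model simulation parameters: group sizes, baseline and
#' noise scales (log2 units), the linear dosage ratio of a three-copy gene,
#' the probability that a cis gene is dosage-compensated, and the size and
#' cross-model sharing of the genome-wide trans-effect program.
#'
#' @param n_control,n_trisomic animals per group.
#' @param baseline_mean,baseline_sd log2 baseline intensity distribution.
#' @param noise_sd residual per-sample noise, log2 units.
#' @param dosage_ratio linear fold change of a non-compensated cis gene
#'   (3 copies vs 2 gives 1.5).
#' @param compensation_prob probability a cis gene shows no dosage effect.
#' @param n_trans_effects number of non-cis genes given trans effects.
#' @param trans_effect_sd SD of trans effect sizes, log2 units.
#' @param shared_program_fraction fraction of the trans program drawn from a
#'   pool shared between models simulated under the same design seed, in
#'   proportion to their interval overlap with the reference span.
#' @param rng_seed default seed used when `simulate_expression()` is called
#'   without one.
#' @return A list of class `expression_design`.
#' @export
expression_design <- function(n_control = 5L, n_trisomic = 5L,
                              baseline_mean = 8, baseline_sd = 1.5,
                              noise_sd = 0.15, dosage_ratio = 1.5,
                              compensation_prob = 0.5,
                              n_trans_effects = 300L, trans_effect_sd = 0.4,
                              shared_program_fraction = 0.5,
                              rng_seed = 1L) {
  stopifnot_scalar_count(n_control, "n_control", min = 2L)
  stopifnot_scalar_count(n_trisomic, "n_trisomic", min = 2L)
  if (dosage_ratio <= 0) stop("`dosage_ratio` must be > 0", call. = FALSE)
  for (p in c(compensation_prob, shared_program_fraction))
    if (p < 0 || p > 1) stop("probabilities/fractions must lie in [0,1]", call. = FALSE)
  structure(as.list(environment()), class = "expression_design")
}

#' Simulate a log2 expression matrix for one trisomy model
#'
#' Cis genes (inside the model's duplicated intervals) are shifted by
#' `log2(dosage_ratio)` in the trisomic group unless flagged compensated
#' (probability `compensation_prob`); `n_trans_effects` non-cis genes
#' receive trans effects drawn from `Normal(0, trans_effect_sd)`; i.i.d.
#' `Normal(0, noise_sd)` noise is added throughout. A fraction of the trans
#' program is reused across models simulated under the same design seed, in
#' proportion to the overlap of the model's intervals with `reference`
#' (default: the model's own span, weight 1), which makes cross-model
#' fold-change correlation a controllable generator parameter.
#'
#' @param genome annotation table.
#' @param model a [trisomy_model()].
#' @param design an [expression_design()].
#' @param seed overrides `design$rng_seed` (model-specific randomness still
#'   differs between models via the model name).
#' @param reference optional [trisomy_model()] whose intervals define the
#'   span against which interval overlap is measured (typically the panel's
#'   full-span model).
#' @return List of class `sim_expression` with elements `values` (log2
#'   matrix, genes x samples), `groups` (factor `control`/`trisomic`),
#'   `truth` (per-gene label `cis`, `cis_compensated`, `trans` or `null`,
#'   and the planted log2 effect).
#' @export
simulate_expression <- function(genome, model, design = expression_design(),
                                seed = NULL, reference = NULL) {
  if (is.null(seed)) seed <- design$rng_seed
  ids <- genome$gene_id
  m <- length(ids)
  cis <- ids %in% cis_genes(genome, model)

  # shared trans pool: deterministic given the design seed only, so two
  # models under one design can reuse the same (gene, effect) draws
  pool <- with_seed(seed + 10007L, {
    ord <- sample.int(m)
    data.frame(gene = ids[ord],
               effect = stats::rnorm(m, 0, design$trans_effect_sd))
  })

  w <- overlap_weight(model, reference)
  n_trans <- min(design$n_trans_effects, sum(!cis))
  n_shared <- round(design$shared_program_fraction * w * n_trans)

  model_seed <- seed + (utf8ToInt(substr(paste0(model$name, "____"), 1, 4)) %*%
                          c(1L, 256L, 7L, 31L))[1] %% 99991L
  with_seed(model_seed, {
    effect <- numeric(m)
    label <- rep("null", m)
    # cis effects with compensation
    comp <- stats::runif(m) < design$compensation_prob
    shift <- log2(design$dosage_ratio) * (model$copy_number - 2L)
    effect[cis & !comp] <- shift
    label[cis & !comp] <- "cis"
    label[cis & comp] <- "cis_compensated"
    # trans program: shared pool entries first, then model-specific draws
    shared <- pool[!(pool$gene %in% ids[cis]), , drop = FALSE]
    shared <- utils::head(shared, n_shared)
    free <- setdiff(ids[!cis], shared$gene)
    n_own <- n_trans - nrow(shared)
    own <- if (n_own > 0)
      data.frame(gene = sample(free, n_own),
                 effect = stats::rnorm(n_own, 0, design$trans_effect_sd))
    else shared[0, ]
    trans <- rbind(shared, own)
    effect[match(trans$gene, ids)] <- trans$effect
    label[match(trans$gene, ids)] <- "trans"

    n_c <- design$n_control; n_t <- design$n_trisomic
    baseline <- stats::rnorm(m, design$baseline_mean, design$baseline_sd)
    vals <- matrix(stats::rnorm(m * (n_c + n_t), 0, design$noise_sd),
                   nrow = m) + baseline
    vals[, (n_c + 1):(n_c + n_t)] <- vals[, (n_c + 1):(n_c + n_t)] + effect
    dimnames(vals) <- list(ids, c(sprintf("wt_%d", seq_len(n_c)),
                                  sprintf("tg_%d", seq_len(n_t))))
    structure(list(
      values = vals,
      groups = factor(rep(c("control", "trisomic"), c(n_c, n_t)),
                      levels = c("control", "trisomic")),
      truth = data.frame(gene_id = ids, label = label, effect = effect,
                         stringsAsFactors = FALSE),
      model = model$name
    ), class = "sim_expression")
  })
}

# Fraction of the model's duplicated length overlapping the reference span.
overlap_weight <- function(model, reference) {
  if (is.null(reference)) return(1)
  a <- model_intervals(model); b <- model_intervals(reference)
  len <- function(iv) sum(iv$end - iv$start + 1)
  ov <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    lo <- max(a$start[i], b$start[j]); hi <- min(a$end[i], b$end[j])
    if (hi >= lo) ov <- ov + (hi - lo + 1)
  }
  la <- len(a)
  if (la == 0) 0 else ov / la
}

#' Simulate a confidence-scored protein-interaction network
#'
#' Grows an undirected preferential-attachment graph (heavy-tailed degree
#' distribution, as observed for real interactomes), assigns each edge a
#' confidence score, and optionally plants a fully connected clique over
#' `n_seed_clique` nodes to emulate a densely wired functional module.
#'
#' @param n_nodes number of proteins (>= 3).
#' @param edges_per_node attachment parameter `m` of the growth process.
#' @param seed integer seed.
#' @param n_seed_clique size of the planted seed clique (0 for none).
#' @param score_range range of the confidence scores of background edges;
#'   planted clique edges get scores in the upper half.
#' @return List with `edges` (`data.frame`: `node_a`, `node_b`,
#'   `confidence`), `seeds` (ids of planted-clique members) and `graph`
#'   (an `igraph` object).
#' @export
simulate_ppi <- function(n_nodes, edges_per_node = 2L, seed = 1L,
                         n_seed_clique = 0L, score_range = c(0.2, 1)) {
  stopifnot_scalar_count(n_nodes, "n_nodes", min = 3L)
  with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = edges_per_node, directed = FALSE)
    igraph::V(g)$name <- sprintf("p%0*d", nchar(n_nodes), seq_len(n_nodes))
    seeds <- character(0)
    if (n_seed_clique > 0) {
      if (n_seed_clique > n_nodes) stop("clique larger than graph", call. = FALSE)
      seeds <- sample(igraph::V(g)$name, n_seed_clique)
      need <- t(utils::combn(seeds, 2))
      have <- igraph::as_edgelist(g)
      key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
      add <- need[!(key(need) %in% key(have)), , drop = FALSE]
      if (nrow(add)) g <- igraph::add_edges(g, t(add))
    }
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g)
    conf <- stats::runif(nrow(el), score_range[1], score_range[2])
    in_clique <- el[, 1] %in% seeds & el[, 2] %in% seeds
    conf[in_clique] <- stats::runif(sum(in_clique), mean(score_range), score_range[2])
    igraph::E(g)$confidence <- conf
    list(edges = data.frame(node_a = el[, 1], node_b = el[, 2],
                            confidence = conf, stringsAsFactors = FALSE),
         seeds = sort(seeds), graph = g)
  })
}

#' Simulate phenotype tables
#'
#' Generates the three non-transcriptome data types the quantification
#' stage consumes: a behaviour table (one measure per animal, bounded to
#' `[0, 100]` for percentage measures), a qPCR cycle-threshold table over
#' target and candidate reference genes with genotype and light-exposure
#' metadata, and an MRI morphometry table of structure volumes plus whole
#' brain volume.
#'
#' @param n_per_group animals per genotype group.
#' @param group_effect additive shift applied to the non-reference groups'
#'   behaviour measure (0 = null simulation).
#' @param groups genotype labels; first is the reference (wild type).
#' @param behaviour_mean,behaviour_sd behaviour measure distribution.
#' @param shifted_structure,structure_shift index of one brain structure
#'   receiving a relative volume shift in non-wt animals, and its size
#'   (e.g. 0.2 for +20%).
#' @param seed integer seed.
#' @return List with `behaviour`, `qpcr`, `morphometry` data frames.
#' @export
simulate_phenotypes <- function(n_per_group = 12L, group_effect = 0,
                                groups = c("wt", "tg"),
                                behaviour_mean = 55, behaviour_sd = 8,
                                shifted_structure = NULL, structure_shift = 0,
                                seed = 1L) {
  with_seed(seed, {
    n_g <- length(groups)
    n <- n_per_group * n_g
    genotype <- factor(rep(groups, each = n_per_group), levels = groups)
    eff <- ifelse(genotype == groups[1], 0, group_effect)
    beh <- data.frame(
      animal = sprintf("a%02d", seq_len(n)),
      genotype = genotype,
      measure = pmin(100, pmax(0, stats::rnorm(n, behaviour_mean + eff,
                                               behaviour_sd))))

    qpcr_genes <- c("target1", "target2", "ref1", "ref2", "ref3")
    conds <- c("dark", "1h", "3h", "7.5h")
    meta <- expand.grid(genotype = groups, condition = conds,
                        rep = 1:3, KEEP.OUT.ATTRS = FALSE)
    meta$sample <- sprintf("s%02d", seq_len(nrow(meta)))
    gene_base <- stats::setNames(stats::runif(length(qpcr_genes), 18, 26), qpcr_genes)
    qpcr <- do.call(rbind, lapply(qpcr_genes, function(gn) {
      induce <- if (grepl("^target", gn))
        ifelse(meta$condition == "dark", 0, -1.5) else 0
      data.frame(sample = meta$sample, gene = gn,
                 ct = gene_base[gn] + induce + stats::rnorm(nrow(meta), 0, 0.15),
                 genotype = meta$genotype, condition = meta$condition,
                 row.names = NULL)
    }))

    n_struct <- 10L
    frac <- stats::runif(n_struct, 0.01, 0.08)
    wb <- stats::rnorm(n, 450, 15)
    morph <- do.call(rbind, lapply(seq_len(n), function(i) {
      f <- frac
      if (!is.null(shifted_structure) && genotype[i] != groups[1])
        f[shifted_structure] <- f[shifted_structure] * (1 + structure_shift)
      data.frame(animal = beh$animal[i], genotype = genotype[i],
                 structure = sprintf("struct%02d", seq_len(n_struct)),
                 volume = wb[i] * f * (1 + stats::rnorm(n_struct, 0, 0.05)),
                 whole_brain = wb[i], row.names = NULL)
    }))
    list(behaviour = beh, qpcr = qpcr, morphometry = morph)
  })
}
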