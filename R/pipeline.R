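#' Read an expression matrix and sample sheet from TSV
#'
#' @param matrix_path TSV, rows = genes (first column = gene id),
#'   columns = samples.
#' @param samples_path TSV with columns `sample`, `genotype` (values
#'   `control`/`trisomic` or `wt`/`tg`).
#' @return List with `values` (matrix) and `groups` (factor).
#' @export
read_expression_tsv <- function(matrix_path, samples_path) {
  x <- utils::read.delim(matrix_path, check.names = FALSE)
  values <- as.matrix(x[, -1, drop = FALSE])
  rownames(values) <- x[[1]]
  ss <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "genotype") %in% names(ss)))
  ss <- ss[match(colnames(values), ss$sample), ]
  if (anyNA(ss$sample)) stop("sample sheet does not cover all columns",
                             call. = FALSE)
  g <- ifelse(ss$genotype %in% c("control", "wt"), "control", "trisomic")
  list(values = values,
       groups = factor(g, levels = c("control", "trisomic")))
}

#' Write a simulated expression data set as TSV files
#'
#' Writes the expression matrix, sample sheet, annotation and truth labels
#' under `dir` with fixed names.
#'
#' @param sim a `sim_expression` object.
#' @param genome the annotation used to simulate it.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_expression_tsv <- function(sim, genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("expression.tsv", "samples.tsv",
                            "annotation.tsv", "truth.tsv"))
  utils::write.table(data.frame(gene_id = rownames(sim$values), sim$values,
                                check.names = FALSE),
                     paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(sim$values),
                                genotype = as.character(sim$groups)),
                     paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genome, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Validate a pipeline run configuration
#'
#' Checks structural validity before any computation: an explicit seed, an
#' output directory, and existence of every referenced input file.
#'
#' @param config list (or path to a YAML file).
#' @return The normalized config list, invisibly classed `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must set an explicit `seed`",
                                 call. = FALSE)
  if (is.null(config$outdir)) stop("config must set `outdir`", call. = FALSE)
  for (p in c(config$expression$matrix, config$expression$samples,
              config$genesets$gmt, config$network$edges,
              config$network$seeds_file)) {
    if (!is.null(p) && !file.exists(p))
      stop("input file does not exist: ", p, call. = FALSE)
  }
  defaults <- list(
    dge = list(alpha_low = 0.025, alpha_high = 0.975,
               standardization = "empirical"),
    genesets = list(q_cutoff = 0.1, n_random_sets = 60L, set_size = 25L),
    network = list(min_confidence = 0.4, null_metric = "seed_internal_edges",
                   null_replicates = 1000L, n_nodes = 300L,
                   n_seed_clique = 10L),
    simulate = list(n_genes = 2000L, n_chromosomes = 3L,
                    design = list())
  )
  for (sec in names(defaults))
    config[[sec]] <- utils::modifyList(defaults[[sec]],
                                       if (is.null(config[[sec]])) list()
                                       else config[[sec]])
  class(config) <- c("run_config", "list")
  invisible(config)
}

#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate (optional) -> differential expression -> trisomy
#' bookkeeping -> gene sets / meta-pathways -> network decomposition ->
#' phenotype statistics, writing per-stage outputs under `outdir` and a
#' manifest recording every parameter, seed and output checksum. Identical
#' configurations yield identical manifests.
#'
#' @param config list or YAML path, see [validate_config()]. When no
#'   expression input files are given, data are simulated from the
#'   config's generator parameters.
#' @return List of class `run_result`: `summary` (per-model TEG/DEG/
#'   compensation table), `correlation`, `meta` (meta-pathway matrix),
#'   `hubs`, `null` (null-model result), `behaviour`, `mri`, `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)

  # --- stage: data ---------------------------------------------------
  stage <- "simulate"
  res <- tryCatch({
    design <- do.call(expression_design, cfg$simulate$design)
    genome <- generate_genome(cfg$simulate$n_genes, cfg$simulate$n_chromosomes,
                              seed = seed)
    panel <- generate_model_panel(genome)
    sims <- lapply(panel, function(mdl)
      simulate_expression(genome, mdl, design, seed = seed,
                          reference = panel$DpFull))

    # --- stage: differential expression -----------------------------
    stage <- "dge"
    fits <- lapply(sims, function(s)
      fcros(s, alpha_low = cfg$dge$alpha_low, alpha_high = cfg$dge$alpha_high,
            standardization = cfg$dge$standardization))
    degs <- lapply(fits, call_degs)

    # --- stage: trisomy bookkeeping ---------------------------------
    stage <- "trisomy"
    summaries <- lapply(names(panel), function(nm) {
      cls <- classify_genes(genome, panel[[nm]],
                            expressed_genes(sims[[nm]]), degs[[nm]])
      if (any(cls$teg)) {
        cf <- compensation_fraction(cls)
      } else {
        # a model whose cis genes all fall below the detection threshold
        # has no defined compensation percentage
        cf <- list(n_teg = 0L, n_differential_teg = 0L,
                   pct_differential = NA_integer_,
                   pct_compensated = NA_integer_)
      }
      data.frame(model = nm, n_teg = cf$n_teg,
                 n_deg = nrow(degs[[nm]]),
                 n_differential_teg = cf$n_differential_teg,
                 pct_differential = cf$pct_differential,
                 pct_compensated = cf$pct_compensated)
    })
    summary_tab <- do.call(rbind, summaries)
    corr <- cross_model_fc_correlation(fits)
    overlap <- deg_overlap(lapply(degs, `[[`, "gene_id"))

    # --- stage: gene sets -------------------------------------------
    stage <- "genesets"
    sets <- if (!is.null(cfg$genesets$gmt)) read_gmt(cfg$genesets$gmt)
    else with_seed(seed + 1L, {
      nm <- sprintf("random set %02d", seq_len(cfg$genesets$n_random_sets))
      s <- lapply(seq_along(nm), function(i)
        sample(genome$gene_id, cfg$genesets$set_size))
      names(s) <- nm
      s[["GO synaptic signaling (planted cis)"]] <-
        utils::head(cis_genes(genome, panel$DpProx), 30)
      s
    })
    gres <- lapply(sims, function(s) {
      fc <- pairwise_fold_changes(s$values, s$groups)
      gage_collection(fc, sets, q_cutoff = cfg$genesets$q_cutoff)
    })
    meta <- assign_meta_pathways(gres)

    # --- stage: network ---------------------------------------------
    stage <- "network"
    ppi <- simulate_ppi(cfg$network$n_nodes, seed = seed + 2L,
                        n_seed_clique = cfg$network$n_seed_clique)
    edges <- if (!is.null(cfg$network$edges))
      load_edges(cfg$network$edges, cfg$network$min_confidence)
    else load_edges(ppi$edges, min(cfg$network$min_confidence,
                                   min(ppi$edges$confidence)))
    net_seeds <- if (!is.null(cfg$network$seeds_file))
      readLines(cfg$network$seeds_file) else ppi$seeds
    net <- build_minppinet(edges, net_seeds)
    hubs <- betweenness_hubs(net, top_k = 10)
    null <- degree_preserving_null(net, metric = cfg$network$null_metric,
                                   n_replicates = cfg$network$null_replicates,
                                   seed = seed + 3L)

    # --- stage: phenotypes ------------------------------------------
    stage <- "quant"
    phen <- simulate_phenotypes(seed = seed + 4L, group_effect = 8)
    beh <- behaviour_stats(phen$behaviour$measure, phen$behaviour$genotype)
    mri <- mri_compare(phen$morphometry)

    list(summary = summary_tab, correlation = corr, overlap = overlap,
         meta = meta, hubs = hubs, null = null, behaviour = beh, mri = mri,
         genome = genome, panel = panel, fits = fits, degs = degs, net = net)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  # --- outputs and manifest -----------------------------------------
  out <- cfg$outdir
  utils::write.table(res$summary, file.path(out, "model_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(round(res$correlation$percent, 2),
                     file.path(out, "fc_correlation_percent.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(res$meta$net, file.path(out, "meta_pathway_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(res$hubs, file.path(out, "hub_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(metric = res$null$metric, observed = res$null$observed,
         null_mean = res$null$null_mean, null_sd = res$null$null_sd,
         empirical_p = res$null$empirical_p,
         n_replicates = res$null$n_replicates),
    file.path(out, "null_model.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$overlap$partition,
                       file.path(out, "deg_overlap.json"), auto_unbox = TRUE)

  files <- list.files(out, full.names = TRUE)
  manifest <- list(
    parameters = unclass(cfg),
    seeds = list(root = seed, genesets = seed + 1L, network = seed + 2L,
                 null = seed + 3L, phenotypes = seed + 4L),
    checksums = as.list(tools::md5sum(files))
  )
  names(manifest$checksums) <- basename(files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  class(res) <- c("run_result", "list")
  invisible(res)
}

#' @export
print.run_result <- function(x, ...) {
  cat("Pipeline run:", nrow(x$summary), "models\n")
  print(x$summary, row.names = FALSE)
  print(x$null)
  invisible(x)
}
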