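#' Read gene sets from a GMT file
#'
#' @param path path to a tab-separated GMT file (set name, description,
#'   then member ids).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, "", 1))
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), ""), path)
}

#' Directional gene-set test on pairwise fold changes (GAGE-style)
#'
#' For each test/control sample pair, compares the log2 fold changes of the
#' set members against all other measured genes with an unequal-variance
#' two-sample t test, yielding one-sided p-values for up- and
#' down-regulation; the k per-pair p-values are combined by Stouffer's
#' method. Significance and q-values are assigned across a collection by
#' [gage_collection()].
#'
#' @param fc pairwise log2 fold-change matrix from
#'   [pairwise_fold_changes()] (rownames = gene ids).
#' @param members character vector of set member ids.
#' @return List: `size_measured`, `mean_stat` (mean per-pair t), `p_up`,
#'   `p_down`, `too_small` (fewer than 2 measured members).
#' @export
gage_test <- function(fc, members) {
  idx <- rownames(fc) %in% members
  n_in <- sum(idx)
  if (n_in < 2)
    return(list(size_measured = n_in, mean_stat = NA_real_,
                p_up = NA_real_, p_down = NA_real_, too_small = TRUE))
  k <- ncol(fc)
  t_stats <- numeric(k); p_up <- numeric(k)
  if (all(idx)) {
    # set equals the universe: no background to compare against
    t_stats[] <- 0; p_up[] <- 0.5
  } else {
    for (j in seq_len(k)) {
      a <- fc[idx, j]; b <- fc[!idx, j]
      tt <- tryCatch(stats::t.test(a, b, alternative = "greater"),
                     error = function(e) NULL)
      if (is.null(tt)) { t_stats[j] <- 0; p_up[j] <- 0.5 }
      else { t_stats[j] <- unname(tt$statistic); p_up[j] <- tt$p.value }
    }
  }
  clamp <- function(p) pmin(1 - 1e-15, pmax(1e-15, p))
  # Stouffer denominator: columns sharing a control or test sample are
  # correlated (approx. corr = (same control + same test) / 2), so the
  # variance of the summed z-scores exceeds k. When the pair design is
  # known (attached by pairwise_fold_changes()) the exact double sum of
  # correlations is used; plain matrices are treated as independent.
  pd <- attr(fc, "pair_design")
  denom <- if (is.null(pd)) k else {
    sum((outer(pd$control, pd$control, "==") +
           outer(pd$test, pd$test, "==")) / 2)
  }
  stouffer <- function(p) {
    z <- stats::qnorm(1 - clamp(p))
    1 - stats::pnorm(sum(z) / sqrt(denom))
  }
  list(size_measured = n_in, mean_stat = mean(t_stats),
       p_up = stouffer(p_up), p_down = stouffer(1 - p_up),
       too_small = FALSE)
}

#' Test a gene-set collection and assign directions by FDR
#'
#' Runs [gage_test()] on every set, converts the smaller of the combined
#' one-sided p-values to a two-sided p, applies Benjamini-Hochberg across
#' all testable sets, and calls a direction for sets with `q < q_cutoff`.
#'
#' @param fc pairwise log2 fold-change matrix.
#' @param sets named list of member id vectors.
#' @param q_cutoff FDR cutoff for calling a direction (default 0.1).
#' @return `data.frame` of class `geneset_result`: `set`, `size_measured`,
#'   `mean_stat`, `p_up`, `p_down`, `p` (two-sided), `q`, `direction`
#'   (`up`/`down`/`none`), `too_small`.
#' @export
gage_collection <- function(fc, sets, q_cutoff = 0.1) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("`sets` must be uniquely named", call. = FALSE)
  res <- lapply(sets, function(s) gage_test(fc, s))
  out <- data.frame(
    set = names(sets),
    size_measured = vapply(res, `[[`, 0L, "size_measured"),
    mean_stat = vapply(res, `[[`, 0, "mean_stat"),
    p_up = vapply(res, `[[`, 0, "p_up"),
    p_down = vapply(res, `[[`, 0, "p_down"),
    too_small = vapply(res, `[[`, TRUE, "too_small"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$p <- pmin(1, 2 * pmin(out$p_up, out$p_down))
  out$q <- NA_real_
  testable <- !out$too_small
  out$q[testable] <- stats::p.adjust(out$p[testable], "BH")
  out$direction <- "none"
  sig <- testable & !is.na(out$q) & out$q < q_cutoff
  out$direction[sig] <- ifelse(out$p_up[sig] <= out$p_down[sig], "up", "down")
  attr(out, "q_cutoff") <- q_cutoff
  class(out) <- c("geneset_result", "data.frame")
  out
}

#' Default meta-pathway keyword map
#'
#' Ten broad functional groups into which significant pathways are
#' aggregated, each defined by a case-insensitive keyword rule applied to
#' the pathway name. A pathway is assigned to the first matching group in
#' map order. The grouping mirrors the meta-pathway categories customarily
#' used for trisomy hippocampus panels (synaptic, transcription and
#' epigenomics, enzymes, ribosome, mitochondria, cell structure and
#' organelles, phospho-kinases, interferon, myelin/SNARE, stemness); the
#' keyword rules are a best-effort reconstruction and fully editable.
#'
#' @return Named character vector of regular expressions, in precedence
#'   order.
#' @export
meta_pathway_map <- function() {
  c(
    "Myelin & SNARE"    = "myelin|snare|vesicle fusion",
    "Ribosome related"  = "ribosom|translation|rrna processing",
    "Mitochondria related" = "mitochond|oxidative phosphorylation|respirat|electron transport",
    "Interferon"        = "interferon|jak.stat|antiviral",
    "Synaptic related"  = "synap|neurotransmitter|dendrit|axon guidance|glutamat|gaba|potentiation",
    "Transcription & epigenomics regulation" =
      "transcription|chromatin|histone|epigen|methylation",
    "Phospho-kinase related" = "kinase|phosphoryl|phosphatase",
    "Cell structure & organelle related" =
      "cytoskelet|organelle|golgi|endoplasmic reticulum|lysosom|peroxisom|adhesion|membrane",
    "Stemness & differentiation" = "stem cell|differentiation|neurogenesis|development",
    "Enzymes activity"  = "ase activity|catalytic|metabolic process|biosynthe"
  )
}

#' Aggregate significant pathways into signed meta-pathway counts
#'
#' @param results named list of [gage_collection()] results, one per model
#'   (or a single result).
#' @param map named vector of keyword rules, see [meta_pathway_map()].
#' @return List of class `meta_pathway_matrix`: `up` and `down` (integer
#'   matrices, groups x models), `net` (`up - down`), `unmapped` (named
#'   list of significant pathway names matching no rule), `assignment`
#'   (pathway name to group, for significant pathways).
#' @export
assign_meta_pathways <- function(results, map = meta_pathway_map()) {
  if (inherits(results, "geneset_result")) results <- list(model = results)
  groups <- names(map)
  models <- names(results)
  up <- down <- matrix(0L, length(groups), length(models),
                       dimnames = list(groups, models))
  unmapped <- list()
  assignment <- list()
  for (mdl in models) {
    res <- results[[mdl]]
    sig <- res[res$direction != "none", , drop = FALSE]
    if (!nrow(sig)) { unmapped[[mdl]] <- character(0); next }
    grp <- vapply(sig$set, function(nm) {
      hit <- which(vapply(map, function(rx) grepl(rx, nm, ignore.case = TRUE),
                          TRUE))
      if (length(hit)) groups[hit[1]] else NA_character_
    }, "")
    unmapped[[mdl]] <- sig$set[is.na(grp)]
    assignment[[mdl]] <- stats::setNames(grp[!is.na(grp)], sig$set[!is.na(grp)])
    for (i in which(!is.na(grp))) {
      if (sig$direction[i] == "up") up[grp[i], mdl] <- up[grp[i], mdl] + 1L
      else down[grp[i], mdl] <- down[grp[i], mdl] + 1L
    }
  }
  structure(list(up = up, down = down, net = up - down,
                 unmapped = unmapped, assignment = assignment),
            class = "meta_pathway_matrix")
}

#' @export
print.meta_pathway_matrix <- function(x, ...) {
  cat("Meta-pathway matrix (net = up - down significant pathways):\n")
  print(x$net)
  n_un <- sum(lengths(x$unmapped))
  if (n_un) cat(n_un, "significant pathway(s) matched no group\n")
  invisible(x)
}

# Core members of a significant set in one model: measured members whose
# mean log2FC has the set's direction and magnitude above the set median.
core_members <- function(fit, members, direction) {
  idx <- match(intersect(members, fit$genes), fit$genes)
  lfc <- fit$log2fc[idx]
  med <- stats::median(abs(lfc))
  sgn <- if (direction == "up") lfc > 0 else lfc < 0
  fit$genes[idx][sgn & abs(lfc) > med]
}

#' Inter-model meta-pathway connectivity
#'
#' For each meta-pathway and each pair of models, counts (and identifies)
#' the genes that are core members of significant pathways of that group in
#' both models. "Core member" = measured set member whose per-gene median
#' fold change agrees with the set's direction and exceeds the set's median
#' magnitude.
#'
#' @param fits named list of [fcros()] fits per model.
#' @param results named list of [gage_collection()] results per model.
#' @param sets the gene-set collection (named list of id vectors).
#' @param map meta-pathway map, see [meta_pathway_map()].
#' @return List of class `meta_connectivity`: for each group, a list of
#'   model-pair entries `list(models, n_shared, genes)`.
#' @export
intermodel_connectivity <- function(fits, results, sets,
                                    map = meta_pathway_map()) {
  if (length(results) < 2) stop("need >= 2 models", call. = FALSE)
  stopifnot(identical(sort(names(fits)), sort(names(results))))
  meta <- assign_meta_pathways(results, map)
  models <- names(results)
  # per model and group: union of core members of significant sets
  core <- lapply(models, function(mdl) {
    asg <- meta$assignment[[mdl]]
    res <- results[[mdl]]
    out <- lapply(rownames(meta$up), function(grp) {
      nms <- names(asg)[asg == grp]
      unique(unlist(lapply(nms, function(nm)
        core_members(fits[[mdl]], sets[[nm]],
                     res$direction[res$set == nm]))))
    })
    stats::setNames(out, rownames(meta$up))
  })
  names(core) <- models
  pairs <- utils::combn(models, 2, simplify = FALSE)
  out <- lapply(rownames(meta$up), function(grp) {
    lapply(pairs, function(pr) {
      shared <- intersect(core[[pr[1]]][[grp]], core[[pr[2]]][[grp]])
      list(models = pr, n_shared = length(shared), genes = sort(shared))
    })
  })
  structure(stats::setNames(out, rownames(meta$up)),
            class = "meta_connectivity")
}
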