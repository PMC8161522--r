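#' Classify genes of one trisomy model
#'
#' Flags every annotated gene as expressed (EG), differentially expressed
#' (DEG), inside the model's duplicated region, trisomic expressed (TEG =
#' expressed AND in region) and differential TEG (TEG AND DEG). Following
#' the usual bookkeeping of segmental-duplication panels, "TEG" denotes any
#' expressed cis gene; the subset also called differential carries the
#' `differential_teg` flag.
#'
#' @param genome annotation table.
#' @param model a [trisomy_model()].
#' @param expressed character vector of expressed gene ids.
#' @param degs DEG table from [call_degs()] (or any data frame with a
#'   `gene_id` column), or a character vector of gene ids.
#' @return `data.frame` of class `gene_classification` with one row per
#'   annotated gene and logical columns `expressed`, `deg`,
#'   `in_trisomic_region`, `teg`, `differential_teg`.
#' @export
classify_genes <- function(genome, model, expressed, degs) {
  deg_ids <- if (is.data.frame(degs)) degs$gene_id else as.character(degs)
  missing <- setdiff(deg_ids, genome$gene_id)
  if (length(missing))
    stop("DEG ids absent from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "", call. = FALSE)
  in_region <- genome$gene_id %in% cis_genes(genome, model)
  out <- data.frame(
    gene_id = genome$gene_id,
    expressed = genome$gene_id %in% expressed,
    deg = genome$gene_id %in% deg_ids,
    in_trisomic_region = in_region,
    stringsAsFactors = FALSE
  )
  out$teg <- out$expressed & out$in_trisomic_region
  out$differential_teg <- out$teg & out$deg
  attr(out, "model") <- model$name
  class(out) <- c("gene_classification", "data.frame")
  out
}

#' Dosage-compensation summary of a model
#'
#' From TEG counts computes the percentage of trisomic expressed genes that
#' are differential and its complement, the percentage showing dosage
#' compensation (no detected overexpression despite the extra copy).
#' Percentages are integer, halves rounded away from zero.
#'
#' @param x a `gene_classification` from [classify_genes()], or the TEG
#'   count `n_teg` when `n_differential_teg` is also given.
#' @param n_differential_teg differential TEG count (counts interface).
#' @return List of class `compensation_summary`: `n_teg`,
#'   `n_differential_teg`, `pct_differential`, `pct_compensated`.
#' @examples
#' compensation_fraction(155, 66)  # 43% differential, 57% compensated
#' @export
compensation_fraction <- function(x, n_differential_teg = NULL) {
  if (inherits(x, "gene_classification")) {
    n_teg <- sum(x$teg)
    n_diff <- sum(x$differential_teg)
  } else {
    n_teg <- x
    n_diff <- n_differential_teg
    if (is.null(n_diff)) stop("supply `n_differential_teg`", call. = FALSE)
  }
  if (n_teg < 1)
    stop("compensation undefined: model has no trisomic expressed genes",
         call. = FALSE)
  if (n_diff > n_teg)
    stop("differential TEGs exceed TEGs", call. = FALSE)
  pct <- as.integer(round_half_up(100 * n_diff / n_teg))
  structure(list(n_teg = n_teg, n_differential_teg = n_diff,
                 pct_differential = pct, pct_compensated = 100L - pct),
            class = "compensation_summary")
}

#' @export
print.compensation_summary <- function(x, ...) {
  cat(sprintf("TEGs: %d, differential: %d (%d%%), compensated: %d%%\n",
              x$n_teg, x$n_differential_teg, x$pct_differential,
              x$pct_compensated))
  invisible(x)
}

#' Cross-model fold-change correlation matrix
#'
#' Pearson (default) correlation of per-gene log2 fold changes between every
#' pair of models, over a common gene universe: either the union of all
#' models' DEGs or the genes of a duplicated (cis) region. Reported both as
#' `r` and as a percentage (`100 r`), the convention used when stating,
#' e.g., that two models' misregulation is "33% correlated".
#'
#' @param fits named list of [fcros()] fits (same gene universe).
#' @param universe `"union_degs"` (union of the models' called DEGs) or a
#'   character vector of gene ids (e.g. a cis-region universe).
#' @param method `"pearson"` or `"spearman"`.
#' @return List of class `model_comparison`: `r` (correlation matrix),
#'   `percent` (`100 r`), `universe` (gene ids used).
#' @export
cross_model_fc_correlation <- function(fits, universe = "union_degs",
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(fits) < 2) stop("need >= 2 models", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, TRUE, "fcros")))
  if (identical(universe, "union_degs")) {
    universe <- unique(unlist(lapply(fits, function(f) call_degs(f)$gene_id)))
  }
  universe <- Reduce(intersect, c(list(universe),
                                  lapply(fits, function(f) f$genes)))
  if (length(universe) < 3)
    stop("gene universe has fewer than 3 measured genes", call. = FALSE)
  fc <- sapply(fits, function(f) f$log2fc[match(universe, f$genes)])
  r <- stats::cor(fc, method = method)
  structure(list(r = r, percent = 100 * r, universe = universe,
                 method = method), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Fold-change correlation (%s) over %d genes, as percent:\n",
              x$method, length(x$universe)))
  print(round(x$percent, 1))
  invisible(x)
}

#' DEG overlap (Venn partition) across models
#'
#' Counts every region of the Venn partition of the given DEG sets: for each
#' non-empty subset S of models, the number of genes called in exactly the
#' models of S.
#'
#' @param sets named list of character vectors (DEG ids per model).
#' @return List of class `deg_overlap` with `partition` (named counts,
#'   names like `"A&B"`), `pairwise` (matrix of pairwise intersection
#'   sizes), `union_size`.
#' @export
deg_overlap <- function(sets) {
  if (length(sets) < 2) stop("need >= 2 sets", call. = FALSE)
  if (is.null(names(sets))) names(sets) <- paste0("S", seq_along(sets))
  sets <- lapply(sets, unique)
  all_genes <- unique(unlist(sets))
  member <- sapply(sets, function(s) all_genes %in% s)
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1,
                                                dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(row)
    paste(names(sets)[row], collapse = "&"))
  partition <- table(pattern)
  n <- length(sets)
  pw <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n))
    pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  structure(list(partition = c(partition), pairwise = pw,
                 union_size = length(all_genes)), class = "deg_overlap")
}

#' @export
print.deg_overlap <- function(x, ...) {
  cat("DEG overlap over", x$union_size, "genes; Venn partition counts:\n")
  print(x$partition)
  invisible(x)
}

#' Low-dimensional sample embedding on differential genes
#'
#' Projects samples onto 2-3 components using the expression of a gene
#' subset (typically the DEGs), either by principal components or by a
#' spectral neighbour embedding (Laplacian eigenmaps on a k-nearest-
#' neighbour sample graph). Reports the mean silhouette width between
#' genotype groups as a separation score.
#'
#' @param values log2 matrix (genes x samples) or `sim_expression`.
#' @param groups group labels per sample (taken from a `sim_expression`).
#' @param genes optional gene subset (e.g. DEG ids).
#' @param method `"pca"` or `"spectral"`.
#' @param n_components 2 or 3.
#' @param k neighbours for the spectral method.
#' @param seed seed (the spectral eigen-solver sign convention is fixed, so
#'   both methods are deterministic; kept for interface symmetry).
#' @return List of class `sample_embedding`: `coords` (samples x
#'   components), `silhouette` (mean silhouette width over groups, NA for a
#'   single group), `method`.
#' @export
sample_embedding <- function(values, groups = NULL, genes = NULL,
                             method = c("pca", "spectral"),
                             n_components = 2, k = 5, seed = 1L) {
  method <- match.arg(method)
  if (inherits(values, "sim_expression")) {
    groups <- values$groups
    values <- values$values
  }
  if (!is.null(genes)) values <- values[intersect(genes, rownames(values)), ,
                                        drop = FALSE]
  n <- ncol(values)
  if (n < 4) stop("need >= 4 samples", call. = FALSE)
  if (n_components >= n) stop("fewer samples than components", call. = FALSE)
  x <- t(values)
  coords <- if (method == "pca") {
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    p$x[, seq_len(n_components), drop = FALSE]
  } else {
    with_seed(seed, {
      d <- as.matrix(stats::dist(x))
      k <- min(k, n - 1)
      w <- matrix(0, n, n)
      for (i in seq_len(n)) {
        nb <- order(d[i, ])[2:(k + 1)]
        w[i, nb] <- exp(-d[i, nb]^2 / stats::median(d[d > 0])^2)
      }
      w <- pmax(w, t(w))
      dg <- rowSums(w)
      l <- diag(n) - diag(1 / sqrt(pmax(dg, 1e-12))) %*% w %*%
        diag(1 / sqrt(pmax(dg, 1e-12)))
      ev <- eigen(l, symmetric = TRUE)
      sel <- seq(n - 1, by = -1, length.out = n_components)
      co <- ev$vectors[, sel, drop = FALSE]
      # fix sign convention for determinism
      for (jj in seq_len(ncol(co)))
        if (co[which.max(abs(co[, jj])), jj] < 0) co[, jj] <- -co[, jj]
      rownames(co) <- rownames(x)
      co
    })
  }
  colnames(coords) <- paste0("C", seq_len(ncol(coords)))
  sil <- NA_real_
  if (!is.null(groups) && length(unique(groups)) > 1) {
    sil <- mean_silhouette(coords, as.integer(factor(groups)))
  }
  structure(list(coords = coords, silhouette = sil, method = method),
            class = "sample_embedding")
}

# mean silhouette width from embedded coordinates and integer labels
mean_silhouette <- function(coords, labels) {
  if (requireNamespace("cluster", quietly = TRUE)) {
    return(mean(cluster::silhouette(labels, stats::dist(coords))[, 3]))
  }
  d <- as.matrix(stats::dist(coords))
  s <- vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), 0))
    if (sum(own) == 1) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}
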