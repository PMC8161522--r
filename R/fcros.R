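#' Pairwise log2 fold changes between all test/control sample pairs
#'
#' For every (control i, test j) pair the per-gene log2 fold change is the
#' difference of log2 intensities, `test_j - control_i`. Columns are in
#' control-major order: all tests against control 1, then control 2, and so
#' on, giving `k = n_control * n_trisomic` columns.
#'
#' @param values log2 expression matrix, genes x samples, rownames = gene ids.
#' @param groups factor/character of length `ncol(values)` with levels
#'   `control` and `trisomic` (or supply `control`/`test` label vectors via
#'   `control_level`).
#' @param control_level label in `groups` identifying the control samples;
#'   all other samples are treated as test.
#' @return Numeric matrix genes x k of log2 fold changes; column names
#'   `"<control>.<test>"`.
#' @export
pairwise_fold_changes <- function(values, groups, control_level = "control") {
  if (is.null(rownames(values)))
    stop("`values` must have gene ids as rownames", call. = FALSE)
  if (anyNA(values)) stop("`values` contains missing values", call. = FALSE)
  if (length(groups) != ncol(values))
    stop("`groups` length must equal ncol(values)", call. = FALSE)
  groups <- as.character(groups)
  ctrl <- which(groups == control_level)
  test <- which(groups != control_level)
  if (length(ctrl) < 2)
    stop(sprintf("group '%s' has fewer than 2 samples", control_level), call. = FALSE)
  if (length(test) < 2)
    stop(sprintf("group '%s' has fewer than 2 samples",
                 setdiff(groups, control_level)[1]), call. = FALSE)
  fc <- matrix(0, nrow = nrow(values), ncol = length(ctrl) * length(test),
               dimnames = list(rownames(values), NULL))
  cn <- character(ncol(fc))
  pd <- data.frame(control = integer(ncol(fc)), test = integer(ncol(fc)))
  col <- 0L
  for (i in ctrl) for (j in test) {
    col <- col + 1L
    fc[, col] <- values[, j] - values[, i]
    cn[col] <- paste0(colnames(values)[i], ".", colnames(values)[j])
    pd$control[col] <- i; pd$test[col] <- j
  }
  colnames(fc) <- cn
  # which samples each column reuses; downstream combinations across pairs
  # need this to account for the induced correlation
  attr(fc, "pair_design") <- pd
  fc
}

#' Fold-change rank-ordering differential expression (FCROS-type statistic)
#'
#' Fits the rank-based differential expression statistic used for trisomy
#' model panels. For each of the `k = n_control * n_trisomic` test/control
#' sample pairs, per-gene log2 fold changes are ranked in increasing order
#' (ties averaged) and normalized by the gene count `m` to `(0, 1]`. The
#' per-gene mean normalized rank `rbar` over the `k` pairs is standardized
#' to a z-score and mapped through the standard normal CDF to an f-value in
#' `(0, 1)`: genes with f below `alpha_low` are called down-regulated, above
#' `alpha_high` up-regulated. The reported effect size is the per-gene
#' median of the pairwise log2 fold changes.
#'
#' Standardization `"empirical"` uses the mean and SD of the observed
#' `rbar` values (robust to an asymmetric burden of differential
#' expression); `"theoretical"` uses the null moments of a mean of `k`
#' independent uniform ranks, mean 0.5 and SD `sqrt(1/(12 k))`.
#'
#' @param values log2 expression matrix (genes x samples) or a
#'   `sim_expression` object from [simulate_expression()].
#' @param groups sample group labels (ignored for `sim_expression` input).
#' @param alpha_low,alpha_high f-value window bounds outside which genes are
#'   called differential (defaults 0.025 and 0.975, a 5% window).
#' @param standardization `"empirical"` or `"theoretical"`.
#' @param control_level label of the control group in `groups`.
#' @return An object of class `fcros`: a list with `k`, `m`, `rbar`,
#'   `f_value`, `log2fc` (median pairwise log2 FC), `is_deg`, `direction`,
#'   and the call parameters. Methods: `print`, `summary`, `coef`
#'   (log2 fold changes), `plot` (rank/fold-change diagnostic).
#' @examples
#' genome <- generate_genome(200, 2, seed = 1)
#' panel <- generate_model_panel(genome)
#' sim <- simulate_expression(genome, panel$DpProx,
#'                            expression_design(n_trans_effects = 10), seed = 3)
#' fit <- fcros(sim)
#' summary(fit)
#' @export
fcros <- function(values, groups = NULL, alpha_low = 0.025, alpha_high = 0.975,
                  standardization = c("empirical", "theoretical"),
                  control_level = "control") {
  standardization <- match.arg(standardization)
  if (inherits(values, "sim_expression")) {
    groups <- values$groups
    values <- values$values
  }
  fc <- pairwise_fold_changes(values, groups, control_level)
  fcros_stat(fc, alpha_low = alpha_low, alpha_high = alpha_high,
             standardization = standardization)
}

#' Rank statistic on a pre-computed pairwise fold-change matrix
#'
#' The computational core of [fcros()], exposed for workflows that already
#' hold the genes x pairs log2 fold-change matrix.
#'
#' @param fc matrix genes x pairs of log2 fold changes, rownames = gene ids.
#' @inheritParams fcros
#' @return An `fcros` object (see [fcros()]).
#' @export
fcros_stat <- function(fc, alpha_low = 0.025, alpha_high = 0.975,
                       standardization = c("empirical", "theoretical")) {
  standardization <- match.arg(standardization)
  if (!(alpha_low > 0 && alpha_low < alpha_high && alpha_high < 1))
    stop("need 0 < alpha_low < alpha_high < 1", call. = FALSE)
  m <- nrow(fc)
  if (m < 10)
    warning("rank statistic is unreliable below 10 genes", call. = FALSE)
  k <- ncol(fc)
  # per pair: ascending fractional ranks normalized to (0, 1]
  rnorm_ranks <- apply(fc, 2, function(col) rank(col, ties.method = "average") / m)
  rbar <- rowMeans(rnorm_ranks)

  degenerate <- FALSE
  if (standardization == "empirical") {
    s <- stats::sd(rbar)
    if (!is.finite(s) || s < .Machine$double.eps^0.5) {
      warning("degenerate input: all genes tied in every pair; f-values set to 0.5")
      degenerate <- TRUE
      f <- rep(0.5, m)
    } else f <- stats::pnorm((rbar - mean(rbar)) / s)
  } else {
    f <- stats::pnorm((rbar - 0.5) / sqrt(1 / (12 * k)))
  }
  log2fc <- apply(fc, 1, stats::median)
  is_deg <- !degenerate & (f < alpha_low | f > alpha_high)
  direction <- ifelse(!is_deg, "none", ifelse(f > alpha_high, "up", "down"))

  structure(list(
    k = k, m = m, rbar = rbar, f_value = f, log2fc = log2fc,
    is_deg = is_deg, direction = direction,
    genes = rownames(fc),
    alpha_low = alpha_low, alpha_high = alpha_high,
    standardization = standardization, degenerate = degenerate
  ), class = "fcros")
}

#' @export
print.fcros <- function(x, ...) {
  cat(sprintf(
    "Fold-change rank-ordering DE fit: %d genes, %d sample pairs (%s standardization)\n",
    x$m, x$k, x$standardization))
  cat(sprintf("f-value window (%g, %g): %d genes called (%d up, %d down)\n",
              x$alpha_low, x$alpha_high, sum(x$is_deg),
              sum(x$direction == "up"), sum(x$direction == "down")))
  invisible(x)
}

#' @export
summary.fcros <- function(object, ...) {
  tab <- data.frame(gene_id = object$genes, rbar = object$rbar,
                    f_value = object$f_value, log2fc = object$log2fc,
                    direction = object$direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(fit = object, table = tab)
  class(out) <- "summary.fcros"
  out
}

#' @export
print.summary.fcros <- function(x, ...) {
  print(x$fit)
  deg <- x$table[x$table$direction != "none", ]
  deg <- deg[order(-abs(deg$log2fc), deg$gene_id), ]
  cat("Top differential genes:\n")
  print(utils::head(deg, 10), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.fcros <- function(object, ...) {
  stats::setNames(object$log2fc, object$genes)
}

#' @export
plot.fcros <- function(x, ...) {
  graphics::plot(x$log2fc, -log10(pmin(x$f_value, 1 - x$f_value) * 2),
                 pch = 20, cex = 0.4,
                 col = ifelse(x$is_deg, "firebrick", "grey50"),
                 xlab = "median pairwise log2 fold change",
                 ylab = "-log10 two-sided f-derived p", ...)
  invisible(x)
}

#' Extract the differential-gene table from an `fcros` fit
#'
#' @param fit an [fcros()] object.
#' @param adjust apply a Benjamini-Hochberg adjustment to the two-sided
#'   f-derived p-values (`2 * min(f, 1 - f)`) and require adjusted p below
#'   `fdr` in addition to the f-value window. Off by default: the window on
#'   raw f-values is the primary calling rule.
#' @param fdr FDR level used when `adjust = TRUE`.
#' @return `data.frame` with columns `gene_id`, `rbar`, `f_value`, `log2fc`,
#'   `direction`, sorted by decreasing `|log2fc|` with ties broken by gene
#'   id; empty when nothing is called.
#' @export
call_degs <- function(fit, adjust = FALSE, fdr = 0.05) {
  stopifnot(inherits(fit, "fcros"))
  keep <- fit$is_deg
  if (adjust) {
    p2 <- pmin(1, 2 * pmin(fit$f_value, 1 - fit$f_value))
    keep <- keep & stats::p.adjust(p2, "BH") < fdr
  }
  out <- data.frame(gene_id = fit$genes, rbar = fit$rbar,
                    f_value = fit$f_value, log2fc = fit$log2fc,
                    direction = fit$direction,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(-abs(out$log2fc), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expressed-gene detection
#'
#' A gene is considered expressed when its mean log2 intensity exceeds a
#' detection threshold; by default the matrix-wide 10th percentile of gene
#' means, a simple detection proxy for single-channel intensity arrays.
#'
#' @param values log2 matrix or `sim_expression`.
#' @param threshold absolute log2 threshold; when `NULL` uses
#'   `quantile(gene means, quantile)`.
#' @param quantile quantile defining the adaptive threshold.
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(values, threshold = NULL, quantile = 0.1) {
  if (inherits(values, "sim_expression")) values <- values$values
  mu <- rowMeans(values)
  if (is.null(threshold)) threshold <- stats::quantile(mu, quantile)
  names(mu)[mu > threshold]
}
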