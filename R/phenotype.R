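#' Comparative-Ct relative quantities
#'
#' Transforms qPCR cycle thresholds to relative quantities with
#' `quantity = E^(Ct_min(gene) - Ct(sample, gene))`, where `E` is the
#' amplification efficiency (2 for perfect doubling) and `Ct_min` the
#' smallest Ct observed for that gene, so all values are expressed relative
#' to the most expressed sample and the per-gene maximum quantity is 1.
#'
#' @param qpcr `data.frame` with columns `sample`, `gene`, `ct` (additional
#'   metadata columns are carried through).
#' @param efficiency amplification factor `E` in `(1, 2]`.
#' @return Input with an added `quantity` column.
#' @export
comparative_ct <- function(qpcr, efficiency = 2) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(qpcr)))
  if (efficiency <= 1 || efficiency > 2)
    stop("`efficiency` must be in (1, 2]", call. = FALSE)
  if (anyNA(qpcr$ct)) stop("missing Ct values", call. = FALSE)
  if (any(qpcr$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  ct_min <- tapply(qpcr$ct, qpcr$gene, min)
  qpcr$quantity <- as.numeric(efficiency^(ct_min[qpcr$gene] - qpcr$ct))
  qpcr
}

#' geNorm reference-gene selection
#'
#' For every pair of candidate reference genes computes the pairwise
#' variation `V_jk = sd over samples of log2(q_j / q_k)`; each candidate's
#' stability `M_j` is the mean of its pairwise variations. The least stable
#' candidate (highest M) is dropped iteratively until `keep` remain or all
#' remaining M values fall below `m_threshold`. The per-sample
#' normalization factor is the geometric mean of the kept references.
#'
#' @param quantities matrix samples x candidate genes of relative
#'   quantities (from [comparative_ct()]), all strictly positive.
#' @param keep minimum number of references kept (default 2).
#' @param m_threshold stop dropping once all M values are below this.
#' @return List of class `genorm_result`: `m_values` (initial M per
#'   candidate), `selected`, `normalization_factor` (per sample),
#'   `dropped` (in drop order).
#' @export
genorm_select <- function(quantities, keep = 2, m_threshold = 0.5) {
  q <- as.matrix(quantities)
  if (ncol(q) < 3) stop("need >= 3 candidate references", call. = FALSE)
  if (nrow(q) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(q <= 0)) stop("zero or negative quantity: log undefined", call. = FALSE)
  m_of <- function(mat) {
    nc <- ncol(mat)
    vapply(seq_len(nc), function(j) {
      mean(vapply(setdiff(seq_len(nc), j), function(k)
        stats::sd(log2(mat[, j] / mat[, k])), 0))
    }, 0)
  }
  m0 <- stats::setNames(m_of(q), colnames(q))
  cur <- q
  dropped <- character(0)
  while (ncol(cur) > keep) {
    m <- m_of(cur)
    if (all(m < m_threshold)) break
    worst <- which.max(m)
    dropped <- c(dropped, colnames(cur)[worst])
    cur <- cur[, -worst, drop = FALSE]
  }
  nf <- apply(cur, 1, function(x) exp(mean(log(x))))
  structure(list(m_values = m0, selected = colnames(cur),
                 normalization_factor = nf, dropped = dropped),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stability M:\n"); print(round(x$m_values, 3))
  cat("selected references:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Fold induction relative to dark-housed baseline
#'
#' Divides each sample's normalized quantity by the mean normalized
#' quantity of the dark-housed samples of the same genotype, so the
#' dark-housed group of each genotype averages exactly 1. Group means and
#' standard errors per (genotype, condition) are reported.
#'
#' @param x `data.frame` with columns `sample`, `gene`, `genotype`,
#'   `condition` and `quantity` (normalized relative quantity).
#' @param baseline condition label of the dark-housed baseline.
#' @return List: `per_sample` (input with `fold_induction` column),
#'   `summary` (`gene`, `genotype`, `condition`, `mean`, `sem`, `n`).
#' @export
fold_induction <- function(x, baseline = "dark") {
  need <- c("sample", "gene", "genotype", "condition", "quantity")
  stopifnot(all(need %in% names(x)))
  x$fold_induction <- NA_real_
  for (gn in unique(x$gene)) for (gt in unique(x$genotype)) {
    sel <- x$gene == gn & x$genotype == gt
    base <- x$quantity[sel & x$condition == baseline]
    if (!length(base))
      stop(sprintf("no '%s' baseline samples for genotype %s", baseline, gt),
           call. = FALSE)
    x$fold_induction[sel] <- x$quantity[sel] / mean(base)
  }
  agg <- stats::aggregate(fold_induction ~ gene + genotype + condition,
                          data = x, FUN = function(v)
                            c(mean = mean(v),
                              sem = stats::sd(v) / sqrt(length(v)),
                              n = length(v)))
  s <- data.frame(agg[, 1:3], agg$fold_induction)
  names(s)[4:6] <- c("mean", "sem", "n")
  list(per_sample = x, summary = s)
}

#' Western-blot relative quantification
#'
#' Normalizes each sample's protein signal by its loading-control signal
#' and expresses the ratio relative to the mean ratio of the wild-type
#' group, whose mean is therefore 1 by construction. Invariant to rescaling
#' all signals by a constant.
#'
#' @param signal protein-of-interest signal per sample.
#' @param loading loading-control (e.g. beta-actin) signal per sample.
#' @param genotype group label per sample.
#' @param wt label of the reference (wild-type) group.
#' @return `data.frame`: `genotype`, `ratio`, `relative` (ratio / wt mean).
#' @export
wb_relative <- function(signal, loading, genotype, wt = "wt") {
  if (any(loading <= 0)) stop("loading-control signal must be > 0", call. = FALSE)
  if (!any(genotype == wt)) stop("empty wild-type group", call. = FALSE)
  ratio <- signal / loading
  data.frame(genotype = genotype, ratio = ratio,
             relative = ratio / mean(ratio[genotype == wt]))
}

#' MRI normalized-volume group comparison with FDR
#'
#' Normalizes each structure volume by the animal's whole-brain volume,
#' compares the two genotype groups per structure by Student's t-test, and
#' adjusts p-values across structures with Benjamini-Hochberg.
#'
#' @param morph `data.frame` with columns `animal`, `genotype`,
#'   `structure`, `volume`, `whole_brain`.
#' @param wt reference genotype label.
#' @param var_equal passed to [stats::t.test()] (classic Student's test
#'   uses `TRUE`).
#' @return `data.frame`: `structure`, `mean_wt`, `mean_other`, `t`, `p`,
#'   `q`, sorted by `p`.
#' @export
mri_compare <- function(morph, wt = "wt", var_equal = TRUE) {
  need <- c("animal", "genotype", "structure", "volume", "whole_brain")
  stopifnot(all(need %in% names(morph)))
  if (any(morph$volume > morph$whole_brain))
    stop("structure volume exceeds whole-brain volume", call. = FALSE)
  morph$norm <- morph$volume / morph$whole_brain
  out <- do.call(rbind, lapply(split(morph, morph$structure), function(d) {
    a <- d$norm[d$genotype == wt]; b <- d$norm[d$genotype != wt]
    if (length(a) < 2 || length(b) < 2)
      stop("need >= 2 animals per group", call. = FALSE)
    tt <- stats::t.test(b, a, var.equal = var_equal)
    data.frame(structure = d$structure[1], mean_wt = mean(a),
               mean_other = mean(b), t = unname(tt$statistic),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  out$q <- stats::p.adjust(out$p, "BH")
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Behavioural statistics decision tree
#'
#' Standard omnibus pipeline for behavioural measures: Shapiro-Wilk
#' normality per group and Brown-Forsythe homogeneity of variances gate
#' (both at `alpha`) the choice between one-way ANOVA and Kruskal-Wallis;
#' Fisher's LSD post-hoc comparisons run only when the omnibus test is
#' significant. Groups smaller than 3 skip the normality gate and take the
#' non-parametric path. With `chance` set, a single-group measure is
#' instead tested against the chance level with a two-sided one-sample
#' t-test (e.g. novel-object sniffing percentage vs 50).
#'
#' @param measure numeric response per animal.
#' @param group group label per animal (ignored for the chance-level test
#'   when only one group is present).
#' @param alpha gate and omnibus significance level.
#' @param chance optional chance level for a one-sample test.
#' @return List of class `behaviour_report`: `test` (name of the omnibus
#'   test used), `gates` (normality / variance-homogeneity p-values),
#'   `statistic`, `p`, `posthoc` (LSD table or `NULL`), `note`.
#' @export
behaviour_stats <- function(measure, group = NULL, alpha = 0.05,
                            chance = NULL) {
  if (!is.null(chance) && (is.null(group) || length(unique(group)) == 1)) {
    tt <- stats::t.test(measure, mu = chance)
    return(structure(list(test = "one-sample t vs chance",
                          gates = NULL, statistic = unname(tt$statistic),
                          p = tt$p.value, posthoc = NULL,
                          note = sprintf("chance level %g", chance)),
                     class = "behaviour_report"))
  }
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups", call. = FALSE)
  ns <- table(group)
  note <- NULL
  if (any(ns < 3)) {
    normal <- FALSE
    gates <- list(shapiro_p = NA_real_, bf_p = NA_real_)
    note <- "group n < 3: normality gate skipped, non-parametric path"
  } else {
    sh <- vapply(levels(group), function(g) {
      v <- measure[group == g]
      if (stats::sd(v) == 0) 0 else stats::shapiro.test(v)$p.value
    }, 0)
    bf <- brown_forsythe(measure, group)
    gates <- list(shapiro_p = sh, bf_p = bf)
    normal <- all(sh > alpha) && bf > alpha
  }
  if (normal) {
    fit <- stats::aov(measure ~ group)
    an <- summary(fit)[[1]]
    stat <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
    test <- "one-way ANOVA"
    posthoc <- if (p < alpha) fisher_lsd(measure, group) else NULL
  } else {
    kw <- stats::kruskal.test(measure, group)
    stat <- unname(kw$statistic); p <- kw$p.value
    test <- "Kruskal-Wallis"
    posthoc <- if (p < alpha)
      pairwise_wilcox_table(measure, group) else NULL
  }
  structure(list(test = test, gates = gates, statistic = stat, p = p,
                 posthoc = posthoc, note = note),
            class = "behaviour_report")
}

# Brown-Forsythe test: ANOVA on absolute deviations from group medians.
brown_forsythe <- function(measure, group) {
  med <- tapply(measure, group, stats::median)
  z <- abs(measure - med[group])
  summary(stats::aov(z ~ group))[[1]][["Pr(>F)"]][1]
}

# Fisher's LSD: pairwise t-tests with the pooled ANOVA error term and no
# multiplicity adjustment (run only behind a significant omnibus F).
fisher_lsd <- function(measure, group) {
  fit <- stats::aov(measure ~ group)
  mse <- summary(fit)[[1]][["Mean Sq"]][2]
  dfe <- fit$df.residual
  lv <- levels(group)
  means <- tapply(measure, group, mean)
  ns <- table(group)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    se <- sqrt(mse * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    t <- (means[pr[1]] - means[pr[2]]) / se
    data.frame(group1 = pr[1], group2 = pr[2],
               diff = unname(means[pr[1]] - means[pr[2]]),
               t = unname(t),
               p = unname(2 * stats::pt(-abs(t), dfe)),
               stringsAsFactors = FALSE)
  }))
}

pairwise_wilcox_table <- function(measure, group) {
  pairs <- utils::combn(levels(group), 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    w <- suppressWarnings(stats::wilcox.test(measure[group == pr[1]],
                                             measure[group == pr[2]]))
    data.frame(group1 = pr[1], group2 = pr[2],
               W = unname(w$statistic), p = w$p.value,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.behaviour_report <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, p = %.4g\n", x$test, x$statistic, x$p))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  if (!is.null(x$posthoc)) { cat("post-hoc:\n"); print(x$posthoc) }
  invisible(x)
}
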