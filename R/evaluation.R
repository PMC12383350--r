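#' Per-gene means and variances
#'
#' Gene-wise mean and unbiased (n-1 denominator) variance over cells, the
#' statistics compared between predicted and observed populations.
#'
#' @param ds `expression_dataset` (normalized_log layer).
#' @return list with named numeric vectors `means` and `variances`.
#' @export
gene_stats <- function(ds) {
  validate_dataset(ds)
  if (n_cells(ds) == 0L) stop("gene_stats on an empty dataset")
  list(means = colMeans(ds$matrix), variances = .col_vars(ds$matrix))
}

#' Squared-Pearson regression with Fisher-z confidence interval
#'
#' Pearson correlation `r` between a predicted and an observed per-gene
#' statistic vector, its square `R^2`, a 95% confidence interval obtained by
#' Fisher-z transform (`atanh(r) +/- 1.96/sqrt(d-3)`, mapped back through
#' `tanh`, clamped to [-1, 1] and squared), and the two-sided p-value for
#' `r = 0` (t-test with d-2 degrees of freedom).
#'
#' @param pred_stat,true_stat numeric vectors of equal length `d >= 3` with
#'   nonzero variance.
#' @return list with `r`, `r2`, `ci` (length-2), `p`, `n`.
#' @export
regression_r2 <- function(pred_stat, true_stat) {
  d <- length(pred_stat)
  if (length(true_stat) != d) stop("statistic vectors differ in length")
  if (d < 3) stop("need at least 3 genes")
  if (stats::sd(pred_stat) == 0 || stats::sd(true_stat) == 0)
    stop("constant statistic vector; correlation undefined")
  r <- stats::cor(pred_stat, true_stat)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  hw <- 1.96 / sqrt(d - 3)
  r_int <- pmin(pmax(tanh(c(z - hw, z + hw)), -1), 1)
  ci <- sort(r_int^2)
  tstat <- r * sqrt((d - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = d - 2)
  list(r = r, r2 = r^2, ci = ci, p = p, n = d)
}

#' Rank genes by a two-sample Wilcoxon rank-sum score
#'
#' For every gene, the tie-corrected standardized rank-sum (Mann-Whitney)
#' statistic between the two groups on log-normalized values; genes are
#' ranked by decreasing absolute score with deterministic tie-break by input
#' gene order. The top `n_top` gene ids are returned.
#'
#' @param group_a,group_b `expression_dataset`s sharing the gene axis, each
#'   with at least 2 cells.
#' @param n_top list length (default 100).
#' @return character vector of gene ids, most differential first. The
#'   standardized scores are attached as attribute `"score"`.
#' @export
top_degs <- function(group_a, group_b, n_top = 100L) {
  if (!identical(colnames(group_a$matrix), colnames(group_b$matrix)))
    stop("gene axes differ between the two groups")
  na <- n_cells(group_a); nb <- n_cells(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 cells")
  z <- wilcox_scores(group_a$matrix, group_b$matrix)
  ord <- order(abs(z), decreasing = TRUE) # ties: earlier gene order wins
  top <- utils::head(ord, min(n_top, length(z)))
  out <- colnames(group_a$matrix)[top]
  attr(out, "score") <- z[top]
  out
}

#' Standardized rank-sum scores per gene
#'
#' Vector of tie-corrected normal-approximation z-scores of the Mann-Whitney
#' U statistic of `a`'s cells against `b`'s, one per gene (column). Exposed
#' for independent verification of the ranking.
#'
#' @param a,b numeric matrices (cells x genes) with identical gene columns.
#' @return numeric vector of length `ncol(a)`.
#' @export
wilcox_scores <- function(a, b) {
  na <- nrow(a); nb <- nrow(b); n <- na + nb
  x <- rbind(a, b)
  vapply(seq_len(ncol(x)), function(j) {
    rk <- rank(x[, j])
    U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
    ties <- table(x[, j])
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- na * nb / 12 * ((n + 1) - tie_term)
    if (v <= 0) return(0)
    (U - na * nb / 2) / sqrt(v)
  }, numeric(1))
}

#' Overlap between two gene lists
#'
#' Size of the set intersection (duplicates ignored).
#'
#' @param list_a,list_b character vectors of gene ids.
#' @return integer count.
#' @export
deg_overlap <- function(list_a, list_b) length(intersect(list_a, list_b))

#' Evaluate one held-out-type experiment
#'
#' Scores predictions against the observed stimulated cells: squared-Pearson
#' regression of gene-wise means and variances (with Fisher-z CI and p-value
#' on the mean regression), plus the overlap between the top-`n_top`
#' differential genes of predicted-vs-control and observed-stimulated-vs-
#' control (both ranked against the same control group).
#'
#' @param predicted predicted `expression_dataset` (from
#'   [predict_perturbed()]).
#' @param test_stimulated observed held-out stimulated cells.
#' @param test_control held-out control cells (DEG reference group).
#' @param n_top DEG list length.
#' @return object of class `eval_report`.
#' @export
evaluate_experiment <- function(predicted, test_stimulated, test_control,
                                n_top = 100L) {
  if (!identical(colnames(predicted$matrix), colnames(test_stimulated$matrix)))
    stop("predicted and observed gene axes differ")
  sp <- gene_stats(predicted)
  st <- gene_stats(test_stimulated)
  rm <- regression_r2(sp$means, st$means)
  rv <- regression_r2(sp$variances, st$variances)
  deg_true <- top_degs(test_stimulated, test_control, n_top)
  deg_pred <- top_degs(predicted, test_control, n_top)
  structure(list(r_mean = rm$r, r2_mean = rm$r2,
                 ci_low = rm$ci[1], ci_high = rm$ci[2], p_value = rm$p,
                 r_var = rv$r, r2_var = rv$r2,
                 n_genes = rm$n,
                 deg_true = as.character(deg_true),
                 deg_pred = as.character(deg_pred),
                 deg_overlap = deg_overlap(deg_true, deg_pred),
                 n_top = as.integer(n_top)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report over %d genes:\n", x$n_genes))
  cat(sprintf("  mean regression:     R^2 = %.4f (95%% CI %.4f-%.4f, p = %.3g)\n",
              x$r2_mean, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  variance regression: R^2 = %.4f\n", x$r2_var))
  cat(sprintf("  DEG overlap: %d / %d\n", x$deg_overlap, x$n_top))
  invisible(x)
}

#' One-row data.frame summary of an eval report
#' @param x an `eval_report`.
#' @param ... ignored.
#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(r2_mean = x$r2_mean, r2_var = x$r2_var,
             ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value,
             deg_overlap = x$deg_overlap, n_genes = x$n_genes)
}
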