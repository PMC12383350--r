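#' Quality filter on cells and genes
#'
#' Keeps cells expressing at least `min_genes_per_cell` genes (nonzero counts)
#' and then genes expressed in at least `min_cells_per_gene` of the surviving
#' cells — one pass each, cell-first. The defaults are the standard PBMC
#' thresholds (500 genes/cell, 5 cells/gene).
#'
#' @param ds raw-count `expression_dataset`.
#' @param min_genes_per_cell minimum number of expressed genes per cell.
#' @param min_cells_per_gene minimum number of expressing cells per gene.
#' @return filtered `expression_dataset`.
#' @export
filter_cells_genes <- function(ds, min_genes_per_cell = 500L,
                               min_cells_per_gene = 5L) {
  validate_dataset(ds)
  if (ds$layer_tag != "raw_counts")
    stop("filter_cells_genes expects raw counts, got ", ds$layer_tag)
  nz <- ds$matrix > 0
  keep_cells <- rowSums(nz) >= min_genes_per_cell
  if (!any(keep_cells)) stop("quality filter removed all cells")
  nz <- nz[keep_cells, , drop = FALSE]
  keep_genes <- colSums(nz) >= min_cells_per_gene
  ds[keep_cells, keep_genes]
}

#' Library-size normalization followed by log1p
#'
#' Scales each cell's counts so that they sum to `target_sum`, then applies
#' `log(1 + x)`. The result carries `layer_tag = "normalized_log"`.
#'
#' @param ds raw-count `expression_dataset`.
#' @param target_sum per-cell total after scaling (default 1e4, the common
#'   counts-per-10k convention).
#' @return normalized `expression_dataset`.
#' @export
normalize_log <- function(ds, target_sum = 1e4) {
  validate_dataset(ds)
  if (ds$layer_tag != "raw_counts")
    stop("normalize_log expects raw counts, got ", ds$layer_tag)
  totals <- rowSums(ds$matrix)
  if (any(totals == 0)) {
    bad <- rownames(ds$matrix)[totals == 0]
    stop("cell(s) with zero total counts: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- ds
  out$matrix <- log1p(ds$matrix * (target_sum / totals))
  out$layer_tag <- "normalized_log"
  out
}

#' Dispersion score used for highly-variable-gene selection
#'
#' Mean-binned normalized dispersion (Seurat flavour): expression is
#' de-logged (`expm1`), per-gene mean and dispersion (variance/mean) are
#' computed, genes are cut into `n_bins` equal-frequency mean bins, and the
#' dispersion is z-scored within each bin. Exposed so tests can recompute the
#' ranking independently.
#'
#' @param mat normalized_log cells x genes matrix.
#' @param n_bins number of mean bins.
#' @return numeric vector of normalized dispersions (one per gene; constant
#'   genes get `-Inf`).
#' @export
hvg_score <- function(mat, n_bins = 20L) {
  x <- expm1(mat)
  mu <- colMeans(x)
  v <- .col_vars(x)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency bins on the mean; collapse if few distinct values
  brk <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(brk) < 2) brk <- c(min(mu) - 1, max(mu) + 1)
  bin <- cut(mu, breaks = brk, include.lowest = TRUE)
  z <- disp
  for (b in levels(bin)) {
    idx <- which(bin == b)
    m <- mean(disp[idx]); s <- stats::sd(disp[idx])
    if (!is.finite(s) || s == 0) s <- 1
    z[idx] <- (disp[idx] - m) / s
  }
  z[v == 0] <- -Inf
  z
}

#' Select highly variable genes
#'
#' Keeps the `n_top` genes with the highest [hvg_score()], preserving the
#' input gene order among the selected.
#'
#' @param ds `expression_dataset` with the `normalized_log` layer.
#' @param n_top number of genes to keep (default 6998).
#' @return `expression_dataset` restricted to `min(n_top, n_genes)` genes.
#' @export
select_hvg <- function(ds, n_top = 6998L) {
  validate_dataset(ds)
  if (ds$layer_tag != "normalized_log")
    stop("select_hvg expects the normalized_log layer, got ", ds$layer_tag)
  if (n_top < 1L) stop("n_top must be >= 1")
  d <- n_genes(ds)
  if (n_top >= d) return(ds)
  score <- hvg_score(ds$matrix)
  keep <- sort(order(score, decreasing = TRUE)[seq_len(n_top)])
  ds[, keep]
}

#' Held-out cell-type split
#'
#' Withholds all stimulated cells of `holdout_type` as ground truth. The
#' training set keeps every other cell, including the held-out type's control
#' cells (which double as the test inputs); `strict = TRUE` additionally
#' removes those control cells from training.
#'
#' @param ds an `expression_dataset`.
#' @param holdout_type cell-type label present in both conditions.
#' @param strict exclude the holdout type's control cells from training.
#' @return list with `train`, `test_control`, `test_stimulated`.
#' @export
holdout_split <- function(ds, holdout_type, strict = FALSE) {
  validate_dataset(ds)
  is_type <- ds$obs$cell_type == holdout_type
  is_stim <- ds$obs$condition == "stimulated"
  if (!any(is_type & !is_stim))
    stop("holdout type '", holdout_type, "' absent from the control condition")
  if (!any(is_type & is_stim))
    stop("holdout type '", holdout_type, "' absent from the stimulated condition")
  test_stim_idx <- is_type & is_stim
  train_idx <- !test_stim_idx
  if (strict) train_idx <- train_idx & !(is_type & !is_stim)
  list(train = ds[train_idx, ],
       test_control = ds[is_type & !is_stim, ],
       test_stimulated = ds[test_stim_idx, ])
}

#' Stratified subsampling of a training set
#'
#' Uniform subset without replacement within each (cell_type, condition)
#' stratum; every stratum present in the input keeps at least one cell.
#'
#' @param ds an `expression_dataset`.
#' @param fraction sampling fraction in (0, 1]; 1 returns the input unchanged.
#' @param seed integer seed.
#' @return subsampled `expression_dataset`.
#' @export
subsample_train <- function(ds, fraction, seed = 0L) {
  validate_dataset(ds)
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(ds)
  set_global_seed(seed)
  strata <- interaction(ds$obs$cell_type, ds$obs$condition, drop = TRUE)
  keep <- integer(0)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    k <- round(length(idx) * fraction)
    if (k < 1L) {
      warning("stratum ", s, " would be emptied; keeping 1 cell")
      k <- 1L
    }
    keep <- c(keep, sort(sample(idx, k)))
  }
  ds[sort(keep), ]
}

# internal: unbiased per-column variances without matrixStats
.col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}
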