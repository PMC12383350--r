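#' Run one held-out-cell-type sub-experiment
#'
#' The full pipeline for a single holdout: (optional) quality filter +
#' library-size normalization + HVG selection, held-out-type split, MMD-VAE
#' training, latent transport alignment, delta-matrix construction,
#' similarity-weighted prediction of the held-out control cells, and
#' evaluation against the held-out stimulated ground truth.
#'
#' @param ds `expression_dataset` (raw counts unless `preprocessed = TRUE`).
#' @param holdout_type cell type to withhold under stimulation.
#' @param config a [run_config()].
#' @param emb optional [embedding_set()].
#' @param preprocessed set when `ds` already carries the normalized_log layer
#'   restricted to the modelling genes.
#' @param fraction training-set subsampling fraction (sensitivity analysis).
#' @param n_top DEG list length for evaluation.
#' @param out_dir optional directory: writes the predicted dataset, the report
#'   row, and the resolved config.
#' @param verbose log stage progress.
#' @return list with `report` (an `eval_report`), `predicted`, `model`,
#'   `holdout_type`.
#' @export
run_subexperiment <- function(ds, holdout_type, config = run_config(),
                              emb = NULL, preprocessed = FALSE, fraction = 1,
                              n_top = 100L, out_dir = NULL, verbose = FALSE) {
  validate_config(config)
  if (!preprocessed) {
    if (verbose) .log("preprocess: filter + normalize + HVG")
    ds <- filter_cells_genes(ds, config$min_genes_per_cell, config$min_cells_per_gene)
    ds <- normalize_log(ds, config$target_sum)
    ds <- select_hvg(ds, config$hvg_count)
  } else if (ds$layer_tag != "normalized_log") {
    stop("preprocessed = TRUE but layer is ", ds$layer_tag)
  }
  sp <- holdout_split(ds, holdout_type)
  train <- if (fraction < 1) subsample_train(sp$train, fraction, config$seed) else sp$train
  if (verbose) .log("train: %d cells, %d genes, holdout '%s'",
                    n_cells(train), n_genes(train), holdout_type)
  model <- train_mmdvae(train, config, emb, verbose = verbose)
  # the held-out type's control cells train the autoencoder but, lacking
  # same-type stimulated counterparts, are kept out of the alignment unless
  # explicitly requested
  ot_train <- if (config$ot_include_test_control) train else {
    keep <- !(train$obs$cell_type == holdout_type &
                train$obs$condition == "control")
    train[keep, ]
  }
  pops <- latent_populations(model, ot_train, config$ot_max_cells, config$seed, emb)
  if (verbose) .log("transport: %d x %d", nrow(pops$z_ctrl), nrow(pops$z_stim))
  res <- solve_emd(cost_matrix(pops$z_ctrl, pops$z_stim),
                   method = if (config$sinkhorn) "sinkhorn" else "exact",
                   reg = config$sinkhorn_reg)
  deltas <- delta_matrix(res, pops$z_ctrl, pops$z_stim,
                         literal = config$literal_delta)
  predicted <- predict_perturbed(sp$test_control, model, deltas, pops$z_ctrl,
                                 config, emb)
  report <- evaluate_experiment(predicted, sp$test_stimulated, sp$test_control,
                                n_top = n_top)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset(predicted, file.path(out_dir, paste0("predicted_", holdout_type, ".tsv")))
    row <- cbind(holdout_type = holdout_type, as.data.frame(report))
    utils::write.table(row, file.path(out_dir, paste0("report_", holdout_type, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_config(config, file.path(out_dir, "config_resolved.txt"))
  }
  if (verbose) .log("holdout '%s': R2_mean %.4f, R2_var %.4f, DEG overlap %d/%d",
                    holdout_type, report$r2_mean, report$r2_var,
                    report$deg_overlap, report$n_top)
  list(report = report, predicted = predicted, model = model,
       holdout_type = holdout_type)
}

#' Run every eligible held-out-type sub-experiment
#'
#' One sub-experiment per cell type present in both conditions, plus an
#' aggregate row holding the arithmetic means of the per-type metrics.
#' Preprocessing is done once on the full dataset (HVGs computed before
#' splitting), then shared across holdouts. Existing per-type report files in
#' `out_dir` are reused unless `force = TRUE`.
#'
#' @param ds raw-count `expression_dataset` (or preprocessed with
#'   `preprocessed = TRUE`).
#' @param config a [run_config()].
#' @param emb optional [embedding_set()].
#' @param preprocessed see [run_subexperiment()].
#' @param fraction training subsampling fraction.
#' @param n_top DEG list length.
#' @param out_dir optional output directory (enables resumability).
#' @param force recompute even if a per-type report file exists.
#' @param verbose log stage progress.
#' @return data.frame: one row per holdout type plus a final `"mean"` row
#'   with columns `holdout_type`, `r2_mean`, `r2_var`, `ci_low`, `ci_high`,
#'   `p_value`, `deg_overlap`, `n_genes`.
#' @export
run_all <- function(ds, config = run_config(), emb = NULL, preprocessed = FALSE,
                    fraction = 1, n_top = 100L, out_dir = NULL, force = FALSE,
                    verbose = FALSE) {
  if (!preprocessed) {
    ds <- filter_cells_genes(ds, config$min_genes_per_cell, config$min_cells_per_gene)
    ds <- normalize_log(ds, config$target_sum)
    ds <- select_hvg(ds, config$hvg_count)
  }
  tab <- table(ds$obs$cell_type, ds$obs$condition)
  eligible <- rownames(tab)[tab[, "control"] > 0 & tab[, "stimulated"] > 0]
  if (length(eligible) < 2L)
    stop("need at least 2 cell types present in both conditions")
  rows <- vector("list", length(eligible))
  for (i in seq_along(eligible)) {
    ht <- eligible[i]
    cache <- if (!is.null(out_dir)) file.path(out_dir, paste0("report_", ht, ".tsv")) else NULL
    if (!force && !is.null(cache) && file.exists(cache)) {
      rows[[i]] <- utils::read.table(cache, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE)
      next
    }
    out <- run_subexperiment(ds, ht, config, emb, preprocessed = TRUE,
                             fraction = fraction, n_top = n_top,
                             out_dir = out_dir, verbose = verbose)
    rows[[i]] <- cbind(holdout_type = ht, as.data.frame(out$report))
  }
  res <- do.call(rbind, rows)
  agg <- res[1, ]
  agg$holdout_type <- "mean"
  for (cn in setdiff(colnames(res), "holdout_type")) agg[[cn]] <- mean(res[[cn]])
  rbind(res, agg)
}
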