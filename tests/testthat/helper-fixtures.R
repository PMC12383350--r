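# Shared fixtures: everything is generated in code, nothing is read from disk.

# tiny labelled dataset with deterministic values
tiny_dataset <- function(n_per = 4, d = 6, seed = 42, layer = "raw_counts") {
  set.seed(seed)
  types <- rep(c("A", "B"), each = 2 * n_per)
  cond <- rep(rep(c("control", "stimulated"), each = n_per), 2)
  m <- matrix(rpois(length(types) * d, lambda = 5), length(types), d)
  if (layer == "normalized_log") m <- log1p(m)
  expression_dataset(m, types, cond, layer)
}

# small simulated experiment shared by model-level tests
small_sim <- function(seed = 7, types = 3, cells = 60, genes = 120, response = 25) {
  simulate_dataset(sim_config(n_cell_types = types,
                              cells_per_type_per_condition = cells,
                              n_genes = genes, n_response_genes = response,
                              seed = seed))
}

# small config that trains in seconds; ... overrides any default
small_config <- function(...) {
  args <- list(seed = 3, latent_dim = 8, hidden_widths = c(32, 32), epochs = 15,
               batch_size = 64, dropout = 0, hvg_count = 100,
               min_genes_per_cell = 10, min_cells_per_gene = 2, top_k = 10)
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}

# preprocessed small simulation (memoized per session)
.small_pre_env <- new.env()
small_preprocessed <- function() {
  if (is.null(.small_pre_env$ds)) {
    sim <- small_sim()
    ds <- filter_cells_genes(sim$dataset, 10, 2)
    ds <- normalize_log(ds)
    .small_pre_env$ds <- select_hvg(ds, 100)
    .small_pre_env$truth <- sim$truth
  }
  list(ds = .small_pre_env$ds, truth = .small_pre_env$truth)
}

# a trained small model + transport artefacts, shared across test files
.small_fit_env <- new.env()
small_fit <- function() {
  if (is.null(.small_fit_env$fit)) {
    pre <- small_preprocessed()
    cfg <- small_config()
    sp <- holdout_split(pre$ds, "type1")
    model <- train_mmdvae(sp$train, cfg)
    pops <- latent_populations(model, sp$train, cfg$ot_max_cells, cfg$seed)
    res <- solve_emd(cost_matrix(pops$z_ctrl, pops$z_stim))
    deltas <- delta_matrix(res, pops$z_ctrl, pops$z_stim)
    .small_fit_env$fit <- list(cfg = cfg, split = sp, model = model,
                               pops = pops, transport = res, deltas = deltas,
                               truth = pre$truth)
  }
  .small_fit_env$fit
}

# brute-force O(m^2) MMD^2 oracle (independent of the package implementation)
mmd2_oracle <- function(z, p, bw) {
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * bw^2))
  s <- function(x, y) {
    acc <- 0
    for (i in seq_len(nrow(x))) for (j in seq_len(nrow(y)))
      acc <- acc + k(x[i, ], y[j, ])
    acc / (nrow(x) * nrow(y))
  }
  s(z, z) + s(p, p) - 2 * s(z, p)
}

# exact EMD oracle for square uniform problems: minimum over all permutations
emd_perm_oracle <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), n <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(cost[cbind(seq_len(n), p)]) / n, numeric(1)))
}
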