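#' Simulator configuration
#'
#' Describes a synthetic unpaired perturbation experiment: several cell types,
#' independent control and stimulated populations (no cell-level pairing), a
#' response program shared across types but scaled per type, negative-binomial
#' counts with lognormal library-size variation. Defaults give a desk-scale
#' fixture (3 types x 400 cells/condition x 1000 genes, 100 response genes,
#' response magnitudes around 1 natural-log unit) that trains on a CPU in
#' minutes.
#'
#' @param n_cell_types number of cell types.
#' @param cells_per_type_per_condition cells per (type, condition); a single
#'   integer, or a 2-column matrix (types x control/stimulated) to emulate
#'   condition imbalance.
#' @param n_genes gene count.
#' @param n_response_genes genes carrying the perturbation program.
#' @param base_mean_log_mu,base_mean_log_sd lognormal parameters of baseline
#'   per-gene mean counts.
#' @param type_effect_sd sd of per-(type, gene) lognormal modulation — the
#'   source of cell-type identity.
#' @param lfc_mu,lfc_sd mean/sd of response-gene log-fold-change magnitudes
#'   (natural log); signs are random with probability `prop_up` of being up.
#' @param prop_up probability a response gene is upregulated.
#' @param type_response_scale per-type multipliers on the response program
#'   (length `n_cell_types`), or `NULL` to draw them from N(1, 0.15) truncated
#'   to be positive — shared direction, type-modulated magnitude.
#' @param nb_dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param library_size_cv coefficient of variation of the lognormal per-cell
#'   library scaling.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cell_types = 3L,
                       cells_per_type_per_condition = 400L,
                       n_genes = 1000L,
                       n_response_genes = 100L,
                       base_mean_log_mu = 0,
                       base_mean_log_sd = 1,
                       type_effect_sd = 0.4,
                       lfc_mu = 1,
                       lfc_sd = 0.25,
                       prop_up = 0.7,
                       type_response_scale = NULL,
                       nb_dispersion = 10,
                       library_size_cv = 0.3,
                       seed = 0L) {
  if (n_response_genes > n_genes) stop("n_response_genes must be <= n_genes")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  cells <- cells_per_type_per_condition
  if (is.matrix(cells)) {
    if (nrow(cells) != n_cell_types || ncol(cells) != 2L)
      stop("cells_per_type_per_condition matrix must be n_cell_types x 2")
  } else {
    cells <- matrix(as.integer(cells), n_cell_types, 2)
  }
  if (any(cells < 1L)) stop("each (type, condition) stratum needs >= 1 cell")
  if (!is.null(type_response_scale) && length(type_response_scale) != n_cell_types)
    stop("type_response_scale must have one entry per cell type")
  structure(list(n_cell_types = as.integer(n_cell_types),
                 cells = cells, n_genes = as.integer(n_genes),
                 n_response_genes = as.integer(n_response_genes),
                 base_mean_log_mu = base_mean_log_mu,
                 base_mean_log_sd = base_mean_log_sd,
                 type_effect_sd = type_effect_sd,
                 lfc_mu = lfc_mu, lfc_sd = lfc_sd, prop_up = prop_up,
                 type_response_scale = type_response_scale,
                 nb_dispersion = nb_dispersion,
                 library_size_cv = library_size_cv,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an unpaired perturbation dataset
#'
#' Draws negative-binomial counts with per-cell mean
#' `lib * base_g * type_effect * (stimulated ? exp(lfc_g * scale_t) : 1)`,
#' where the last factor applies only to response genes. Control and
#' stimulated cells are drawn independently (unpaired). The ground truth
#' records the response gene set, the signed log-fold-changes, and the
#' per-type scales.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (raw-count `expression_dataset`) and `truth`
#'   (class `sim_truth`: `response_genes`, `lfc` — length-d signed natural-log
#'   fold changes, zero off the response set —, `type_scale`, `base_mean`,
#'   `type_effect`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set_global_seed(config$seed)
  d <- config$n_genes
  types <- sprintf("type%d", seq_len(config$n_cell_types))
  genes <- sprintf("gene%04d", seq_len(d))

  base_mean <- stats::rlnorm(d, config$base_mean_log_mu, config$base_mean_log_sd)
  type_effect <- matrix(stats::rlnorm(config$n_cell_types * d,
                                      0, config$type_effect_sd),
                        config$n_cell_types, d,
                        dimnames = list(types, genes))
  resp <- sort(sample.int(d, config$n_response_genes))
  lfc <- rep(0, d)
  if (length(resp)) {
    mag <- abs(stats::rnorm(length(resp), config$lfc_mu, config$lfc_sd))
    sgn <- ifelse(stats::runif(length(resp)) < config$prop_up, 1, -1)
    lfc[resp] <- sgn * mag
  }
  scale_t <- config$type_response_scale
  if (is.null(scale_t)) {
    scale_t <- stats::rnorm(config$n_cell_types, 1, 0.15)
    scale_t <- pmax(scale_t, 0.2)
  }
  names(scale_t) <- types

  ncells <- sum(config$cells)
  counts <- matrix(0L, ncells, d)
  cell_type <- character(ncells)
  condition <- character(ncells)
  sdlog <- sqrt(log(1 + config$library_size_cv^2))
  row <- 0L
  for (t in seq_len(config$n_cell_types)) {
    mu_ctrl <- base_mean * type_effect[t, ]
    mu_stim <- mu_ctrl
    mu_stim[resp] <- mu_stim[resp] * exp(lfc[resp] * scale_t[t])
    for (cond in 1:2) {
      nc <- config$cells[t, cond]
      mu <- if (cond == 1) mu_ctrl else mu_stim
      lib <- stats::rlnorm(nc, -sdlog^2 / 2, sdlog) # mean-1 library factors
      draw <- stats::rnbinom(nc * d, size = config$nb_dispersion,
                             mu = outer(lib, mu))
      counts[row + seq_len(nc), ] <- matrix(draw, nc, d)
      cell_type[row + seq_len(nc)] <- types[t]
      condition[row + seq_len(nc)] <- c("control", "stimulated")[cond]
      row <- row + nc
    }
  }
  dimnames(counts) <- list(sprintf("cell_%05d", seq_len(ncells)), genes)
  ds <- expression_dataset(counts, cell_type, condition, "raw_counts")
  truth <- structure(list(response_genes = genes[resp], lfc = stats::setNames(lfc, genes),
                          type_scale = scale_t, base_mean = stats::setNames(base_mean, genes),
                          type_effect = type_effect),
                     class = "sim_truth")
  list(dataset = ds, truth = truth)
}

#' Ground-truth expression shift for one cell type
#'
#' The programmed per-gene shift for `cell_type` on the natural-log scale of
#' mean counts: `lfc_g * type_scale[cell_type]` on response genes and exactly
#' 0 elsewhere. This is the count-space program; the empirically observed
#' shift of mean log-normalized expression tracks it closely but not exactly
#' (log1p curvature and renormalization of library sizes; see the methods
#' vignette).
#'
#' @param truth a `sim_truth`.
#' @param cell_type one of the simulated type labels.
#' @return named numeric vector of length `n_genes`.
#' @export
ground_truth_shift <- function(truth, cell_type) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!cell_type %in% names(truth$type_scale))
    stop("unknown cell type: ", cell_type)
  truth$lfc * truth$type_scale[[cell_type]]
}
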