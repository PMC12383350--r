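#' Model/run configuration
#'
#' Collects every tunable of the pipeline in one validated list. Defaults
#' follow common practice for scGen-family models at typical PBMC data scale:
#' MLP encoder/decoder with two hidden layers of 800 units plus a linear
#' latent-to-gene skip path, latent dimension 100, Adam at 1e-3 with a
#' step-decay tail, batch size 64, 100 epochs, no dropout (see the methods
#' vignette for why the smaller batch and zero dropout are the defaults).
#'
#' @param seed integer; master seed for the run.
#' @param latent_dim latent dimension k.
#' @param hidden_widths integer vector of encoder hidden-layer widths (the
#'   decoder mirrors them).
#' @param alpha positive weight of the latent regularizer in the total loss.
#' @param kernel_bandwidth positive RBF bandwidth sigma; 1 and 2 are the
#'   competitive settings for unit-scale latents.
#' @param extra_bandwidths optional additional bandwidths; when non-empty the
#'   MMD is the sum over `c(kernel_bandwidth, extra_bandwidths)`.
#' @param dropout dropout rate on hidden layers during training.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param top_k number of most-similar training control cells whose deltas are
#'   aggregated per test cell.
#' @param regularizer `"mmd"` (default) or `"kl"` (ablation arm).
#' @param use_cell_embedding,use_perturb_embedding enable injection of the
#'   respective precomputed embedding.
#' @param perturb_embed_scope `"all"` adds the perturbation embedding to every
#'   cell; `"stimulated"` restricts it to stimulated cells.
#' @param ot_max_cells per-population cap on cells entering the transport
#'   problem (bounds the n x m cost matrix).
#' @param ot_include_test_control keep the held-out type's control cells in
#'   the transport populations. They stay in VAE training either way, but by
#'   default they are excluded from the alignment: having no same-type
#'   stimulated counterpart, their transport deltas mix cross-type
#'   displacement into the response signal (see the methods vignette).
#' @param hvg_count number of highly variable genes kept by [select_hvg()].
#' @param target_sum per-cell total after library-size normalization.
#' @param min_genes_per_cell,min_cells_per_gene quality-filter thresholds.
#' @param literal_delta keep the unnormalized coupling-weighted sum when
#'   building the delta matrix (debug; see [delta_matrix()]).
#' @param sinkhorn use entropic regularization instead of exact EMD.
#' @param sinkhorn_reg entropic regularization strength when `sinkhorn=TRUE`.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(seed = 0L,
                       latent_dim = 100L,
                       hidden_widths = c(800L, 800L),
                       alpha = 1,
                       kernel_bandwidth = 1,
                       extra_bandwidths = numeric(0),
                       dropout = 0,
                       batch_size = 64L,
                       epochs = 100L,
                       learning_rate = 1e-3,
                       top_k = 30L,
                       regularizer = c("mmd", "kl"),
                       use_cell_embedding = FALSE,
                       use_perturb_embedding = FALSE,
                       perturb_embed_scope = c("all", "stimulated"),
                       ot_max_cells = 5000L,
                       ot_include_test_control = FALSE,
                       hvg_count = 6998L,
                       target_sum = 1e4,
                       min_genes_per_cell = 500L,
                       min_cells_per_gene = 5L,
                       literal_delta = FALSE,
                       sinkhorn = FALSE,
                       sinkhorn_reg = 0.05) {
  regularizer <- match.arg(regularizer)
  perturb_embed_scope <- match.arg(perturb_embed_scope)
  cfg <- list(seed = as.integer(seed), latent_dim = as.integer(latent_dim),
              hidden_widths = as.integer(hidden_widths), alpha = alpha,
              kernel_bandwidth = kernel_bandwidth,
              extra_bandwidths = as.numeric(extra_bandwidths),
              dropout = dropout, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), learning_rate = learning_rate,
              top_k = as.integer(top_k), regularizer = regularizer,
              use_cell_embedding = isTRUE(use_cell_embedding),
              use_perturb_embedding = isTRUE(use_perturb_embedding),
              perturb_embed_scope = perturb_embed_scope,
              ot_max_cells = as.integer(ot_max_cells),
              ot_include_test_control = isTRUE(ot_include_test_control),
              hvg_count = as.integer(hvg_count), target_sum = target_sum,
              min_genes_per_cell = as.integer(min_genes_per_cell),
              min_cells_per_gene = as.integer(min_cells_per_gene),
              literal_delta = isTRUE(literal_delta),
              sinkhorn = isTRUE(sinkhorn), sinkhorn_reg = sinkhorn_reg)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!(cfg$alpha >= 0)) stop("alpha must be >= 0")
  if (cfg$kernel_bandwidth <= 0) stop("kernel_bandwidth must be > 0")
  if (cfg$top_k < 1L) stop("top_k must be >= 1")
  if (cfg$hvg_count < 1L) stop("hvg_count must be >= 1")
  if (cfg$latent_dim < 1L) stop("latent_dim must be >= 1")
  if (any(cfg$hidden_widths < 1L)) stop("hidden_widths must be positive")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0,1)")
  if (cfg$learning_rate <= 0) stop("learning_rate must be > 0")
  if (!cfg$regularizer %in% c("mmd", "kl"))
    stop("regularizer must be 'mmd' or 'kl'")
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

#' Read/write a flat key:value config file
#'
#' One `key: value` pair per line; vector values are comma-separated. Unknown
#' keys are rejected so typos fail loudly.
#'
#' @param path config file path.
#' @param overrides named list applied on top of the file.
#' @return a `run_config`.
#' @export
read_config <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  args <- list()
  for (p in kv) {
    key <- trimws(p[[1]])
    val <- trimws(paste(p[-1], collapse = ":"))
    args[[key]] <- val
  }
  args[names(overrides)] <- overrides
  defaults <- formals(run_config)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (key in names(args)) {
    if (is.character(args[[key]])) {
      v <- strsplit(args[[key]], ",", fixed = TRUE)[[1]]
      v <- trimws(v)
      num <- suppressWarnings(as.numeric(v))
      if (!anyNA(num)) args[[key]] <- num
      else if (all(v %in% c("TRUE", "FALSE", "true", "false")))
        args[[key]] <- as.logical(toupper(v))
      else args[[key]] <- v
    }
  }
  do.call(run_config, args)
}

#' @rdname read_config
#' @param cfg a `run_config` to serialize.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  lines <- vapply(names(cfg), function(nm)
    sprintf("%s: %s", nm, paste(format(cfg[[nm]], scientific = FALSE), collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

# internal: timestamped log line on stderr
.log <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}
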