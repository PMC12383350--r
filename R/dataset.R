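#' Construct an expression dataset
#'
#' The central data container: a dense cells x genes matrix together with
#' per-cell metadata. Cells are rows and genes are columns throughout the
#' package. The `condition` label has exactly two modelling levels,
#' `"control"` and `"stimulated"` (predicted output additionally uses
#' `"predicted"`).
#'
#' @param matrix numeric matrix, cells x genes, with rownames (cell ids) and
#'   colnames (gene ids). If names are absent they are generated.
#' @param cell_type character/factor vector of per-cell type labels.
#' @param condition character/factor vector of per-cell condition labels;
#'   values must be in `c("control", "stimulated", "predicted")`.
#' @param layer_tag which transform the matrix carries: `"raw_counts"` or
#'   `"normalized_log"`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix`, `obs` (data.frame with `cell_type`, `condition`), `layer_tag`.
#' @export
expression_dataset <- function(matrix, cell_type, condition,
                               layer_tag = c("raw_counts", "normalized_log")) {
  layer_tag <- match.arg(layer_tag)
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) stop("expression matrix must be numeric")
  n <- nrow(matrix)
  if (is.null(rownames(matrix))) rownames(matrix) <- sprintf("cell_%d", seq_len(n))
  if (is.null(colnames(matrix))) colnames(matrix) <- sprintf("gene_%d", seq_len(ncol(matrix)))
  if (length(cell_type) != n) stop("cell_type length (", length(cell_type),
                                   ") != number of cells (", n, ")")
  if (length(condition) != n) stop("condition length (", length(condition),
                                   ") != number of cells (", n, ")")
  obs <- data.frame(cell_type = as.character(cell_type),
                    condition = as.character(condition),
                    row.names = rownames(matrix),
                    stringsAsFactors = FALSE)
  ds <- structure(list(matrix = matrix, obs = obs, layer_tag = layer_tag),
                  class = "expression_dataset")
  validate_dataset(ds)
  ds
}

#' Validate an expression dataset
#'
#' Checks the structural invariants: matrix/metadata agreement, populated
#' labels, admissible condition levels, nonnegative counts for the raw layer
#' and finite values for the log layer.
#'
#' @param ds an `expression_dataset`.
#' @return `ds`, invisibly; otherwise an error naming the violated invariant.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (nrow(ds$matrix) != nrow(ds$obs))
    stop("matrix has ", nrow(ds$matrix), " rows but obs has ", nrow(ds$obs))
  if (anyNA(ds$obs$cell_type) || any(!nzchar(ds$obs$cell_type)))
    stop("every cell must carry a cell_type label")
  if (anyNA(ds$obs$condition))
    stop("every cell must carry a condition label")
  bad <- setdiff(unique(ds$obs$condition), c("control", "stimulated", "predicted"))
  if (length(bad))
    stop("unexpected condition level(s): ", paste(bad, collapse = ", "),
         " (expected control/stimulated)")
  if (ds$layer_tag == "raw_counts" && any(ds$matrix < 0))
    stop("raw_counts layer contains negative entries")
  if (ds$layer_tag == "normalized_log" && any(!is.finite(ds$matrix)))
    stop("normalized_log layer contains non-finite entries")
  invisible(ds)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d cells x %d genes [%s]\n",
              nrow(x$matrix), ncol(x$matrix), x$layer_tag))
  cat("  cell types:", paste(names(table(x$obs$cell_type)), collapse = ", "), "\n")
  cat("  conditions:", paste(sprintf("%s(%d)", names(table(x$obs$condition)),
                                     table(x$obs$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Number of cells / genes
#' @param ds an `expression_dataset`.
#' @return integer count.
#' @export
n_cells <- function(ds) nrow(ds$matrix)

#' @rdname n_cells
#' @export
n_genes <- function(ds) ncol(ds$matrix)

#' Subset a dataset by cells and/or genes
#' @param x an `expression_dataset`.
#' @param i cell index (logical, integer, or cell-id character).
#' @param j gene index.
#' @param ... ignored.
#' @export
`[.expression_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$matrix))
  if (missing(j)) j <- seq_len(ncol(x$matrix))
  structure(list(matrix = x$matrix[i, j, drop = FALSE],
                 obs = x$obs[i, , drop = FALSE],
                 layer_tag = x$layer_tag),
            class = "expression_dataset")
}

#' Read a dataset from delimited text
#'
#' Reads a cells x genes matrix (first column = cell id, remaining columns =
#' genes) plus a cell metadata table, and maps the given condition levels onto
#' the package's canonical `control`/`stimulated` levels. Tab- and
#' comma-separated files are auto-detected from the extension.
#'
#' @param path matrix file (`.tsv`/`.csv`); first column holds cell ids.
#' @param obs_path metadata file with a cell-id first column; defaults to
#'   `<path-without-ext>_obs.<ext>`.
#' @param cell_type_key,condition_key metadata column names.
#' @param control_level,stimulated_level values of `condition_key` to map onto
#'   the canonical levels.
#' @param layer_tag transform carried by the matrix.
#' @return an `expression_dataset`.
#' @export
read_dataset <- function(path, obs_path = NULL,
                         cell_type_key = "cell_type",
                         condition_key = "condition",
                         control_level = "control",
                         stimulated_level = "stimulated",
                         layer_tag = c("raw_counts", "normalized_log")) {
  layer_tag <- match.arg(layer_tag)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (is.null(obs_path)) {
    ext <- tools::file_ext(path)
    obs_path <- sub(paste0("\\.", ext, "$"), paste0("_obs.", ext), path)
  }
  if (!file.exists(obs_path)) stop("metadata file not found: ", obs_path)
  sep_of <- function(p) if (tolower(tools::file_ext(p)) == "csv") "," else "\t"
  mat_df <- utils::read.table(path, header = TRUE, sep = sep_of(path),
                              check.names = FALSE, stringsAsFactors = FALSE)
  obs <- utils::read.table(obs_path, header = TRUE, sep = sep_of(obs_path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  cell_ids <- as.character(mat_df[[1]])
  m <- as.matrix(mat_df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(m)[!vapply(seq_len(ncol(m)), function(j) is.numeric(mat_df[[j + 1]]), TRUE)]
    stop("non-numeric expression column(s): ", paste(bad, collapse = ", "))
  }
  rownames(m) <- cell_ids
  obs_ids <- as.character(obs[[1]])
  if (!setequal(obs_ids, cell_ids))
    stop("cell ids in metadata do not match the matrix file")
  obs <- obs[match(cell_ids, obs_ids), , drop = FALSE]
  for (key in c(cell_type_key, condition_key))
    if (!key %in% colnames(obs))
      stop("metadata column not found: ", key)
  cond_raw <- as.character(obs[[condition_key]])
  cond <- rep(NA_character_, length(cond_raw))
  cond[cond_raw == control_level] <- "control"
  cond[cond_raw == stimulated_level] <- "stimulated"
  if (anyNA(cond)) {
    extra <- unique(cond_raw[is.na(cond)])
    stop("condition column '", condition_key, "' has unmapped level(s): ",
         paste(extra, collapse = ", "))
  }
  expression_dataset(m, cell_type = obs[[cell_type_key]], condition = cond,
                     layer_tag = layer_tag)
}

#' Write a dataset to delimited text
#'
#' Writes the matrix (cell-id first column) and a `<stem>_obs.<ext>` metadata
#' table next to it. Round-trips through [read_dataset()] losslessly for
#' labels and within float-print tolerance for values.
#'
#' @param ds an `expression_dataset` with at least one cell.
#' @param path output matrix file (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  if (n_cells(ds) == 0L) stop("refusing to write an empty dataset (0 cells)")
  ext <- tools::file_ext(path)
  sep <- if (tolower(ext) == "csv") "," else "\t"
  obs_path <- sub(paste0("\\.", ext, "$"), paste0("_obs.", ext), path)
  mat_df <- data.frame(cell_id = rownames(ds$matrix), ds$matrix,
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(mat_df, path, sep = sep, quote = FALSE, row.names = FALSE)
  obs_df <- data.frame(cell_id = rownames(ds$obs), ds$obs,
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(obs_df, obs_path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Seed all random streams
#'
#' Every stochastic operation in the package (weight initialization, minibatch
#' order, reparameterization draws, prior draws, dropout masks, subsampling,
#' the simulator) draws from R's global RNG, so a single call makes a full run
#' reproducible. Operations that take an explicit `seed` argument call
#' `set_global_seed` themselves.
#'
#' @param seed integer seed.
#' @return invisible `NULL`.
#' @export
set_global_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}

# internal: split a dataset matrix by condition, returning row indices
.cond_idx <- function(ds, condition) which(ds$obs$condition == condition)
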