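#' Assemble an embedding set
#'
#' Holds optional precomputed per-cell and per-perturbation embeddings
#' (typically exported from a pretrained single-cell or molecular language
#' model) plus the learned linear projections that map them to gene space.
#' The projections live in the model state and are zero-initialized, so at
#' training start the injection is exactly a no-op and the no-embedding
#' ablation arm coincides with the enabled arm at initialization.
#'
#' @param cell_embedding numeric n x e matrix with rownames = cell ids, or
#'   `NULL` (disabled).
#' @param perturb_embedding numeric length-p vector, or `NULL` (disabled).
#' @param dataset the `expression_dataset` the cell embedding must align to.
#' @return object of class `embedding_set` with elements `cell_embedding`,
#'   `perturb_embedding`, `e`, `p`, `enabled_cell`, `enabled_perturb`.
#' @export
embedding_set <- function(cell_embedding = NULL, perturb_embedding = NULL,
                          dataset = NULL) {
  if (!is.null(cell_embedding)) {
    cell_embedding <- as.matrix(cell_embedding)
    if (!is.null(dataset)) {
      if (nrow(cell_embedding) != n_cells(dataset))
        stop("cell embedding has ", nrow(cell_embedding), " rows but dataset has ",
             n_cells(dataset), " cells")
      ids <- rownames(dataset$matrix)
      if (!is.null(rownames(cell_embedding))) {
        if (!setequal(rownames(cell_embedding), ids))
          stop("cell embedding ids do not match dataset cell ids")
        cell_embedding <- cell_embedding[ids, , drop = FALSE]
      } else rownames(cell_embedding) <- ids
    }
  }
  if (!is.null(perturb_embedding)) perturb_embedding <- as.numeric(perturb_embedding)
  structure(list(cell_embedding = cell_embedding,
                 perturb_embedding = perturb_embedding,
                 e = if (is.null(cell_embedding)) 0L else ncol(cell_embedding),
                 p = if (is.null(perturb_embedding)) 0L else length(perturb_embedding),
                 enabled_cell = !is.null(cell_embedding),
                 enabled_perturb = !is.null(perturb_embedding)),
            class = "embedding_set")
}

#' Load embeddings from delimited files
#'
#' The cell embedding file is a delimited matrix whose first column is the
#' cell id (rows may be in any order; they are realigned to the dataset). The
#' perturbation embedding file holds a single numeric row (optionally with a
#' header). Either path may be `NULL`, yielding a disabled component whose
#' injection is a no-op.
#'
#' @param cell_path,perturb_path file paths or `NULL`.
#' @param dataset the `expression_dataset` to align cell rows against.
#' @return an `embedding_set`.
#' @export
load_embeddings <- function(cell_path = NULL, perturb_path = NULL, dataset) {
  cell_embedding <- NULL
  if (!is.null(cell_path)) {
    sep <- if (tolower(tools::file_ext(cell_path)) == "csv") "," else "\t"
    df <- utils::read.table(cell_path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    cell_embedding <- as.matrix(df[, -1, drop = FALSE])
    rownames(cell_embedding) <- as.character(df[[1]])
    if (!is.numeric(cell_embedding)) stop("cell embedding file is not numeric")
  }
  perturb_embedding <- NULL
  if (!is.null(perturb_path)) {
    sep <- if (tolower(tools::file_ext(perturb_path)) == "csv") "," else "\t"
    v <- utils::read.table(perturb_path, header = FALSE, sep = sep)
    v <- suppressWarnings(as.numeric(as.matrix(v)[nrow(v), ]))
    if (anyNA(v)) { # header row present: retry keeping the last row only
      v2 <- utils::read.table(perturb_path, header = TRUE, sep = sep)
      v <- as.numeric(as.matrix(v2)[1, ])
    }
    perturb_embedding <- v
  }
  embedding_set(cell_embedding, perturb_embedding, dataset)
}

#' Inject embeddings into the encoder input
#'
#' Returns `D + cell_embedding %*% cell_proj + perturb broadcast`, the
#' embedding-augmented encoder input. Both embeddings are mapped to gene
#' space through learned linear projections (`cell_proj`: e x d,
#' `perturb_proj`: p x d); the perturbation term is one d-vector broadcast to
#' the selected rows. Disabled components contribute nothing, so with both
#' disabled the input matrix is returned unchanged.
#'
#' @param mat cells x genes matrix (rows must align with `emb`'s cell rows;
#'   pass `rows` to select a subset).
#' @param emb an `embedding_set`.
#' @param cell_proj,perturb_proj projection matrices (from the model state).
#' @param rows integer indices of `emb$cell_embedding` rows matching `mat`'s
#'   rows; defaults to all.
#' @param perturb_rows logical/integer selection of rows that receive the
#'   perturbation term; defaults to all (scope `"all"`).
#' @return matrix of the same shape as `mat`.
#' @export
inject <- function(mat, emb, cell_proj = NULL, perturb_proj = NULL,
                   rows = NULL, perturb_rows = NULL) {
  out <- mat
  if (emb$enabled_cell) {
    if (is.null(cell_proj)) stop("cell embedding enabled but cell_proj missing")
    ce <- emb$cell_embedding
    if (!is.null(rows)) ce <- ce[rows, , drop = FALSE]
    if (nrow(ce) != nrow(mat))
      stop("cell embedding rows (", nrow(ce), ") != matrix rows (", nrow(mat), ")")
    if (ncol(cell_proj) != ncol(mat)) stop("cell projection output dimension mismatch")
    out <- out + ce %*% cell_proj
  }
  if (emb$enabled_perturb) {
    if (is.null(perturb_proj)) stop("perturbation embedding enabled but perturb_proj missing")
    if (ncol(perturb_proj) != ncol(mat)) stop("perturbation projection output dimension mismatch")
    v <- as.numeric(emb$perturb_embedding %*% perturb_proj)
    if (is.null(perturb_rows)) {
      out <- sweep(out, 2L, v, "+")
    } else {
      out[perturb_rows, ] <- sweep(out[perturb_rows, , drop = FALSE], 2L, v, "+")
    }
  }
  out
}
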