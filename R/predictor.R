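#' Top-k cosine similarity weights
#'
#' For each test latent, cosine similarity to every training control latent is
#' computed; the `top_k` largest are kept, negative similarities are clamped
#' to zero, and the rest are renormalized to sum to one (uniform fallback over
#' the selected cells if all are clamped). Cosine similarity is
#' scale-invariant, so the weights do not depend on latent magnitudes.
#'
#' @param z_test t x k matrix (or single k-vector) of test-cell latents.
#' @param z_ctrl_train n x k matrix of training control latents.
#' @param top_k number of neighbours kept per test cell.
#' @return object of class `similarity_weights`: list with integer matrix
#'   `indices` (t x min(top_k, n)) and weight matrix `weights` (rows sum to 1).
#' @export
similarity_weights <- function(z_test, z_ctrl_train, top_k = 30L) {
  if (is.null(dim(z_test))) z_test <- matrix(z_test, nrow = 1)
  if (is.null(dim(z_ctrl_train))) z_ctrl_train <- matrix(z_ctrl_train, nrow = 1)
  if (ncol(z_test) != ncol(z_ctrl_train)) stop("latent dimensions differ")
  if (top_k < 1L) stop("top_k must be >= 1")
  nt <- sqrt(rowSums(z_test^2))
  nc <- sqrt(rowSums(z_ctrl_train^2))
  if (any(nt == 0))
    stop("zero-norm test latent for cell(s): ",
         paste(utils::head(which(nt == 0), 5), collapse = ", "))
  if (any(nc == 0))
    stop("zero-norm training latent for cell(s): ",
         paste(utils::head(which(nc == 0), 5), collapse = ", "))
  sim <- tcrossprod(z_test / nt, z_ctrl_train / nc)
  k <- min(as.integer(top_k), nrow(z_ctrl_train))
  t_n <- nrow(z_test)
  idx <- matrix(0L, t_n, k)
  w <- matrix(0, t_n, k)
  for (i in seq_len(t_n)) {
    ord <- order(sim[i, ], decreasing = TRUE)[seq_len(k)]
    s <- pmax(sim[i, ord], 0)
    tot <- sum(s)
    idx[i, ] <- ord
    w[i, ] <- if (tot > 0) s / tot else rep(1 / k, k)
  }
  structure(list(indices = idx, weights = w), class = "similarity_weights")
}

#' Aggregate transport deltas under similarity weights
#'
#' The predicted latent shift per test cell: the convex combination of the
#' selected training-cell delta rows, `sum_i s_i * delta[i, ]`.
#'
#' @param weights a [similarity_weights()] object.
#' @param deltas a [delta_matrix()] (n x k).
#' @return t x k matrix of predicted latent shifts.
#' @export
aggregate_delta <- function(weights, deltas) {
  stopifnot(inherits(weights, "similarity_weights"))
  if (max(weights$indices) > nrow(deltas)) stop("weight indices exceed delta rows")
  t_n <- nrow(weights$indices)
  out <- matrix(0, t_n, ncol(deltas))
  for (i in seq_len(t_n))
    out[i, ] <- weights$weights[i, ] %*% deltas[weights$indices[i, ], , drop = FALSE]
  out
}

#' Shift latents and decode
#'
#' Applies the predicted perturbation shift in latent space and decodes:
#' `Decoder(z_test + delta_pred)`. Deterministic.
#'
#' @param z_test t x k matrix (or k-vector) of test-cell latents.
#' @param delta_pred matching matrix/vector of predicted shifts.
#' @param model trained `perturbot_model`.
#' @return t x genes matrix of predicted stimulated expression.
#' @export
shift_and_decode <- function(z_test, delta_pred, model) {
  if (is.null(dim(z_test))) z_test <- matrix(z_test, nrow = 1)
  if (is.null(dim(delta_pred))) delta_pred <- matrix(delta_pred, nrow = 1)
  if (!all(dim(z_test) == dim(delta_pred)))
    stop("z_test and delta_pred shapes differ")
  decode(model, z_test + delta_pred)
}

#' Predict stimulated profiles for unseen control cells
#'
#' End-to-end inference for a held-out population: encode the test control
#' cells (latent means), find each cell's top-k most similar training control
#' cells by cosine similarity, aggregate their transport deltas, shift, and
#' decode. Fully deterministic given a trained model.
#'
#' @param test_control `expression_dataset` of held-out control cells.
#' @param model trained `perturbot_model`.
#' @param deltas [delta_matrix()] over the training control cells.
#' @param z_ctrl_train latent means of the same training control cells
#'   (rows aligned with `deltas`).
#' @param config a [run_config()] (supplies `top_k`); defaults to the model's.
#' @param emb optional `embedding_set` matching the training run.
#' @return `expression_dataset` with one predicted profile per test control
#'   cell, `condition = "predicted"`, layer `normalized_log`.
#' @export
predict_perturbed <- function(test_control, model, deltas, z_ctrl_train,
                              config = NULL, emb = NULL) {
  validate_dataset(test_control)
  if (n_cells(test_control) == 0L) stop("empty test set")
  if (is.null(config)) config <- model$config
  z_test <- encode_dataset(model, test_control, emb)
  sw <- similarity_weights(z_test, z_ctrl_train, config$top_k)
  dpred <- aggregate_delta(sw, deltas)
  xpred <- shift_and_decode(z_test, dpred, model)
  rownames(xpred) <- rownames(test_control$matrix)
  expression_dataset(xpred,
                     cell_type = test_control$obs$cell_type,
                     condition = rep("predicted", nrow(xpred)),
                     layer_tag = "normalized_log")
}
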