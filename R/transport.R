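#' Latent control and stimulated populations
#'
#' Encodes the training control and stimulated cells to their latent means
#' (deterministic; no sampling at alignment time) and subsamples each
#' population to at most `max_cells` to bound the transport problem.
#'
#' @param model trained `perturbot_model`.
#' @param train `expression_dataset` used for training.
#' @param max_cells per-population cap (default from the model config).
#' @param seed seed for the subsampling draw.
#' @param emb optional `embedding_set` matching the training run.
#' @return list with matrices `z_ctrl` (n x k) and `z_stim` (m x k); rownames
#'   carry the cell ids.
#' @export
latent_populations <- function(model, train, max_cells = NULL, seed = 0L,
                               emb = NULL) {
  if (is.null(max_cells)) max_cells <- model$config$ot_max_cells
  ic <- .cond_idx(train, "control")
  is <- .cond_idx(train, "stimulated")
  if (!length(ic)) stop("no control cells in the training set")
  if (!length(is)) stop("no stimulated cells in the training set")
  set_global_seed(seed)
  if (length(ic) > max_cells) ic <- sort(sample(ic, max_cells))
  if (length(is) > max_cells) is <- sort(sample(is, max_cells))
  Z <- encode_dataset(model, train, emb)
  rownames(Z) <- rownames(train$matrix)
  list(z_ctrl = Z[ic, , drop = FALSE], z_stim = Z[is, , drop = FALSE])
}

#' Squared-Euclidean latent cost matrix
#'
#' `C[i, j] = ||z_ctrl[i, ] - z_stim[j, ]||^2`, the transport cost between
#' every control/stimulated latent pair.
#'
#' @param z_ctrl n x k matrix of control latents.
#' @param z_stim m x k matrix of stimulated latents.
#' @return n x m nonnegative matrix.
#' @export
cost_matrix <- function(z_ctrl, z_stim) {
  if (is.null(dim(z_ctrl))) z_ctrl <- matrix(z_ctrl, nrow = 1)
  if (is.null(dim(z_stim))) z_stim <- matrix(z_stim, nrow = 1)
  if (ncol(z_ctrl) != ncol(z_stim))
    stop("latent dimensions differ: ", ncol(z_ctrl), " vs ", ncol(z_stim))
  .sq_dists(z_ctrl, z_stim)
}

#' Solve the exact earth mover's distance problem
#'
#' Exact optimal transport between the two populations under uniform
#' marginals (1/n and 1/m), solved with a transportation-simplex
#' implementation (network simplex on the bipartite transportation graph).
#' The returned coupling satisfies the marginal constraints to 1e-8 and
#' minimizes `sum(coupling * cost)`. An entropically regularized Sinkhorn
#' alternative is available for very large populations.
#'
#' @param cost finite nonnegative n x m cost matrix.
#' @param method `"exact"` (default) or `"sinkhorn"`.
#' @param reg entropic regularization strength (sinkhorn only).
#' @return object of class `transport_result`: list with `cost`, `coupling`,
#'   `source_marginal`, `target_marginal`, `objective`.
#' @export
solve_emd <- function(cost, method = c("exact", "sinkhorn"), reg = 0.05) {
  method <- match.arg(method)
  cost <- as.matrix(cost)
  if (any(!is.finite(cost)) || any(cost < 0))
    stop("cost matrix (", nrow(cost), "x", ncol(cost), ") must be finite and nonnegative")
  n <- nrow(cost); m <- ncol(cost)
  mu <- rep(1 / n, n); nu <- rep(1 / m, m)
  if (method == "exact") {
    # integer-valued supplies keep the simplex arithmetic exact; the plan is
    # rescaled to the uniform marginals afterwards
    g <- .gcd(n, m)
    total <- as.double(n) * (m / g)
    sol <- .emd_exact_cpp(cost, rep(m / g, n), rep(n / g, m))
    gamma <- sol$coupling / total
    objective <- sol$objective / total
  } else {
    gamma <- .sinkhorn(cost, mu, nu, reg)
    objective <- sum(gamma * cost)
  }
  res <- structure(list(cost = cost, coupling = gamma,
                        source_marginal = mu, target_marginal = nu,
                        objective = objective, method = method),
                   class = "transport_result")
  validate_transport(res)
  res
}

#' Validate a transport result
#'
#' Asserts the coupling invariants: nonnegativity, marginals satisfied to
#' `tol`, and objective consistent with `sum(coupling * cost)`.
#'
#' @param res a `transport_result`.
#' @param tol marginal tolerance (default 1e-8; relaxed for sinkhorn).
#' @return `res`, invisibly.
#' @export
validate_transport <- function(res, tol = if (res$method == "exact") 1e-8 else 1e-4) {
  stopifnot(inherits(res, "transport_result"))
  if (any(res$coupling < -1e-15)) stop("coupling has negative entries")
  if (max(abs(rowSums(res$coupling) - res$source_marginal)) > tol)
    stop("row sums of the coupling violate the source marginal")
  if (max(abs(colSums(res$coupling) - res$target_marginal)) > tol)
    stop("column sums of the coupling violate the target marginal")
  if (abs(sum(res$coupling * res$cost) - res$objective) >
      1e-8 * (1 + abs(res$objective)))
    stop("objective inconsistent with coupling and cost")
  invisible(res)
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf("transport_result (%s): %d x %d coupling, objective %.6g\n",
              x$method, nrow(x$coupling), ncol(x$coupling), x$objective))
  invisible(x)
}

# log-domain Sinkhorn for the entropic alternative
.sinkhorn <- function(cost, mu, nu, reg, max_iter = 5000L, tol = 1e-10) {
  K <- -cost / reg
  f <- rep(0, length(mu)); g <- rep(0, length(nu))
  logmu <- log(mu); lognu <- log(nu)
  for (i in seq_len(max_iter)) {
    f_old <- f
    # f_i = reg * (logmu_i - logsumexp_j((K_ij + g_j)/reg ... work in scaled domain
    M <- sweep(K, 2L, g / reg, "+")
    f <- reg * (logmu - apply(M, 1L, .logsumexp))
    M <- sweep(K, 1L, f / reg, "+")
    g <- reg * (lognu - apply(M, 2L, .logsumexp))
    if (max(abs(f - f_old)) < tol) break
  }
  exp(sweep(sweep(K, 1L, f / reg, "+"), 2L, g / reg, "+"))
}

.logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

.gcd <- function(x, y) { while (y) { t <- x %% y; x <- y; y <- t }; x }

#' Per-cell perturbation delta matrix
#'
#' For each training control cell the transport-inferred latent displacement
#' toward the stimulated population: the barycentric projection
#' `(coupling[i, ] %*% z_stim) / rowmass[i] - z_ctrl[i, ]`. The row-mass
#' normalization gives each delta the scale of a latent displacement; setting
#' `literal = TRUE` keeps the raw coupling-weighted sum (whose rows carry mass
#' 1/n) for comparison.
#'
#' @param result a `transport_result`.
#' @param z_ctrl,z_stim the latent populations the coupling was solved on.
#' @param literal skip the row-mass normalization.
#' @return object of class `delta_matrix`: n x k matrix of latent deltas,
#'   rownames = control cell ids.
#' @export
delta_matrix <- function(result, z_ctrl, z_stim, literal = FALSE) {
  stopifnot(inherits(result, "transport_result"))
  gamma <- result$coupling
  if (nrow(gamma) != nrow(z_ctrl) || ncol(gamma) != nrow(z_stim))
    stop("coupling shape does not match the latent populations")
  rm <- rowSums(gamma)
  if (any(rm <= 0)) stop("coupling has a zero-mass row; cannot project")
  bary <- gamma %*% z_stim
  if (!literal) bary <- bary / rm
  deltas <- bary - z_ctrl
  rownames(deltas) <- rownames(z_ctrl)
  class(deltas) <- c("delta_matrix", class(deltas))
  deltas
}
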