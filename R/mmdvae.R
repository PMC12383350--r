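#' Gaussian RBF kernel
#'
#' `k(x, y) = exp(-||x - y||^2 / (2 * bandwidth^2))`. Vectorized over the rows
#' of two matrices; scalars/vectors are treated as single rows.
#'
#' @param x,y numeric vectors or matrices with rows as points.
#' @param bandwidth positive kernel bandwidth (sigma).
#' @return matrix of kernel values in (0, 1] (scalar if both inputs are single
#'   points).
#' @export
rbf_kernel <- function(x, y, bandwidth = 1) {
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  if (ncol(x) != ncol(y)) stop("x and y must have equal dimension")
  k <- exp(-.sq_dists(x, y) / (2 * bandwidth^2))
  if (length(k) == 1L) as.numeric(k) else k
}

# pairwise squared Euclidean distances between rows (clamped at 0 against
# cancellation)
.sq_dists <- function(x, y) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

#' Squared maximum mean discrepancy (V-statistic)
#'
#' Biased V-statistic estimator of MMD^2 between two samples under the RBF
#' kernel: `mean(Kxx) + mean(Kyy) - 2 mean(Kxy)`, with all pairs including
#' self-pairs. Nonnegative by construction and exactly 0 when the two samples
#' coincide. With several bandwidths the per-bandwidth estimates are summed.
#'
#' @param z numeric m1 x k sample matrix (rows = points).
#' @param z_prior numeric m2 x k sample matrix.
#' @param bandwidth positive bandwidth(s); a vector gives a multi-kernel sum.
#' @return nonnegative scalar.
#' @export
mmd2 <- function(z, z_prior, bandwidth = 1) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  if (is.null(dim(z_prior))) z_prior <- matrix(z_prior, ncol = 1)
  if (nrow(z) == 0L || nrow(z_prior) == 0L) stop("mmd2 requires nonempty samples")
  if (ncol(z) != ncol(z_prior)) stop("latent dimensions differ")
  dzz <- .sq_dists(z, z)
  dpp <- .sq_dists(z_prior, z_prior)
  dzp <- .sq_dists(z, z_prior)
  val <- 0
  for (bw in bandwidth) {
    if (bw <= 0) stop("bandwidth must be > 0")
    s <- 2 * bw^2
    val <- val + mean(exp(-dzz / s)) + mean(exp(-dpp / s)) - 2 * mean(exp(-dzp / s))
  }
  max(val, 0)
}

# gradient of mmd2 w.r.t. the rows of z (z_prior held fixed)
.mmd2_grad_z <- function(z, z_prior, bandwidth) {
  m1 <- nrow(z); m2 <- nrow(z_prior)
  dzz <- .sq_dists(z, z)
  dzp <- .sq_dists(z, z_prior)
  g <- matrix(0, m1, ncol(z))
  for (bw in bandwidth) {
    s2 <- bw^2
    Kzz <- exp(-dzz / (2 * s2))
    Kzp <- exp(-dzp / (2 * s2))
    # d/dz_a mean(Kzz): -(2/(m1^2 s2)) * (z_a * rowSums(Kzz) - Kzz %*% z)
    g <- g - (2 / (m1^2 * s2)) * (z * rowSums(Kzz) - Kzz %*% z)
    # d/dz_a of -2 mean(Kzp): +(2/(m1 m2 s2)) * (z_a * rowSums(Kzp) - Kzp %*% p)
    g <- g + (2 / (m1 * m2 * s2)) * (z * rowSums(Kzp) - Kzp %*% z_prior)
  }
  g
}

#' Reparameterization
#'
#' `z = mu + eps * sigma`, elementwise — the reparameterization trick that
#' makes the Gaussian sample differentiable in `mu` and `sigma`.
#'
#' @param mu,sigma,eps conformable numeric vectors/matrices.
#' @return `mu + eps * sigma`.
#' @export
reparameterize <- function(mu, sigma, eps) {
  stopifnot(length(mu) == length(sigma), length(mu) == length(eps))
  mu + eps * sigma
}

#' Closed-form KL regularizer (ablation arm)
#'
#' `KL(N(mu, sigma^2) || N(0, I))`, summed over latent dimensions and averaged
#' over the batch: `0.5 * sum(sigma^2 + mu^2 - 1 - 2 log sigma)`.
#'
#' @param mu,sigma numeric matrices (rows = cells) or vectors.
#' @return nonnegative scalar.
#' @export
kl_regularizer <- function(mu, sigma) {
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  if (is.null(dim(sigma))) sigma <- matrix(sigma, nrow = 1)
  sum(0.5 * (sigma^2 + mu^2 - 1 - 2 * log(sigma))) / nrow(mu)
}

#' Total training objective
#'
#' Reconstruction plus `alpha` times the latent regularizer:
#' `mean_i ||D_i - Dhat_i||^2 + alpha * reg`. The reconstruction is the
#' squared error summed over genes and averaged over the batch, so `alpha`
#' is batch-size invariant. The regularizer is the MMD^2 between the sampled
#' latents and a fresh standard-normal draw, or the closed-form KL in the
#' ablation arm.
#'
#' @param d,d_hat observed and reconstructed batches (cells x genes).
#' @param z sampled latent batch.
#' @param prior_draw standard-normal sample of matching width (`mmd` arm).
#' @param alpha regularizer weight.
#' @param regularizer `"mmd"` or `"kl"`.
#' @param bandwidth RBF bandwidth(s) for the `mmd` arm.
#' @param mu,sigma latent parameters (required for the `kl` arm).
#' @return list with `recon`, `reg`, `total`.
#' @export
total_loss <- function(d, d_hat, z, prior_draw = NULL, alpha = 1,
                       regularizer = c("mmd", "kl"), bandwidth = 1,
                       mu = NULL, sigma = NULL) {
  regularizer <- match.arg(regularizer)
  recon <- sum((d - d_hat)^2) / nrow(d)
  reg <- 0
  if (alpha > 0) {
    reg <- if (regularizer == "mmd") {
      if (is.null(prior_draw)) stop("mmd regularizer needs a prior draw")
      mmd2(z, prior_draw, bandwidth)
    } else {
      if (is.null(mu) || is.null(sigma)) stop("kl regularizer needs mu and sigma")
      kl_regularizer(mu, sigma)
    }
  }
  list(recon = recon, reg = reg, total = recon + alpha * reg)
}

#' Train the MMD-regularized VAE
#'
#' Minibatch Adam on the total objective. Fully reproducible: the run is
#' seeded from `config$seed`, and all stochastic elements (weight init, batch
#' order, dropout, reparameterization draws, prior draws) consume R's global
#' RNG in a fixed order. When `alpha = 0` the regularizer pathway (including
#' its prior draws) is skipped entirely, so the `mmd` and `kl` arms take an
#' identical code path and produce bit-identical models.
#'
#' @param train_set `expression_dataset` carrying the `normalized_log` layer.
#' @param config a [run_config()].
#' @param emb optional [embedding_set()]; components enabled here and in the
#'   config are injected through learned zero-initialized projections.
#' @param verbose log per-epoch losses.
#' @return a `perturbot_model` with trained parameters, the config, gene ids,
#'   and a per-epoch loss history.
#' @export
train_mmdvae <- function(train_set, config = run_config(), emb = NULL,
                         verbose = FALSE) {
  validate_dataset(train_set)
  validate_config(config)
  if (train_set$layer_tag != "normalized_log")
    stop("train_mmdvae expects the normalized_log layer")
  if (is.null(emb)) emb <- embedding_set()
  set_global_seed(config$seed)
  X <- train_set$matrix
  n <- nrow(X); d <- ncol(X)
  model <- init_model(d, config, emb)
  model$gene_ids <- colnames(X)
  params <- model$params
  # start the decoder output at the per-gene training means so early epochs
  # fit structure, not the mean expression profile
  params[[sprintf("dec%d_b", length(config$hidden_widths) + 1)]] <- colMeans(X)
  state <- list(m = list(), v = list(), t = 0L)
  bws <- c(config$kernel_bandwidth, config$extra_bandwidths)
  use_ce <- config$use_cell_embedding && emb$enabled_cell
  use_pe <- config$use_perturb_embedding && emb$enabled_perturb
  stim_rows_all <- train_set$obs$condition == "stimulated"
  hist <- matrix(0, config$epochs, 3)

  decay_at <- ceiling(0.85 * config$epochs) # step-decay tail: lr / 10
  for (epoch in seq_len(config$epochs)) {
    lr <- config$learning_rate * if (epoch > decay_at) 0.1 else 1
    perm <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    ep <- c(recon = 0, reg = 0, total = 0)
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      B <- length(idx)
      Xb <- X[idx, , drop = FALSE]
      pe_rows <- if (use_pe && config$perturb_embed_scope == "stimulated")
        which(stim_rows_all[idx]) else NULL
      Xin <- inject(Xb, emb, params$proj_cell, params$proj_pert,
                    rows = if (use_ce) idx else NULL,
                    perturb_rows = pe_rows)
      ec <- .enc_forward(params, Xin, config$hidden_widths, config$dropout, TRUE)
      eps <- matrix(stats::rnorm(B * config$latent_dim), B, config$latent_dim)
      Z <- ec$mu + eps * ec$sigma
      dc <- .dec_forward(params, Z, config$hidden_widths, config$dropout, TRUE)

      recon <- sum((Xb - dc$xhat)^2) / B
      reg <- 0
      dZ_reg <- NULL; dmu_reg <- NULL; dls_reg <- NULL
      if (config$alpha > 0) {
        if (config$regularizer == "mmd") {
          prior <- matrix(stats::rnorm(B * config$latent_dim), B, config$latent_dim)
          reg <- mmd2(Z, prior, bws)
          dZ_reg <- config$alpha * .mmd2_grad_z(Z, prior, bws)
        } else {
          reg <- kl_regularizer(ec$mu, ec$sigma)
          dmu_reg <- config$alpha * ec$mu / B
          dls_reg <- config$alpha * (ec$sigma^2 - 1) / B
        }
      }
      total <- recon + config$alpha * reg
      if (!is.finite(total))
        stop(sprintf("non-finite loss at epoch %d (recon=%g, reg=%g); lower the learning rate",
                     epoch, recon, reg))

      dXhat <- 2 * (dc$xhat - Xb) / B
      dg <- .dec_backward(params, dc, dXhat, config$hidden_widths)
      dZ <- dg$dZ
      if (!is.null(dZ_reg)) dZ <- dZ + dZ_reg
      dmu <- dZ
      dls <- dZ * eps * ec$sigma
      if (!is.null(dmu_reg)) { dmu <- dmu + dmu_reg; dls <- dls + dls_reg }
      eg <- .enc_backward(params, ec, dmu, dls, config$hidden_widths,
                          need_dx = use_ce || use_pe)
      grads <- c(dg[names(dg) != "dZ"], eg[names(eg) != "dX_in"])
      if (use_ce)
        grads$proj_cell <- crossprod(emb$cell_embedding[idx, , drop = FALSE], eg$dX_in)
      if (use_pe) {
        csum <- if (is.null(pe_rows)) colSums(eg$dX_in)
                else colSums(eg$dX_in[pe_rows, , drop = FALSE])
        grads$proj_pert <- outer(emb$perturb_embedding, csum)
      }
      grads <- .clip_grads(grads, clip = 5)
      upd <- .adam_step(params, grads, state, lr)
      params <- upd$params; state <- upd$state
      w <- B / n
      ep <- ep + w * c(recon = recon, reg = reg, total = total)
    }
    hist[epoch, ] <- ep
    if (verbose) .log("epoch %3d  recon %.4f  reg %.5f  total %.4f",
                      epoch, ep[1], ep[2], ep[3])
  }
  model$params <- params
  model$epoch <- config$epochs
  model$loss_history <- data.frame(epoch = seq_len(config$epochs),
                                   recon = hist[, 1], reg = hist[, 2],
                                   total = hist[, 3])
  model
}

#' Encode expression rows to latent parameters
#'
#' Deterministic inference pass (no dropout, no sampling): returns the latent
#' Gaussian parameters for each input row. Downstream alignment and
#' prediction use `mu` as the latent representative.
#'
#' @param model a trained `perturbot_model`.
#' @param x matrix (cells x genes) or a single gene-dimensional vector,
#'   already embedding-injected if applicable (see [encode_dataset()]).
#' @return list with matrices `mu` and `sigma` (rows = input rows).
#' @export
encode <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$d)
    stop("input has ", ncol(x), " genes but model expects ", model$d)
  ec <- .enc_forward(model$params, x, model$hidden, 0, FALSE)
  list(mu = ec$mu, sigma = ec$sigma)
}

#' Encode a dataset (with embedding injection)
#'
#' Applies the model's learned projections to the embedding components
#' enabled in its config, adds them to the expression matrix, and encodes.
#' Cell-embedding rows are matched to the dataset by cell id.
#'
#' @param model trained `perturbot_model`.
#' @param ds `expression_dataset` (normalized_log).
#' @param emb the `embedding_set` used at training time (or `NULL`).
#' @return matrix of latent means (cells x k).
#' @export
encode_dataset <- function(model, ds, emb = NULL) {
  if (is.null(emb)) emb <- embedding_set()
  cfg <- model$config
  rows <- NULL
  if (cfg$use_cell_embedding && emb$enabled_cell) {
    rows <- match(rownames(ds$matrix), rownames(emb$cell_embedding))
    if (anyNA(rows)) stop("cell embedding missing rows for some dataset cells")
  }
  pe_rows <- if (cfg$use_perturb_embedding && emb$enabled_perturb &&
                 cfg$perturb_embed_scope == "stimulated")
    which(ds$obs$condition == "stimulated") else NULL
  Xin <- inject(ds$matrix, emb,
                model$params$proj_cell, model$params$proj_pert,
                rows = rows, perturb_rows = pe_rows)
  encode(model, Xin)$mu
}

#' Decode latent rows to expression space
#'
#' Deterministic decoder pass.
#'
#' @param model trained `perturbot_model`.
#' @param z latent matrix (cells x k) or single k-vector.
#' @return reconstruction matrix (cells x genes).
#' @export
decode <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != model$k)
    stop("latent has dimension ", ncol(z), " but model expects ", model$k)
  out <- .dec_forward(model$params, z, model$hidden, 0, FALSE)$xhat
  colnames(out) <- model$gene_ids
  out
}

#' Grid-search the regularizer weight
#'
#' Short probe runs screen each candidate `alpha`: candidates whose
#' reconstruction-to-(alpha x regularizer) magnitude ratio falls outside
#' `ratio_bounds` after the probe are discarded; among the admissible ones the
#' candidate with the lowest held-out reconstruction error wins. If every
#' candidate is discarded the config's default is returned.
#'
#' @param candidate_alphas positive candidates.
#' @param train_set normalized_log `expression_dataset`.
#' @param config a [run_config()]; `probe_epochs` replaces its epoch budget
#'   during screening.
#' @param emb optional `embedding_set`.
#' @param probe_epochs probe length.
#' @param val_fraction held-out fraction for the validation reconstruction.
#' @param ratio_bounds admissible reconstruction:regularizer ratio range.
#' @return the chosen alpha.
#' @export
tune_alpha <- function(candidate_alphas, train_set, config = run_config(),
                       emb = NULL, probe_epochs = 5L, val_fraction = 0.1,
                       ratio_bounds = c(0.1, 10)) {
  stopifnot(length(candidate_alphas) >= 1)
  set_global_seed(config$seed)
  n <- n_cells(train_set)
  val_idx <- sort(sample.int(n, max(2L, floor(n * val_fraction))))
  tr <- train_set[setdiff(seq_len(n), val_idx), ]
  va <- train_set[val_idx, ]
  best <- NULL; best_err <- Inf
  for (a in candidate_alphas) {
    cfg <- config
    cfg$alpha <- a
    cfg$epochs <- as.integer(probe_epochs)
    m <- train_mmdvae(tr, cfg, emb)
    fin <- utils::tail(m$loss_history, 1)
    ratio <- fin$recon / max(a * fin$reg, .Machine$double.eps)
    if (ratio < ratio_bounds[1] || ratio > ratio_bounds[2]) next
    zv <- encode_dataset(m, va, emb)
    err <- sum((va$matrix - decode(m, zv))^2) / nrow(zv)
    if (err < best_err) { best_err <- err; best <- a }
  }
  if (is.null(best)) config$alpha else best
}
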