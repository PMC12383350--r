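# Internal dense-network machinery for the MMD-VAE: parameter init, forward
# passes with caches, backprop, and Adam. Pure matrix ops so BLAS does the
# heavy lifting; all randomness flows through R's global RNG for determinism.

# leaky rectifier: keeps a small negative slope so units cannot die
# permanently under early large gradients
.LEAKY <- 0.1
.relu <- function(x) { neg <- x < 0; x[neg] <- .LEAKY * x[neg]; x }
.relu_grad <- function(pre) { g <- matrix(1, nrow(pre), ncol(pre)); g[pre < 0] <- .LEAKY; g }

# Glorot-uniform init
.glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

# inverted dropout mask (scales kept units so inference needs no correction)
.drop_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

.LOGSD_CLAMP <- 5

# Initialize all parameters. `emb` supplies optional embedding dimensions;
# projections are ZERO-initialized so injection is a no-op at start.
init_model <- function(d, config, emb = NULL) {
  hidden <- config$hidden_widths
  k <- config$latent_dim
  L <- length(hidden)
  params <- list()
  dims <- c(d, hidden)
  for (l in seq_len(L)) {
    params[[sprintf("enc%d_W", l)]] <- .glorot(dims[l], dims[l + 1])
    params[[sprintf("enc%d_b", l)]] <- rep(0, dims[l + 1])
  }
  params$mu_W <- .glorot(hidden[L], k); params$mu_b <- rep(0, k)
  params$ls_W <- .glorot(hidden[L], k); params$ls_b <- rep(0, k)
  ddims <- c(k, rev(hidden), d)
  for (l in seq_len(L + 1)) {
    params[[sprintf("dec%d_W", l)]] <- .glorot(ddims[l], ddims[l + 1])
    params[[sprintf("dec%d_b", l)]] <- rep(0, ddims[l + 1])
  }
  # zero-initialized linear skip (latent -> genes): gives the decoder an
  # exactly-extrapolating first-order path for latent arithmetic
  params$skip_W <- matrix(0, k, d)
  if (!is.null(emb) && emb$enabled_cell && isTRUE(config$use_cell_embedding))
    params$proj_cell <- matrix(0, emb$e, d)
  if (!is.null(emb) && emb$enabled_perturb && isTRUE(config$use_perturb_embedding))
    params$proj_pert <- matrix(0, emb$p, d)
  structure(list(params = params, d = d, k = k, hidden = hidden,
                 config = config, epoch = 0L,
                 loss_history = data.frame(epoch = integer(0), recon = numeric(0),
                                           reg = numeric(0), total = numeric(0))),
            class = "perturbot_model")
}

#' @export
print.perturbot_model <- function(x, ...) {
  cat(sprintf("perturbot_model: %d genes -> [%s] -> k=%d (%s regularizer), %d epoch(s) trained\n",
              x$d, paste(x$hidden, collapse = ","), x$k,
              x$config$regularizer, x$epoch))
  if (nrow(x$loss_history))
    cat(sprintf("  final loss: recon %.4g + reg %.4g = %.4g\n",
                utils::tail(x$loss_history$recon, 1),
                utils::tail(x$loss_history$reg, 1),
                utils::tail(x$loss_history$total, 1)))
  invisible(x)
}

# Encoder forward. Returns mu, lsr (pre-clamp), ls, sigma plus caches needed
# for backprop. Dropout masks are drawn here (in layer order) when training.
.enc_forward <- function(params, X_in, hidden, dropout, training) {
  L <- length(hidden)
  pre <- vector("list", L); act <- vector("list", L); masks <- vector("list", L)
  A <- X_in
  for (l in seq_len(L)) {
    E <- sweep(A %*% params[[sprintf("enc%d_W", l)]], 2L,
               params[[sprintf("enc%d_b", l)]], "+")
    H <- .relu(E)
    M <- if (training) .drop_mask(nrow(H), ncol(H), dropout) else NULL
    if (!is.null(M)) H <- H * M
    pre[[l]] <- E; act[[l]] <- H; masks[l] <- list(M)
    A <- H
  }
  mu <- sweep(A %*% params$mu_W, 2L, params$mu_b, "+")
  lsr <- sweep(A %*% params$ls_W, 2L, params$ls_b, "+")
  ls <- pmin(pmax(lsr, -.LOGSD_CLAMP), .LOGSD_CLAMP)
  list(mu = mu, lsr = lsr, ls = ls, sigma = exp(ls),
       pre = pre, act = act, masks = masks, X_in = X_in)
}

# Decoder forward with caches.
.dec_forward <- function(params, Z, hidden, dropout, training) {
  L <- length(hidden)
  pre <- vector("list", L + 1); act <- vector("list", L + 1); masks <- vector("list", L + 1)
  A <- Z
  for (l in seq_len(L + 1)) {
    E <- sweep(A %*% params[[sprintf("dec%d_W", l)]], 2L,
               params[[sprintf("dec%d_b", l)]], "+")
    if (l <= L) {
      H <- .relu(E)
      M <- if (training) .drop_mask(nrow(H), ncol(H), dropout) else NULL
      if (!is.null(M)) H <- H * M
    } else { H <- E; M <- NULL }
    pre[[l]] <- E; act[[l]] <- H; masks[l] <- list(M)
    A <- H
  }
  if (!is.null(params$skip_W)) A <- A + Z %*% params$skip_W
  list(xhat = A, pre = pre, act = act, masks = masks, Z = Z)
}

# Backprop through decoder: returns grads for dec params and dZ.
.dec_backward <- function(params, cache, dXhat, hidden) {
  L <- length(hidden)
  grads <- list()
  dZ_skip <- NULL
  if (!is.null(params$skip_W)) {
    grads$skip_W <- crossprod(cache$Z, dXhat)
    dZ_skip <- tcrossprod(dXhat, params$skip_W)
  }
  dH <- dXhat
  for (l in rev(seq_len(L + 1))) {
    if (l <= L) {
      if (!is.null(cache$masks[[l]])) dH <- dH * cache$masks[[l]]
      dH <- dH * .relu_grad(cache$pre[[l]])
    }
    Ain <- if (l == 1) cache$Z else cache$act[[l - 1]]
    grads[[sprintf("dec%d_W", l)]] <- crossprod(Ain, dH)
    grads[[sprintf("dec%d_b", l)]] <- colSums(dH)
    dH <- tcrossprod(dH, params[[sprintf("dec%d_W", l)]])
  }
  grads$dZ <- if (is.null(dZ_skip)) dH else dH + dZ_skip
  grads
}

# Backprop through encoder heads and trunk: returns grads and dX_in.
.enc_backward <- function(params, cache, dmu, dls, hidden, need_dx = FALSE) {
  L <- length(hidden)
  grads <- list()
  clamp_mask <- (cache$lsr > -.LOGSD_CLAMP) & (cache$lsr < .LOGSD_CLAMP)
  dls <- dls * clamp_mask
  Atop <- if (L >= 1) cache$act[[L]] else cache$X_in
  grads$mu_W <- crossprod(Atop, dmu); grads$mu_b <- colSums(dmu)
  grads$ls_W <- crossprod(Atop, dls); grads$ls_b <- colSums(dls)
  dH <- tcrossprod(dmu, params$mu_W) + tcrossprod(dls, params$ls_W)
  for (l in rev(seq_len(L))) {
    if (!is.null(cache$masks[[l]])) dH <- dH * cache$masks[[l]]
    dH <- dH * .relu_grad(cache$pre[[l]])
    Ain <- if (l == 1) cache$X_in else cache$act[[l - 1]]
    grads[[sprintf("enc%d_W", l)]] <- crossprod(Ain, dH)
    grads[[sprintf("enc%d_b", l)]] <- colSums(dH)
    dH <- if (l > 1 || need_dx) tcrossprod(dH, params[[sprintf("enc%d_W", l)]]) else NULL
  }
  if (need_dx) grads$dX_in <- dH
  grads
}

# rescale gradients so their global L2 norm is at most `clip`
.clip_grads <- function(grads, clip = 5) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > clip)
    grads <- lapply(grads, function(g) g * (clip / gn))
  grads
}

# Adam step (in place on the params list); state carries m, v, t.
.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) { state$m[[nm]] <- g * 0; state$v[[nm]] <- g * 0 }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
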