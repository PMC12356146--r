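# Compact neural-network engine: dense, 1-D convolutional and recurrent
# layers with analytic backprop, trained by Adam on binary cross-entropy
# (classifiers) or mean squared error (autoencoders). Everything is plain
# base-R matrix arithmetic; all stochasticity (weight init, batch shuffling,
# dropout) draws from R's RNG, so callers control determinism with a seed.
#
# Conventions:
#  * X is samples x features (B x d); labels y are 0/1.
#  * An "arch" is a list(init, forward, backward):
#      init()                      -> params (named list of arrays)
#      forward(params, X, training)-> list(logit = length-B vector, cache)
#      backward(params, X, cache, dlogit) -> grads (same shapes as params)
#  * Feature maps of the conv stacks are stored as (B*T) x C matrices with
#    row index b + (t-1)*B, which makes im2col and pooling pure reshapes.

sigmoid <- function(z) 1 / (1 + exp(-z))
relu <- function(z) (z > 0) * z

rand_mat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

# inverted dropout: returns pre-scaled multiplicative mask
drop_mask <- function(dim_, rate) {
  if (rate <= 0) {
    return(NULL)
  }
  array(
    (stats::runif(prod(dim_)) >= rate) / (1 - rate),
    dim = dim_
  )
}

apply_mask <- function(a, mask) if (is.null(mask)) a else a * mask

## ---- Adam -------------------------------------------------------------

adam_new <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0
  )
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- multilayer perceptron (also the logistic head) -------------------

build_mlp <- function(d, hidden, dropout_rate = 0) {
  sizes <- c(d, hidden, 1L)
  n_layers <- length(sizes) - 1L
  init <- function() {
    params <- list()
    for (i in seq_len(n_layers)) {
      params[[paste0("W", i)]] <- rand_mat(sizes[i], sizes[i + 1])
      params[[paste0("b", i)]] <- numeric(sizes[i + 1])
    }
    params
  }
  forward <- function(params, X, training = FALSE) {
    a <- X
    zs <- vector("list", n_layers)
    as <- list(a)
    masks <- vector("list", max(0L, n_layers - 1L))
    for (i in seq_len(n_layers)) {
      z <- a %*% params[[paste0("W", i)]] +
        rep(params[[paste0("b", i)]], each = nrow(a))
      if (i < n_layers) {
        a <- relu(z)
        m <- if (training) drop_mask(dim(a), dropout_rate) else NULL
        a <- apply_mask(a, m)
        masks[i] <- list(m)
        zs[[i]] <- z
        as[[i + 1]] <- a
      } else {
        zs[[i]] <- z
      }
    }
    list(logit = drop(zs[[n_layers]]), cache = list(zs = zs, as = as, masks = masks))
  }
  backward <- function(params, X, cache, dlogit) {
    grads <- list()
    dz <- matrix(dlogit, ncol = 1)
    for (i in rev(seq_len(n_layers))) {
      a_prev <- cache$as[[i]]
      grads[[paste0("W", i)]] <- crossprod(a_prev, dz)
      grads[[paste0("b", i)]] <- colSums(dz)
      if (i > 1) {
        da <- dz %*% t(params[[paste0("W", i)]])
        da <- apply_mask(da, cache$masks[[i - 1]])
        dz <- da * (cache$zs[[i - 1]] > 0)
      }
    }
    grads
  }
  list(init = init, forward = forward, backward = backward)
}

## ---- recurrent cells ---------------------------------------------------
# The feature vector is consumed as a length-T sequence of scalars
# (one SNP per time step, in panel order).

gru_init <- function(H) {
  list(
    wz = stats::rnorm(H, sd = 0.3), wr = stats::rnorm(H, sd = 0.3),
    wh = stats::rnorm(H, sd = 0.3),
    Uz = rand_mat(H, H) * 0.3, Ur = rand_mat(H, H) * 0.3,
    Uh = rand_mat(H, H) * 0.3,
    bz = numeric(H), br = numeric(H), bh = numeric(H)
  )
}

gru_forward <- function(p, X) {
  B <- nrow(X)
  T_ <- ncol(X)
  H <- length(p$bz)
  h <- matrix(0, B, H)
  Z <- R <- HC <- HP <- vector("list", T_)
  for (t in seq_len(T_)) {
    x <- X[, t]
    HP[[t]] <- h
    z <- sigmoid(outer(x, p$wz) + h %*% p$Uz + rep(p$bz, each = B))
    r <- sigmoid(outer(x, p$wr) + h %*% p$Ur + rep(p$br, each = B))
    hc <- tanh(outer(x, p$wh) + (r * h) %*% p$Uh + rep(p$bh, each = B))
    h <- (1 - z) * h + z * hc
    Z[[t]] <- z
    R[[t]] <- r
    HC[[t]] <- hc
  }
  list(h = h, cache = list(Z = Z, R = R, HC = HC, HP = HP))
}

gru_backward <- function(p, X, cache, dh) {
  T_ <- ncol(X)
  g <- lapply(p, function(q) array(0, dim = dim(q) %||% length(q)))
  for (t in rev(seq_len(T_))) {
    x <- X[, t]
    z <- cache$Z[[t]]
    r <- cache$R[[t]]
    hc <- cache$HC[[t]]
    hp <- cache$HP[[t]]
    dz <- dh * (hc - hp)
    dhc <- dh * z
    dhp <- dh * (1 - z)
    dpc <- dhc * (1 - hc^2)
    g$wh <- g$wh + colSums(x * dpc)
    g$Uh <- g$Uh + crossprod(r * hp, dpc)
    g$bh <- g$bh + colSums(dpc)
    drh <- dpc %*% t(p$Uh)
    dr <- drh * hp
    dhp <- dhp + drh * r
    dpr <- dr * r * (1 - r)
    g$wr <- g$wr + colSums(x * dpr)
    g$Ur <- g$Ur + crossprod(hp, dpr)
    g$br <- g$br + colSums(dpr)
    dhp <- dhp + dpr %*% t(p$Ur)
    dpz <- dz * z * (1 - z)
    g$wz <- g$wz + colSums(x * dpz)
    g$Uz <- g$Uz + crossprod(hp, dpz)
    g$bz <- g$bz + colSums(dpz)
    dhp <- dhp + dpz %*% t(p$Uz)
    dh <- dhp
  }
  g
}

lstm_init <- function(H) {
  out <- list()
  for (gate in c("i", "f", "o", "g")) {
    out[[paste0("w", gate)]] <- stats::rnorm(H, sd = 0.3)
    out[[paste0("U", gate)]] <- rand_mat(H, H) * 0.3
    out[[paste0("b", gate)]] <- if (gate == "f") rep(1, H) else numeric(H)
  }
  out
}

lstm_forward <- function(p, X) {
  B <- nrow(X)
  T_ <- ncol(X)
  H <- length(p$bi)
  h <- c_ <- matrix(0, B, H)
  cc <- vector("list", T_)
  for (t in seq_len(T_)) {
    x <- X[, t]
    i <- sigmoid(outer(x, p$wi) + h %*% p$Ui + rep(p$bi, each = B))
    f <- sigmoid(outer(x, p$wf) + h %*% p$Uf + rep(p$bf, each = B))
    o <- sigmoid(outer(x, p$wo) + h %*% p$Uo + rep(p$bo, each = B))
    gg <- tanh(outer(x, p$wg) + h %*% p$Ug + rep(p$bg, each = B))
    cn <- f * c_ + i * gg
    cc[[t]] <- list(i = i, f = f, o = o, g = gg, cp = c_, hp = h, cn = cn)
    c_ <- cn
    h <- o * tanh(cn)
  }
  list(h = h, cache = cc)
}

lstm_backward <- function(p, X, cache, dh) {
  T_ <- ncol(X)
  g <- lapply(p, function(q) array(0, dim = dim(q) %||% length(q)))
  dc <- dh * 0
  for (t in rev(seq_len(T_))) {
    x <- X[, t]
    s <- cache[[t]]
    tc <- tanh(s$cn)
    do_ <- dh * tc
    dc <- dc + dh * s$o * (1 - tc^2)
    df <- dc * s$cp
    di <- dc * s$g
    dg <- dc * s$i
    dc_prev <- dc * s$f
    pre <- list(
      i = di * s$i * (1 - s$i), f = df * s$f * (1 - s$f),
      o = do_ * s$o * (1 - s$o), g = dg * (1 - s$g^2)
    )
    dhp <- 0
    for (gate in names(pre)) {
      dp <- pre[[gate]]
      g[[paste0("w", gate)]] <- g[[paste0("w", gate)]] + colSums(x * dp)
      g[[paste0("U", gate)]] <- g[[paste0("U", gate)]] + crossprod(s$hp, dp)
      g[[paste0("b", gate)]] <- g[[paste0("b", gate)]] + colSums(dp)
      dhp <- dhp + dp %*% t(p[[paste0("U", gate)]])
    }
    dh <- dhp
    dc <- dc_prev
  }
  g
}

# prefix every parameter name (to combine several cells in one param list)
prefix_params <- function(p, pre) stats::setNames(p, paste0(pre, names(p)))
strip_prefix <- function(p, pre) {
  keep <- startsWith(names(p), pre)
  stats::setNames(p[keep], substring(names(p)[keep], nchar(pre) + 1))
}

build_gru_classifier <- function(d, units, dropout_rate = 0) {
  init <- function() {
    c(
      prefix_params(gru_init(units), "rnn."),
      list(Wo = rand_mat(units, 1), bo = 0)
    )
  }
  forward <- function(params, X, training = FALSE) {
    rnn <- strip_prefix(params, "rnn.")
    fw <- gru_forward(rnn, X)
    m <- if (training) drop_mask(dim(fw$h), dropout_rate) else NULL
    hd <- apply_mask(fw$h, m)
    logit <- drop(hd %*% params$Wo) + c(params$bo)
    list(logit = logit, cache = list(fw = fw, mask = m, hd = hd))
  }
  backward <- function(params, X, cache, dlogit) {
    dz <- matrix(dlogit, ncol = 1)
    dWo <- crossprod(cache$hd, dz)
    dbo <- sum(dz)
    dh <- apply_mask(dz %*% t(params$Wo), cache$mask)
    rnn <- strip_prefix(params, "rnn.")
    g <- gru_backward(rnn, X, cache$fw$cache, dh)
    c(prefix_params(g, "rnn."), list(Wo = dWo, bo = dbo))
  }
  list(init = init, forward = forward, backward = backward)
}

build_bilstm_classifier <- function(d, units, dropout_rate = 0) {
  init <- function() {
    c(
      prefix_params(lstm_init(units), "fwd."),
      prefix_params(lstm_init(units), "bwd."),
      list(Wo = rand_mat(2 * units, 1), bo = 0)
    )
  }
  forward <- function(params, X, training = FALSE) {
    Xr <- X[, rev(seq_len(ncol(X))), drop = FALSE]
    ff <- lstm_forward(strip_prefix(params, "fwd."), X)
    fb <- lstm_forward(strip_prefix(params, "bwd."), Xr)
    h <- cbind(ff$h, fb$h)
    m <- if (training) drop_mask(dim(h), dropout_rate) else NULL
    hd <- apply_mask(h, m)
    logit <- drop(hd %*% params$Wo) + c(params$bo)
    list(logit = logit, cache = list(ff = ff, fb = fb, Xr = Xr, mask = m, hd = hd))
  }
  backward <- function(params, X, cache, dlogit) {
    H <- (nrow(params$Wo)) / 2
    dz <- matrix(dlogit, ncol = 1)
    dWo <- crossprod(cache$hd, dz)
    dbo <- sum(dz)
    dh <- apply_mask(dz %*% t(params$Wo), cache$mask)
    gf <- lstm_backward(
      strip_prefix(params, "fwd."), X, cache$ff$cache,
      dh[, seq_len(H), drop = FALSE]
    )
    gb <- lstm_backward(
      strip_prefix(params, "bwd."), cache$Xr, cache$fb$cache,
      dh[, H + seq_len(H), drop = FALSE]
    )
    c(
      prefix_params(gf, "fwd."), prefix_params(gb, "bwd."),
      list(Wo = dWo, bo = dbo)
    )
  }
  list(init = init, forward = forward, backward = backward)
}

## ---- 1-D convolutions --------------------------------------------------

# im2col for a single-channel B x T input, valid convolution of width k:
# returns (B*Tout) x k with row index b + (t-1)*B
im2col_valid <- function(X, k) {
  B <- nrow(X)
  T_ <- ncol(X)
  tout <- T_ - k + 1
  A <- matrix(0, B * tout, k)
  for (j in seq_len(k)) {
    A[, j] <- as.vector(X[, j:(j + tout - 1), drop = FALSE])
  }
  A
}

# same-padded im2col for multi-channel maps stored as (B*T) x C
im2col_same <- function(M, B, T_, k) {
  C <- ncol(M)
  pad <- (k - 1) %/% 2
  A <- matrix(0, B * T_, k * C)
  for (j in seq_len(k)) {
    off <- j - pad - 1
    ts <- seq_len(T_)
    ss <- ts + off
    ok <- ss >= 1 & ss <= T_
    rows_t <- rep((ts[ok] - 1) * B, each = B) + seq_len(B)
    rows_s <- rep((ss[ok] - 1) * B, each = B) + seq_len(B)
    A[rows_t, (j - 1) * C + seq_len(C)] <- M[rows_s, , drop = FALSE]
  }
  A
}

im2col_same_scatter <- function(dA, B, T_, k, C) {
  pad <- (k - 1) %/% 2
  dM <- matrix(0, B * T_, C)
  for (j in seq_len(k)) {
    off <- j - pad - 1
    ts <- seq_len(T_)
    ss <- ts + off
    ok <- ss >= 1 & ss <= T_
    rows_t <- rep((ts[ok] - 1) * B, each = B) + seq_len(B)
    rows_s <- rep((ss[ok] - 1) * B, each = B) + seq_len(B)
    dM[rows_s, ] <- dM[rows_s, , drop = FALSE] +
      dA[rows_t, (j - 1) * C + seq_len(C), drop = FALSE]
  }
  dM
}

# mean over the time axis of a (B*T) x C map -> B x C
gap_pool <- function(M, B, T_) {
  arr <- M
  dim(arr) <- c(B, T_, ncol(M))
  colMeans(aperm(arr, c(2, 1, 3)))
}

gap_unpool <- function(dP, B, T_) {
  dP[rep(seq_len(B), T_), , drop = FALSE] / T_
}

build_cnn_classifier <- function(d, filter_size, n_filters = 8,
                                 dropout_rate = 0) {
  k <- min(filter_size, d)
  init <- function() {
    list(
      Wc = rand_mat(k, n_filters), bc = numeric(n_filters),
      Wo = rand_mat(n_filters, 1), bo = 0
    )
  }
  forward <- function(params, X, training = FALSE) {
    B <- nrow(X)
    tout <- ncol(X) - k + 1
    A <- im2col_valid(X, k)
    Z <- A %*% params$Wc + rep(params$bc, each = nrow(A))
    R <- relu(Z)
    pooled <- gap_pool(R, B, tout)
    m <- if (training) drop_mask(dim(pooled), dropout_rate) else NULL
    pd <- apply_mask(pooled, m)
    logit <- drop(pd %*% params$Wo) + c(params$bo)
    list(logit = logit, cache = list(A = A, Z = Z, pd = pd, mask = m, tout = tout))
  }
  backward <- function(params, X, cache, dlogit) {
    B <- nrow(X)
    dz <- matrix(dlogit, ncol = 1)
    dWo <- crossprod(cache$pd, dz)
    dbo <- sum(dz)
    dpd <- dz %*% t(params$Wo)
    dpooled <- apply_mask(dpd, cache$mask)
    dR <- gap_unpool(dpooled, B, cache$tout)
    dZ <- dR * (cache$Z > 0)
    list(
      Wc = crossprod(cache$A, dZ), bc = colSums(dZ),
      Wo = dWo, bo = dbo
    )
  }
  list(init = init, forward = forward, backward = backward)
}

build_resnet_classifier <- function(d, filter_size, n_filters = 8,
                                    n_blocks = 2, dropout_rate = 0) {
  k <- min(filter_size, d)
  if (k %% 2 == 0) k <- max(1L, k - 1L) # same padding needs odd width
  C <- n_filters
  init <- function() {
    params <- list(P = rand_mat(1, C), pb = numeric(C))
    for (b in seq_len(n_blocks)) {
      params[[paste0("W1_", b)]] <- rand_mat(k * C, C) * 0.5
      params[[paste0("b1_", b)]] <- numeric(C)
      params[[paste0("W2_", b)]] <- rand_mat(k * C, C) * 0.5
      params[[paste0("b2_", b)]] <- numeric(C)
    }
    c(params, list(Wo = rand_mat(C, 1), bo = 0))
  }
  forward <- function(params, X, training = FALSE) {
    B <- nrow(X)
    T_ <- ncol(X)
    Xc <- matrix(as.vector(X), ncol = 1)
    U <- relu(Xc %*% params$P + rep(params$pb, each = B * T_))
    blocks <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      A1 <- im2col_same(U, B, T_, k)
      Z1 <- A1 %*% params[[paste0("W1_", b)]] +
        rep(params[[paste0("b1_", b)]], each = B * T_)
      V <- relu(Z1)
      A2 <- im2col_same(V, B, T_, k)
      Z2 <- A2 %*% params[[paste0("W2_", b)]] +
        rep(params[[paste0("b2_", b)]], each = B * T_)
      pre <- Z2 + U
      blocks[[b]] <- list(U = U, A1 = A1, Z1 = Z1, A2 = A2, pre = pre)
      U <- relu(pre)
    }
    pooled <- gap_pool(U, B, T_)
    m <- if (training) drop_mask(dim(pooled), dropout_rate) else NULL
    pd <- apply_mask(pooled, m)
    logit <- drop(pd %*% params$Wo) + c(params$bo)
    list(
      logit = logit,
      cache = list(Xc = Xc, Uin = relu(Xc %*% params$P + rep(params$pb, each = B * T_)),
        blocks = blocks, Ufinal = U, pd = pd, mask = m, B = B, T_ = T_)
    )
  }
  backward <- function(params, X, cache, dlogit) {
    B <- cache$B
    T_ <- cache$T_
    dz <- matrix(dlogit, ncol = 1)
    grads <- list(Wo = crossprod(cache$pd, dz), bo = sum(dz))
    dpd <- dz %*% t(params$Wo)
    dpooled <- apply_mask(dpd, cache$mask)
    dU <- gap_unpool(dpooled, B, T_) # gradient wrt relu(pre) of last block
    for (b in rev(seq_len(n_blocks))) {
      blk <- cache$blocks[[b]]
      dpre <- dU * (blk$pre > 0)
      dU_skip <- dpre
      grads[[paste0("W2_", b)]] <- crossprod(blk$A2, dpre)
      grads[[paste0("b2_", b)]] <- colSums(dpre)
      dA2 <- dpre %*% t(params[[paste0("W2_", b)]])
      dV <- im2col_same_scatter(dA2, B, T_, k, C)
      dZ1 <- dV * (blk$Z1 > 0)
      grads[[paste0("W1_", b)]] <- crossprod(blk$A1, dZ1)
      grads[[paste0("b1_", b)]] <- colSums(dZ1)
      dA1 <- dZ1 %*% t(params[[paste0("W1_", b)]])
      dU <- dU_skip + im2col_same_scatter(dA1, B, T_, k, C)
    }
    # through input projection relu
    Zp <- cache$Xc %*% params$P + rep(params$pb, each = B * T_)
    dZp <- dU * (Zp > 0)
    grads$P <- crossprod(cache$Xc, dZp)
    grads$pb <- colSums(dZp)
    grads
  }
  list(init = init, forward = forward, backward = backward)
}

## ---- training drivers --------------------------------------------------

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# Train a classifier arch with Adam on BCE. Assumes the caller has already
# seeded the RNG (see with_rng); returns params + per-epoch loss history.
train_nn_classifier <- function(arch, X, y, epochs, batch_size, learning_rate) {
  params <- arch$init()
  state <- adam_new(params)
  n <- nrow(X)
  history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    idx <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      b <- idx[start:min(start + batch_size - 1, n)]
      Xb <- X[b, , drop = FALSE]
      yb <- y[b]
      fw <- arch$forward(params, Xb, training = TRUE)
      p <- sigmoid(fw$logit)
      loss <- bce_loss(p, yb)
      if (!is.finite(loss)) {
        abort(sprintf("non-finite training loss at epoch %d", e))
      }
      losses <- c(losses, loss)
      dlogit <- (p - yb) / length(yb)
      grads <- arch$backward(params, Xb, fw$cache, dlogit)
      upd <- adam_step(params, grads, state, learning_rate)
      params <- upd$params
      state <- upd$state
    }
    history[e] <- mean(losses)
  }
  list(params = params, history = history)
}

# Single-hidden-layer (linear) autoencoder trained on MSE with optional L1
# penalties on the encoder weights (feature sparsity) or on the bottleneck
# activations (sparse autoencoder).
train_autoencoder <- function(X, bottleneck, epochs = 100, batch_size = 32,
                              learning_rate = 1e-3, l1_weights = 0,
                              l1_activity = 0) {
  d <- ncol(X)
  bottleneck <- check_count(bottleneck, "bottleneck")
  if (bottleneck >= d && d > 1) bottleneck <- d - 1L
  params <- list(
    W1 = rand_mat(d, bottleneck) * 0.5, b1 = numeric(bottleneck),
    W2 = rand_mat(bottleneck, d) * 0.5, b2 = numeric(d)
  )
  state <- adam_new(params)
  n <- nrow(X)
  history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    idx <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      b <- idx[start:min(start + batch_size - 1, n)]
      Xb <- X[b, , drop = FALSE]
      nb <- nrow(Xb)
      H <- Xb %*% params$W1 + rep(params$b1, each = nb)
      Xhat <- H %*% params$W2 + rep(params$b2, each = nb)
      err <- Xhat - Xb
      loss <- mean(err^2) +
        l1_weights * sum(abs(params$W1)) +
        l1_activity * mean(abs(H))
      if (!is.finite(loss)) {
        abort(sprintf("non-finite autoencoder loss at epoch %d", e))
      }
      losses <- c(losses, loss)
      dXhat <- 2 * err / length(err)
      gW2 <- crossprod(H, dXhat)
      gb2 <- colSums(dXhat)
      dH <- dXhat %*% t(params$W2)
      if (l1_activity > 0) dH <- dH + l1_activity * sign(H) / length(H)
      gW1 <- crossprod(Xb, dH)
      if (l1_weights > 0) gW1 <- gW1 + l1_weights * sign(params$W1)
      gb1 <- colSums(dH)
      upd <- adam_step(params, list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2),
        state, learning_rate)
      params <- upd$params
      state <- upd$state
    }
    history[e] <- mean(losses)
  }
  list(params = params, history = history)
}

ae_encode <- function(params, X) {
  X %*% params$W1 + rep(params$b1, each = nrow(X))
}
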