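# Native neural-network engine for small 1-D sequence classifiers.
#
# Layers operate on batched arrays: sequence layers on [B, T, C]
# (batch, time, channels), vector layers on [B, F] matrices. Every layer
# has a forward pass returning (out, cache) and a backward pass returning
# (dx, grads); gradients are exact and are verified against central
# finite differences in the test suite. The only BLAS entry points are
# ordinary matrix products, so results are deterministic on one thread.

# ---- shape helpers ---------------------------------------------------

# [B, T, C] array <-> [B*T, C] matrix (rows ordered batch-fastest, which
# is R's native column-major flattening, so these are zero-copy dim flips)
mat3 <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}
arr3 <- function(x, b, t, c) {
  dim(x) <- c(b, t, c)
  x
}

add_rowvec <- function(m, v) m + matrix(v, nrow(m), length(v), byrow = TRUE)

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# uniform init in [-a, a], the convention used for all weights
init_mat <- function(nr, nc, a) {
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

# ---- layer constructors ----------------------------------------------

layer_conv1d <- function(in_ch, out_ch, kernel = 3L, relu = TRUE) {
  a <- 1 / sqrt(in_ch * kernel)
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       relu = relu,
       params = list(W = init_mat(kernel * in_ch, out_ch, a),
                     b = stats::runif(out_ch, -a, a)))
}

layer_bilstm <- function(in_ch, hidden = 32L) {
  a <- 1 / sqrt(hidden)
  one_dir <- function() list(Wx = init_mat(in_ch, 4L * hidden, a),
                             Wh = init_mat(hidden, 4L * hidden, a),
                             b_ih = stats::runif(4L * hidden, -a, a),
                             b_hh = stats::runif(4L * hidden, -a, a))
  fw <- one_dir(); bw <- one_dir()
  list(type = "bilstm", in_ch = in_ch, hidden = hidden,
       params = list(Wx_f = fw$Wx, Wh_f = fw$Wh, b_ih_f = fw$b_ih,
                     b_hh_f = fw$b_hh,
                     Wx_b = bw$Wx, Wh_b = bw$Wh, b_ih_b = bw$b_ih,
                     b_hh_b = bw$b_hh))
}

# parameter-free multi-head scaled dot-product self-attention with a
# residual connection (no learned projections; heads by reshaping)
layer_attn_pf <- function(dim, heads = 4L) {
  stopifnot(dim %% heads == 0L)
  list(type = "attn_pf", dim = dim, heads = heads, params = list())
}

# projected multi-head self-attention block: learned Q/K/V/output
# projections, residual connection, learned elementwise-affine layer norm
layer_attn_proj <- function(dim, heads = 4L) {
  stopifnot(dim %% heads == 0L)
  a <- 1 / sqrt(dim)
  pm <- function() init_mat(dim, dim, a)
  list(type = "attn_proj", dim = dim, heads = heads,
       params = list(Wq = pm(), bq = numeric(dim),
                     Wk = pm(), bk = numeric(dim),
                     Wv = pm(), bv = numeric(dim),
                     Wo = pm(), bo = numeric(dim),
                     gamma = rep(1, dim), beta = numeric(dim)))
}

# affine-free layer normalisation over the feature axis
layer_layernorm <- function(dim) {
  list(type = "layernorm", dim = dim, params = list())
}

layer_dropout <- function(p = 0.2) {
  list(type = "dropout", p = p, params = list())
}

layer_gap <- function() list(type = "gap", params = list())

layer_dense <- function(in_dim, out_dim) {
  a <- 1 / sqrt(in_dim)
  list(type = "dense", in_dim = in_dim, out_dim = out_dim,
       params = list(W = init_mat(in_dim, out_dim, a),
                     b = stats::runif(out_dim, -a, a)))
}

# ---- forward passes --------------------------------------------------

fwd_conv1d <- function(layer, x) {
  d <- dim(x); b <- d[1]; t <- d[2]; cin <- d[3]
  k <- layer$kernel
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(b, t + k - 1L, cin))
  xp[, p + seq_len(t), ] <- x
  cols <- vector("list", k)
  for (dd in seq_len(k)) {
    s <- xp[, dd:(dd + t - 1L), , drop = FALSE]
    dim(s) <- c(b * t, cin)
    cols[[dd]] <- s
  }
  xcol <- do.call(cbind, cols)
  z <- add_rowvec(xcol %*% layer$params$W, layer$params$b)
  out <- if (layer$relu) pmax(z, 0) else z
  list(out = arr3(out, b, t, layer$out_ch),
       cache = list(xcol = xcol, mask = if (layer$relu) z > 0 else NULL,
                    b = b, t = t, cin = cin))
}

bwd_conv1d <- function(layer, cache, dout) {
  b <- cache$b; t <- cache$t; cin <- cache$cin; k <- layer$kernel
  p <- (k - 1L) %/% 2L
  dz <- mat3(dout)
  if (layer$relu) dz <- dz * cache$mask
  dW <- crossprod(cache$xcol, dz)
  db <- colSums(dz)
  dxcol <- tcrossprod(dz, layer$params$W)
  dxp <- array(0, c(b, t + k - 1L, cin))
  for (dd in seq_len(k)) {
    blk <- dxcol[, (dd - 1L) * cin + seq_len(cin), drop = FALSE]
    dim(blk) <- c(b, t, cin)
    dxp[, dd:(dd + t - 1L), ] <- dxp[, dd:(dd + t - 1L), , drop = FALSE] + blk
  }
  dx <- dxp[, p + seq_len(t), , drop = FALSE]
  dim(dx) <- c(b, t, cin)
  list(dx = dx, grads = list(W = dW, b = db))
}

# one LSTM direction; returns final hidden state and stacked caches.
# The input projection x %*% Wx for all time steps is a single matrix
# product; only the recurrent product stays inside the loop. Rows of the
# stacked [B*T, .] matrices for step t are (t-1)*B + (1:B).
lstm_dir_forward <- function(x, Wx, Wh, b_ih, b_hh) {
  d <- dim(x); bsz <- d[1]; t_len <- d[2]; cin <- d[3]
  h_dim <- ncol(Wh) %/% 4L
  xw <- mat3(x) %*% Wx # [B*T, 4h]
  bias_m <- matrix(b_ih + b_hh, bsz, 4L * h_dim, byrow = TRUE)
  h <- matrix(0, bsz, h_dim)
  cc <- matrix(0, bsz, h_dim)
  n <- bsz * t_len
  gi_a <- matrix(0, n, h_dim); gf_a <- matrix(0, n, h_dim)
  gg_a <- matrix(0, n, h_dim); go_a <- matrix(0, n, h_dim)
  tc_a <- matrix(0, n, h_dim); cp_a <- matrix(0, n, h_dim)
  hp_a <- matrix(0, n, h_dim)
  idx_i <- seq_len(h_dim)
  for (tt in seq_len(t_len)) {
    rows <- (tt - 1L) * bsz + seq_len(bsz)
    pre <- xw[rows, , drop = FALSE] + h %*% Wh + bias_m
    gi <- sigmoid(pre[, idx_i, drop = FALSE])
    gf <- sigmoid(pre[, h_dim + idx_i, drop = FALSE])
    gg <- tanh(pre[, 2L * h_dim + idx_i, drop = FALSE])
    go <- sigmoid(pre[, 3L * h_dim + idx_i, drop = FALSE])
    cp_a[rows, ] <- cc
    hp_a[rows, ] <- h
    cc <- gf * cc + gi * gg
    tc <- tanh(cc)
    h <- go * tc
    gi_a[rows, ] <- gi; gf_a[rows, ] <- gf
    gg_a[rows, ] <- gg; go_a[rows, ] <- go
    tc_a[rows, ] <- tc
  }
  h_mean <- matrix(0, bsz, h_dim)
  for (tt in seq_len(t_len - 1L)) {
    # h_prev at step t+1 is h at step t
    h_mean <- h_mean + hp_a[tt * bsz + seq_len(bsz), , drop = FALSE]
  }
  h_mean <- (h_mean + h) / t_len
  list(h = h, h_mean = h_mean, x_flat = mat3(x), gi = gi_a, gf = gf_a,
       gg = gg_a, go = go_a, tc = tc_a, c_prev = cp_a, h_prev = hp_a,
       bsz = bsz, t_len = t_len, cin = cin, h_dim = h_dim)
}

# backward through time; the output is the mean over time of the hidden
# states, so the same dh_step = dout / T enters at every step alongside
# the recurrent carry. Per-step gate gradients are stacked and the
# weight gradients formed by two matrix products at the end.
lstm_dir_backward <- function(fw, Wx, Wh, dh_step) {
  bsz <- fw$bsz; t_len <- fw$t_len; cin <- fw$cin; h_dim <- fw$h_dim
  g_all <- matrix(0, bsz * t_len, 4L * h_dim)
  dh <- dh_step
  dc <- matrix(0, bsz, h_dim)
  for (tt in rev(seq_len(t_len))) {
    rows <- (tt - 1L) * bsz + seq_len(bsz)
    gi <- fw$gi[rows, , drop = FALSE]; gf <- fw$gf[rows, , drop = FALSE]
    gg <- fw$gg[rows, , drop = FALSE]; go <- fw$go[rows, , drop = FALSE]
    tc <- fw$tc[rows, , drop = FALSE]
    do_ <- dh * tc
    dc <- dc + dh * go * (1 - tc^2)
    g_pre <- cbind(dc * gg * gi * (1 - gi),
                   dc * fw$c_prev[rows, , drop = FALSE] * gf * (1 - gf),
                   dc * gi * (1 - gg^2),
                   do_ * go * (1 - go))
    g_all[rows, ] <- g_pre
    dh <- tcrossprod(g_pre, Wh) + dh_step
    dc <- dc * gf
  }
  dx <- tcrossprod(g_all, Wx)
  list(dx = arr3(dx, bsz, t_len, cin),
       dWx = crossprod(fw$x_flat, g_all),
       dWh = crossprod(fw$h_prev, g_all),
       db = colSums(g_all))
}

fwd_bilstm <- function(layer, x) {
  p <- layer$params
  t_len <- dim(x)[2]
  xr <- x[, rev(seq_len(t_len)), , drop = FALSE]
  fw <- lstm_dir_forward(x, p$Wx_f, p$Wh_f, p$b_ih_f, p$b_hh_f)
  bw <- lstm_dir_forward(xr, p$Wx_b, p$Wh_b, p$b_ih_b, p$b_hh_b)
  list(out = cbind(fw$h_mean, bw$h_mean), cache = list(fw = fw, bw = bw))
}

bwd_bilstm <- function(layer, cache, dout) {
  p <- layer$params
  h <- layer$hidden
  t_len <- cache$fw$t_len
  g_f <- lstm_dir_backward(cache$fw, p$Wx_f, p$Wh_f,
                           dout[, seq_len(h), drop = FALSE] / t_len)
  g_b <- lstm_dir_backward(cache$bw, p$Wx_b, p$Wh_b,
                           dout[, h + seq_len(h), drop = FALSE] / t_len)
  t_len <- dim(g_f$dx)[2]
  dx <- g_f$dx + g_b$dx[, rev(seq_len(t_len)), , drop = FALSE]
  list(dx = dx,
       grads = list(Wx_f = g_f$dWx, Wh_f = g_f$dWh, b_ih_f = g_f$db,
                    b_hh_f = g_f$db,
                    Wx_b = g_b$dWx, Wh_b = g_b$dWh, b_ih_b = g_b$db,
                    b_hh_b = g_b$db))
}

# core scaled dot-product attention over precomputed Q, K, V arrays
attn_heads_forward <- function(q, k, v, heads) {
  d <- dim(q); bsz <- d[1]; t_len <- d[2]; cdim <- d[3]
  hd <- cdim %/% heads
  out <- array(0, d)
  probs <- vector("list", bsz)
  for (b in seq_len(bsz)) {
    probs[[b]] <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * hd + seq_len(hd)
      qb <- matrix(q[b, , cols], t_len, hd)
      kb <- matrix(k[b, , cols], t_len, hd)
      vb <- matrix(v[b, , cols], t_len, hd)
      s <- tcrossprod(qb, kb) / sqrt(hd)
      p <- softmax_rows(s)
      out[b, , cols] <- p %*% vb
      probs[[b]][[h]] <- p
    }
  }
  list(out = out, probs = probs)
}

attn_heads_backward <- function(dout, q, k, v, probs, heads) {
  d <- dim(q); bsz <- d[1]; t_len <- d[2]; cdim <- d[3]
  hd <- cdim %/% heads
  dq <- array(0, d); dk <- array(0, d); dv <- array(0, d)
  for (b in seq_len(bsz)) {
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * hd + seq_len(hd)
      qb <- matrix(q[b, , cols], t_len, hd)
      kb <- matrix(k[b, , cols], t_len, hd)
      vb <- matrix(v[b, , cols], t_len, hd)
      dob <- matrix(dout[b, , cols], t_len, hd)
      p <- probs[[b]][[h]]
      dp <- tcrossprod(dob, vb)
      dv[b, , cols] <- crossprod(p, dob)
      ds <- p * (dp - rowSums(dp * p))
      dq[b, , cols] <- ds %*% kb / sqrt(hd)
      dk[b, , cols] <- crossprod(ds, qb) / sqrt(hd)
    }
  }
  list(dq = dq, dk = dk, dv = dv)
}

fwd_attn_pf <- function(layer, x) {
  att <- attn_heads_forward(x, x, x, layer$heads)
  list(out = x + att$out, cache = list(x = x, probs = att$probs))
}

bwd_attn_pf <- function(layer, cache, dout) {
  g <- attn_heads_backward(dout, cache$x, cache$x, cache$x, cache$probs,
                           layer$heads)
  list(dx = dout + g$dq + g$dk + g$dv, grads = list())
}

# row-wise layer normalisation of a [N, C] matrix; returns cache for bwd
ln_rows_forward <- function(m, gamma = NULL, beta = NULL, eps = 1e-5) {
  mu <- rowMeans(m)
  ctr <- m - mu
  sig <- sqrt(rowMeans(ctr^2) + eps)
  xhat <- ctr / sig
  y <- if (is.null(gamma)) {
    xhat
  } else {
    add_rowvec(xhat * matrix(gamma, nrow(m), ncol(m), byrow = TRUE), beta)
  }
  list(y = y, xhat = xhat, sig = sig)
}

ln_rows_backward <- function(dy, cache, gamma = NULL) {
  xhat <- cache$xhat
  dxhat <- if (is.null(gamma)) dy
           else dy * matrix(gamma, nrow(dy), ncol(dy), byrow = TRUE)
  dm <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) /
    cache$sig
  out <- list(dx = dm)
  if (!is.null(gamma)) {
    out$dgamma <- colSums(dy * xhat)
    out$dbeta <- colSums(dy)
  }
  out
}

fwd_layernorm <- function(layer, x) {
  d <- dim(x)
  ln <- ln_rows_forward(mat3(x))
  list(out = arr3(ln$y, d[1], d[2], d[3]),
       cache = list(xhat = ln$xhat, sig = ln$sig, d = d))
}

bwd_layernorm <- function(layer, cache, dout) {
  g <- ln_rows_backward(mat3(dout), cache)
  list(dx = arr3(g$dx, cache$d[1], cache$d[2], cache$d[3]), grads = list())
}

fwd_attn_proj <- function(layer, x) {
  p <- layer$params
  d <- dim(x)
  xm <- mat3(x)
  qm <- add_rowvec(xm %*% p$Wq, p$bq)
  km <- add_rowvec(xm %*% p$Wk, p$bk)
  vm <- add_rowvec(xm %*% p$Wv, p$bv)
  q <- arr3(qm, d[1], d[2], d[3])
  k <- arr3(km, d[1], d[2], d[3])
  v <- arr3(vm, d[1], d[2], d[3])
  att <- attn_heads_forward(q, k, v, layer$heads)
  ocat_m <- mat3(att$out)
  am <- add_rowvec(ocat_m %*% p$Wo, p$bo)
  rm_ <- xm + am
  ln <- ln_rows_forward(rm_, p$gamma, p$beta)
  list(out = arr3(ln$y, d[1], d[2], d[3]),
       cache = list(xm = xm, q = q, k = k, v = v, probs = att$probs,
                    ocat_m = ocat_m, xhat = ln$xhat, sig = ln$sig, d = d))
}

bwd_attn_proj <- function(layer, cache, dout) {
  p <- layer$params
  d <- cache$d
  lng <- ln_rows_backward(mat3(dout),
                          list(xhat = cache$xhat, sig = cache$sig),
                          p$gamma)
  dr <- lng$dx                       # gradient at residual sum, [N, C]
  dWo <- crossprod(cache$ocat_m, dr)
  dbo <- colSums(dr)
  docat <- arr3(tcrossprod(dr, p$Wo), d[1], d[2], d[3])
  g <- attn_heads_backward(docat, cache$q, cache$k, cache$v, cache$probs,
                           layer$heads)
  dqm <- mat3(g$dq); dkm <- mat3(g$dk); dvm <- mat3(g$dv)
  dxm <- dr + tcrossprod(dqm, p$Wq) + tcrossprod(dkm, p$Wk) +
    tcrossprod(dvm, p$Wv)
  list(dx = arr3(dxm, d[1], d[2], d[3]),
       grads = list(Wq = crossprod(cache$xm, dqm), bq = colSums(dqm),
                    Wk = crossprod(cache$xm, dkm), bk = colSums(dkm),
                    Wv = crossprod(cache$xm, dvm), bv = colSums(dvm),
                    Wo = dWo, bo = dbo,
                    gamma = lng$dgamma, beta = lng$dbeta))
}

fwd_dropout <- function(layer, x, training) {
  if (!training || layer$p <= 0) {
    return(list(out = x, cache = NULL))
  }
  keep <- 1 - layer$p
  mask <- (matrix(stats::runif(length(x)), nrow(x)) < keep) / keep
  list(out = x * mask, cache = list(mask = mask))
}

bwd_dropout <- function(layer, cache, dout) {
  if (is.null(cache)) return(list(dx = dout, grads = list()))
  list(dx = dout * cache$mask, grads = list())
}

fwd_gap <- function(layer, x) {
  d <- dim(x)
  out <- rowsum(mat3(x), rep(seq_len(d[1]), times = d[2]),
                reorder = TRUE) / d[2]
  list(out = out, cache = list(d = d))
}

bwd_gap <- function(layer, cache, dout) {
  d <- cache$d
  dx <- dout[rep(seq_len(d[1]), times = d[2]), , drop = FALSE] / d[2]
  list(dx = arr3(dx, d[1], d[2], d[3]), grads = list())
}

fwd_dense <- function(layer, x) {
  list(out = add_rowvec(x %*% layer$params$W, layer$params$b),
       cache = list(x = x))
}

bwd_dense <- function(layer, cache, dout) {
  list(dx = tcrossprod(dout, layer$params$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

# ---- model-level forward/backward ------------------------------------

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
                conv1d = fwd_conv1d(l, x),
                bilstm = fwd_bilstm(l, x),
                attn_pf = fwd_attn_pf(l, x),
                attn_proj = fwd_attn_proj(l, x),
                layernorm = fwd_layernorm(l, x),
                dropout = fwd_dropout(l, x, training),
                gap = fwd_gap(l, x),
                dense = fwd_dense(l, x),
                stop("unknown layer type: ", l$type))
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    r <- switch(l$type,
                conv1d = bwd_conv1d(l, caches[[i]], dout),
                bilstm = bwd_bilstm(l, caches[[i]], dout),
                attn_pf = bwd_attn_pf(l, caches[[i]], dout),
                attn_proj = bwd_attn_proj(l, caches[[i]], dout),
                layernorm = bwd_layernorm(l, caches[[i]], dout),
                dropout = bwd_dropout(l, caches[[i]], dout),
                gap = bwd_gap(l, caches[[i]], dout),
                dense = bwd_dense(l, caches[[i]], dout))
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  grads
}

# cross-entropy on logits; y is an integer class vector (1-based)
ce_loss_grad <- function(logits, y) {
  b <- nrow(logits)
  p <- softmax_rows(logits)
  eps <- 1e-12
  loss <- -mean(log(pmax(p[cbind(seq_len(b), y)], eps)))
  dlogits <- p
  dlogits[cbind(seq_len(b), y)] <- dlogits[cbind(seq_len(b), y)] - 1
  list(loss = loss, dlogits = dlogits / b)
}

# ---- Adam with global-norm gradient clipping -------------------------

adam_state_init <- function(layers) {
  lapply(layers, function(l) {
    lapply(l$params, function(p) list(m = p * 0, v = p * 0))
  })
}

grad_global_norm <- function(grads) {
  s <- 0
  for (g in grads) for (gg in g) {
    if (!is.null(gg)) s <- s + sum(gg^2)
  }
  sqrt(s)
}

adam_step <- function(layers, grads, state, step,
                      lr = 1.5e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip_norm = 1.0) {
  if (!is.null(clip_norm)) {
    gn <- grad_global_norm(grads)
    if (gn > clip_norm) {
      sc <- clip_norm / (gn + 1e-12)
      grads <- lapply(grads, function(g) lapply(g, function(gg) gg * sc))
    }
  }
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  for (i in seq_along(layers)) {
    for (nm in names(layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      state[[i]][[nm]] <- st
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  list(layers = layers, state = state)
}
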