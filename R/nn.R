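# Neural-network internals: forward and backward passes for the
# convolution / batch-norm / ReLU blocks, the bidirectional LSTM, the soft
# attention layer and the softmax head, plus the Adam optimizer.
#
# Layout convention: a batch of B encoded reads of length T with C channels
# travels as a (B*T) x C matrix whose rows are time-major blocks of B, i.e.
# rows ((t-1)*B + 1):(t*B) hold position t for all reads. This makes both
# the im2col convolution and the per-timestep LSTM slicing plain row
# operations. All parameters live in a flat named list of matrices/vectors;
# gradients and Adam moments mirror that structure by name.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  ex <- exp(x)
  ex / rowSums(ex)
}

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# ---- parameter initialization ------------------------------------------------

.init_params <- function(hp) {
  p <- list()
  c_in <- 4L
  for (i in seq_len(hp$n_conv_blocks)) {
    p[[paste0("conv", i, "_W")]] <- .glorot(hp$W * c_in, hp$N_c)
    p[[paste0("conv", i, "_b")]] <- numeric(hp$N_c)
    p[[paste0("bn", i, "_gamma")]] <- rep(1, hp$N_c)
    p[[paste0("bn", i, "_beta")]]  <- numeric(hp$N_c)
    c_in <- hp$N_c
  }
  H2 <- hp$N_h %/% 2L
  for (d in c("f", "b")) {
    p[[paste0("lstm_", d, "_Wx")]] <- .glorot(hp$N_c, 4L * H2)
    p[[paste0("lstm_", d, "_Wh")]] <- .glorot(H2, 4L * H2)
    bias <- numeric(4L * H2)
    bias[(H2 + 1L):(2L * H2)] <- 1  # forget-gate bias starts open
    p[[paste0("lstm_", d, "_b")]] <- bias
  }
  p$attn_W1 <- .glorot(hp$N_h, hp$N_a)
  p$attn_b1 <- numeric(hp$N_a)
  p$attn_w2 <- .glorot(hp$N_a, 1L)
  p$out_W <- .glorot(hp$N_h, hp$N_y)
  p$out_b <- numeric(hp$N_y)
  p
}

.init_bn_state <- function(hp) {
  st <- list()
  for (i in seq_len(hp$n_conv_blocks)) {
    st[[paste0("bn", i, "_mean")]] <- numeric(hp$N_c)
    st[[paste0("bn", i, "_var")]]  <- rep(1, hp$N_c)
  }
  st
}

# ---- convolution (im2col, same padding) --------------------------------------

# x: (B*T) x C_in time-major matrix. Returns list(col = (B*T) x (W*C_in)).
.im2col <- function(x, B, T, W) {
  C <- ncol(x)
  pad <- (W - 1L) %/% 2L
  xp <- matrix(0, B * (T + 2L * pad), C)
  xp[(pad * B + 1L):((pad + T) * B), ] <- x
  col <- matrix(0, B * T, W * C)
  for (w in seq_len(W)) {
    rows <- ((w - 1L) * B + 1L):((w - 1L + T) * B)
    col[, ((w - 1L) * C + 1L):(w * C)] <- xp[rows, ]
  }
  col
}

.col2im <- function(dcol, B, T, W, C) {
  pad <- (W - 1L) %/% 2L
  dxp <- matrix(0, B * (T + 2L * pad), C)
  for (w in seq_len(W)) {
    rows <- ((w - 1L) * B + 1L):((w - 1L + T) * B)
    dxp[rows, ] <- dxp[rows, ] + dcol[, ((w - 1L) * C + 1L):(w * C)]
  }
  dxp[(pad * B + 1L):((pad + T) * B), , drop = FALSE]
}

# ---- batch normalization (per channel over all positions and reads) ----------

.bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                        momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    v <- colMeans(xc^2)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var  <- momentum * run_var  + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
    xc <- sweep(x, 2L, mu)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv_sd, "*")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, xhat = xhat, xc = xc, inv_sd = inv_sd,
       run_mean = run_mean, run_var = run_var)
}

.bn_backward <- function(dout, cache, gamma) {
  n <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2L, gamma, "*")
  # dx = inv_sd/n * (n*dxhat - colSums(dxhat) - xhat * colSums(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(n * dxhat, 2L, s1) - sweep(cache$xhat, 2L, s2, "*")
  dx <- sweep(dx, 2L, cache$inv_sd / n, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- LSTM (one direction) ----------------------------------------------------

# x: (B*T) x C time-major. order: forward 1:T, backward T:1.
.lstm_forward <- function(x, Wx, Wh, b, B, T, reverse = FALSE) {
  H2 <- nrow(Wh)
  xa <- x %*% Wx  # precompute input contribution, (B*T) x 4H2
  h <- matrix(0, B, H2); cc <- matrix(0, B, H2)
  hs <- matrix(0, B * T, H2)
  gi <- matrix(0, B * T, H2); gf <- gi; gg <- gi; go <- gi
  tc <- gi; cprev <- gi; hprev <- gi
  ts <- if (reverse) rev(seq_len(T)) else seq_len(T)
  idx <- function(t) ((t - 1L) * B + 1L):(t * B)
  for (t in ts) {
    r <- idx(t)
    hprev[r, ] <- h; cprev[r, ] <- cc
    a <- xa[r, , drop = FALSE] + h %*% Wh
    a <- sweep(a, 2L, b, "+")
    i_ <- .sigmoid(a[, 1:H2, drop = FALSE])
    f_ <- .sigmoid(a[, (H2 + 1):(2 * H2), drop = FALSE])
    g_ <- tanh(a[, (2 * H2 + 1):(3 * H2), drop = FALSE])
    o_ <- .sigmoid(a[, (3 * H2 + 1):(4 * H2), drop = FALSE])
    cc <- f_ * cc + i_ * g_
    tch <- tanh(cc)
    h <- o_ * tch
    hs[r, ] <- h
    gi[r, ] <- i_; gf[r, ] <- f_; gg[r, ] <- g_; go[r, ] <- o_; tc[r, ] <- tch
  }
  list(h = hs, gi = gi, gf = gf, gg = gg, go = go, tc = tc,
       cprev = cprev, hprev = hprev, ts = ts, B = B, T = T)
}

.lstm_backward <- function(dh_all, cache, x, Wx, Wh) {
  B <- cache$B; T <- cache$T; H2 <- ncol(cache$h)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4L * H2)
  dx <- matrix(0, nrow(x), ncol(x))
  dh_next <- matrix(0, B, H2); dc_next <- matrix(0, B, H2)
  idx <- function(t) ((t - 1L) * B + 1L):(t * B)
  dA <- matrix(0, B * T, 4L * H2)  # pre-activation grads, filled per step
  for (t in rev(cache$ts)) {
    r <- idx(t)
    dh <- dh_all[r, , drop = FALSE] + dh_next
    tch <- cache$tc[r, , drop = FALSE]
    o_ <- cache$go[r, , drop = FALSE]
    dc <- dc_next + dh * o_ * (1 - tch^2)
    i_ <- cache$gi[r, , drop = FALSE]; f_ <- cache$gf[r, , drop = FALSE]
    g_ <- cache$gg[r, , drop = FALSE]
    do_ <- dh * tch
    di <- dc * g_; dg <- dc * i_; df <- dc * cache$cprev[r, , drop = FALSE]
    dc_next <- dc * f_
    da <- cbind(di * i_ * (1 - i_), df * f_ * (1 - f_),
                dg * (1 - g_^2), do_ * o_ * (1 - o_))
    dA[r, ] <- da
    dWh <- dWh + crossprod(cache$hprev[r, , drop = FALSE], da)
    db <- db + colSums(da)
    dh_next <- da %*% t(Wh)
  }
  dWx <- crossprod(x, dA)
  dx <- dA %*% t(Wx)
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}

# ---- full forward pass -------------------------------------------------------

# x_arr: B x T x 4 array. Returns scores, attention, embedding, hidden states
# and (when keep_cache) everything backward() needs.
.forward <- function(params, bn_state, hp, x_arr, training = FALSE,
                     keep_cache = FALSE, dropout_mask = NULL) {
  B <- dim(x_arr)[1]; T <- dim(x_arr)[2]
  # to (B*T) x 4 time-major: element (b,t,c) of the array is already ordered
  # b-fastest, so a plain dim change gives the layout we want.
  x <- x_arr
  dim(x) <- c(B * T, 4L)
  cache <- list(B = B, T = T)
  cur <- x
  for (i in seq_len(hp$n_conv_blocks)) {
    col <- .im2col(cur, B, T, hp$W)
    Wm <- params[[paste0("conv", i, "_W")]]
    z <- col %*% Wm
    z <- sweep(z, 2L, params[[paste0("conv", i, "_b")]], "+")
    bn <- .bn_forward(z, params[[paste0("bn", i, "_gamma")]],
                      params[[paste0("bn", i, "_beta")]],
                      bn_state[[paste0("bn", i, "_mean")]],
                      bn_state[[paste0("bn", i, "_var")]],
                      training)
    bn_state[[paste0("bn", i, "_mean")]] <- bn$run_mean
    bn_state[[paste0("bn", i, "_var")]] <- bn$run_var
    act <- pmax(bn$out, 0)
    drop_m <- NULL
    if (training && hp$dropout > 0) {
      drop_m <- matrix(stats::rbinom(length(act), 1L, 1 - hp$dropout),
                       nrow(act)) / (1 - hp$dropout)
      act <- act * drop_m
    }
    if (keep_cache) {
      cache[[paste0("conv", i)]] <- list(col = col, bn = bn,
                                         relu_mask = bn$out > 0,
                                         drop_m = drop_m, c_in = ncol(cur))
    }
    cur <- act
  }
  H2 <- hp$N_h %/% 2L
  lf <- .lstm_forward(cur, params$lstm_f_Wx, params$lstm_f_Wh, params$lstm_f_b,
                      B, T, reverse = FALSE)
  lb <- .lstm_forward(cur, params$lstm_b_Wx, params$lstm_b_Wh, params$lstm_b_b,
                      B, T, reverse = TRUE)
  Hmat <- cbind(lf$h, lb$h)  # (B*T) x N_h
  U <- tanh(sweep(Hmat %*% params$attn_W1, 2L, params$attn_b1, "+"))
  s <- as.vector(U %*% params$attn_w2)          # length B*T, b-fastest
  S <- matrix(s, nrow = B)                      # B x T
  alpha <- .softmax_rows(S)
  r <- matrix(0, B, hp$N_h)
  for (t in seq_len(T)) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    r <- r + alpha[, t] * Hmat[rows, , drop = FALSE]
  }
  emb_drop_m <- NULL
  r_used <- r
  if (training && hp$dropout > 0) {
    emb_drop_m <- matrix(stats::rbinom(length(r), 1L, 1 - hp$dropout),
                         nrow(r)) / (1 - hp$dropout)
    r_used <- r * emb_drop_m
  }
  logits <- sweep(r_used %*% params$out_W, 2L, params$out_b, "+")
  probs <- .softmax_rows(logits)
  out <- list(scores = probs, attention = alpha, embedding = r,
              hidden = Hmat, bn_state = bn_state)
  if (keep_cache) {
    cache$conv_out <- cur; cache$lf <- lf; cache$lb <- lb
    cache$Hmat <- Hmat; cache$U <- U; cache$alpha <- alpha
    cache$r <- r; cache$r_used <- r_used; cache$emb_drop_m <- emb_drop_m
    cache$probs <- probs
    out$cache <- cache
  }
  out
}

# ---- full backward pass ------------------------------------------------------

# y: integer class indices 1..N_y. Returns gradient list keyed like params.
.backward <- function(params, hp, cache, y) {
  B <- cache$B; T <- cache$T
  grads <- list()
  # cross-entropy + softmax
  dlogits <- cache$probs
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  dlogits <- dlogits / B
  grads$out_W <- crossprod(cache$r_used, dlogits)
  grads$out_b <- colSums(dlogits)
  dr <- dlogits %*% t(params$out_W)
  if (!is.null(cache$emb_drop_m)) dr <- dr * cache$emb_drop_m
  # attention-weighted sum: r = sum_t alpha_t * H_t
  Hmat <- cache$Hmat; alpha <- cache$alpha
  dalpha <- matrix(0, B, T)
  dH <- matrix(0, nrow(Hmat), ncol(Hmat))
  for (t in seq_len(T)) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    Ht <- Hmat[rows, , drop = FALSE]
    dalpha[, t] <- rowSums(dr * Ht)
    dH[rows, ] <- alpha[, t] * dr
  }
  # softmax over positions
  dS <- alpha * (dalpha - rowSums(alpha * dalpha))
  ds <- as.vector(dS)  # b-fastest matches row layout
  U <- cache$U
  grads$attn_w2 <- crossprod(U, ds)
  dU <- ds %*% t(params$attn_w2)   # (B*T) x N_a via outer product
  dpre <- dU * (1 - U^2)
  grads$attn_W1 <- crossprod(Hmat, dpre)
  grads$attn_b1 <- colSums(dpre)
  dH <- dH + dpre %*% t(params$attn_W1)
  # split into the two LSTM directions
  H2 <- hp$N_h %/% 2L
  bf <- .lstm_backward(dH[, 1:H2, drop = FALSE], cache$lf, cache$conv_out,
                       params$lstm_f_Wx, params$lstm_f_Wh)
  bb <- .lstm_backward(dH[, (H2 + 1):(2 * H2), drop = FALSE], cache$lb,
                       cache$conv_out, params$lstm_b_Wx, params$lstm_b_Wh)
  grads$lstm_f_Wx <- bf$dWx; grads$lstm_f_Wh <- bf$dWh; grads$lstm_f_b <- bf$db
  grads$lstm_b_Wx <- bb$dWx; grads$lstm_b_Wh <- bb$dWh; grads$lstm_b_b <- bb$db
  dcur <- bf$dx + bb$dx
  for (i in rev(seq_len(hp$n_conv_blocks))) {
    cc <- cache[[paste0("conv", i)]]
    if (!is.null(cc$drop_m)) dcur <- dcur * cc$drop_m
    dcur <- dcur * cc$relu_mask
    bnb <- .bn_backward(dcur, cc$bn, params[[paste0("bn", i, "_gamma")]])
    grads[[paste0("bn", i, "_gamma")]] <- bnb$dgamma
    grads[[paste0("bn", i, "_beta")]] <- bnb$dbeta
    dz <- bnb$dx
    grads[[paste0("conv", i, "_W")]] <- crossprod(cc$col, dz)
    grads[[paste0("conv", i, "_b")]] <- colSums(dz)
    dcol <- dz %*% t(params[[paste0("conv", i, "_W")]])
    dcur <- .col2im(dcol, B, T, hp$W, cc$c_in)
  }
  grads
}

.loss_accuracy <- function(probs, y) {
  eps <- 1e-12
  loss <- -mean(log(pmax(probs[cbind(seq_along(y), y)], eps)))
  acc <- mean(max.col(probs, ties.method = "first") == y)
  c(loss = loss, accuracy = acc)
}

# ---- Adam --------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
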