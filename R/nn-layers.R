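# Minimal neural-network engine: 1-D convolution (im2col), transposed
# convolution, batch normalization, ReLU, max-pooling, dropout, linear
# layers and LSTM cells, each with a hand-derived backward pass, plus Adam.
# Activations are (batch, length, channels) arrays; dense activations are
# (batch, features) matrices. Everything runs on base R matrix ops so a
# single-threaded run is bitwise reproducible.

conv_out_len <- function(L, k, stride, pad = 0L) {
  (L + 2L * pad - k) %/% stride + 1L
}

# --- im2col machinery ------------------------------------------------------

im2col <- function(X, k, stride, pad) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  if (pad > 0L) {
    Xp <- array(0, c(B, L + 2L * pad, C))
    Xp[, (pad + 1L):(pad + L), ] <- X
    X <- Xp; L <- L + 2L * pad
  }
  P <- (L - k) %/% stride + 1L
  idx <- outer(seq(0L, by = stride, length.out = P), seq_len(k), `+`)  # P x k
  Xcol <- array(0, c(B, P, k, C))
  for (c in seq_len(C)) {
    Xcol[, , , c] <- array(X[, as.vector(idx), c], c(B, P, k))
  }
  dim(Xcol) <- c(B * P, k * C)
  list(Xcol = Xcol, P = P, idx = idx, B = B, C = C, Lpad = L)
}

col2im <- function(dXcol, info, k, stride, pad, L) {
  B <- info$B; P <- info$P; C <- info$C
  dim(dXcol) <- c(B, P, k, C)
  dXp <- array(0, c(B, info$Lpad, C))
  for (j in seq_len(k)) {
    pos <- seq(j, by = stride, length.out = P)
    dXp[, pos, ] <- dXp[, pos, ] + dXcol[, , j, ]
  }
  if (pad > 0L) dXp[, (pad + 1L):(pad + L), , drop = FALSE] else dXp
}

conv1d_fwd <- function(X, W, b, stride, pad = 0L) {
  k <- nrow(W) / dim(X)[3]
  info <- im2col(X, k, stride, pad)
  Y <- info$Xcol %*% W
  Y <- sweep(Y, 2L, b, `+`)
  dim(Y) <- c(dim(X)[1], info$P, ncol(W))
  list(out = Y, cache = list(info = info, W = W, k = k, stride = stride,
                             pad = pad, L = dim(X)[2]))
}

conv1d_bwd <- function(cache, dY) {
  d <- dim(dY)
  dYm <- dY; dim(dYm) <- c(d[1] * d[2], d[3])
  dW <- crossprod(cache$info$Xcol, dYm)
  db <- colSums(dYm)
  dXcol <- dYm %*% t(cache$W)
  dX <- col2im(dXcol, cache$info, cache$k, cache$stride, cache$pad, cache$L)
  list(dX = dX, dW = dW, db = db)
}

# Transposed convolution: (B, Lin, Cin) -> (B, (Lin-1)*stride + k, Cout).
# W is an array (k, Cin, Cout).
deconv1d_fwd <- function(X, W, b, stride) {
  d <- dim(X); B <- d[1]; Lin <- d[2]; Cin <- d[3]
  k <- dim(W)[1]; Cout <- dim(W)[3]
  Lout <- (Lin - 1L) * stride + k
  Xm <- X; dim(Xm) <- c(B * Lin, Cin)
  Y <- array(0, c(B, Lout, Cout))
  for (j in seq_len(k)) {
    Yj <- Xm %*% W[j, , ]            # (B*Lin, Cout)
    dim(Yj) <- c(B, Lin, Cout)
    pos <- seq(j, by = stride, length.out = Lin)
    Y[, pos, ] <- Y[, pos, , drop = FALSE] + Yj
  }
  Y <- sweep(Y, 3L, b, `+`)
  list(out = Y, cache = list(Xm = Xm, W = W, B = B, Lin = Lin, Cin = Cin,
                             stride = stride, k = k))
}

deconv1d_bwd <- function(cache, dY) {
  k <- cache$k; stride <- cache$stride
  B <- cache$B; Lin <- cache$Lin; Cin <- cache$Cin
  Cout <- dim(cache$W)[3]
  dW <- array(0, dim(cache$W))
  dXm <- matrix(0, B * Lin, Cin)
  db <- colSums(dY, dims = 2L)
  for (j in seq_len(k)) {
    pos <- seq(j, by = stride, length.out = Lin)
    dYj <- dY[, pos, , drop = FALSE]
    dim(dYj) <- c(B * Lin, Cout)
    dW[j, , ] <- crossprod(cache$Xm, dYj)
    dXm <- dXm + dYj %*% t(cache$W[j, , ])
  }
  dX <- dXm; dim(dX) <- c(B, Lin, Cin)
  list(dX = dX, dW = dW, db = db)
}

# --- batch normalization (per channel, over batch x positions) -------------

bn_fwd <- function(X, gamma, beta, run_mean, run_var, train,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(X)
  Xm <- X; dim(Xm) <- c(prod(d[-length(d)]), d[length(d)])
  if (train) {
    mu <- colMeans(Xm)
    xc <- sweep(Xm, 2L, mu, `-`)
    v <- colMeans(xc^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
    xc <- sweep(Xm, 2L, mu, `-`)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, invstd, `*`)
  Y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  dim(Y) <- d
  list(out = Y, run_mean = run_mean, run_var = run_var,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d,
                    train = train))
}

bn_bwd <- function(cache, dY) {
  d <- cache$d
  dYm <- dY; dim(dYm) <- c(prod(d[-length(d)]), d[length(d)])
  N <- nrow(dYm)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  if (cache$train) {
    dxhat <- sweep(dYm, 2L, cache$gamma, `*`)
    t1 <- sweep(dxhat, 2L, colMeans(dxhat), `-`)
    t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), `*`)
    dXm <- sweep(t1 - t2, 2L, cache$invstd, `*`)
  } else {
    dXm <- sweep(sweep(dYm, 2L, cache$gamma, `*`), 2L, cache$invstd, `*`)
  }
  dim(dXm) <- d
  list(dX = dXm, dgamma = dgamma, dbeta = dbeta)
}

# --- elementwise / pooling -------------------------------------------------

relu_fwd <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_bwd <- function(cache, dY) dY * cache

dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, cache = NULL))
  mask <- array(stats::runif(length(X)) >= p, dim(X)) / (1 - p)
  list(out = X * mask, cache = mask)
}
dropout_bwd <- function(cache, dY) if (is.null(cache)) dY else dY * cache

maxpool1d_fwd <- function(X, size, stride) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  P <- (L - size) %/% stride + 1L
  idx <- outer(seq(0L, by = stride, length.out = P), seq_len(size), `+`)
  Xcol <- array(0, c(B, P, size, C))
  for (c in seq_len(C)) {
    Xcol[, , , c] <- array(X[, as.vector(idx), c], c(B, P, size))
  }
  M <- aperm(Xcol, c(1, 2, 4, 3))      # B, P, C, size
  dim(M) <- c(B * P * C, size)
  amax <- max.col(M, ties.method = "first")
  Y <- M[cbind(seq_len(nrow(M)), amax)]
  dim(Y) <- c(B, P, C)
  list(out = Y, cache = list(amax = amax, idx = idx, B = B, P = P, C = C,
                             L = L, size = size, stride = stride))
}

maxpool1d_bwd <- function(cache, dY) {
  B <- cache$B; P <- cache$P; C <- cache$C
  dX <- array(0, c(B, cache$L, C))
  dYv <- as.vector(dY)                 # ordered (B, P, C)
  # linear index into (B, L, C): row b, pos idx[p, amax], channel c
  ib <- rep(seq_len(B), times = P * C)
  ip <- rep(rep(seq_len(P), each = B), times = C)
  ic <- rep(seq_len(C), each = B * P)
  pos <- cache$idx[cbind(ip, cache$amax)]
  lin <- ib + (pos - 1L) * B + (ic - 1L) * B * cache$L
  # accumulate (duplicates possible when windows overlap)
  acc <- rowsum(dYv, lin)
  dX[as.integer(rownames(acc))] <- acc[, 1L]
  dX
}

# --- dense -----------------------------------------------------------------

linear_fwd <- function(X, W, b) {
  list(out = sweep(X %*% W, 2L, b, `+`), cache = list(X = X, W = W))
}
linear_bwd <- function(cache, dY) {
  list(dX = dY %*% t(cache$W), dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# mean cross-entropy over rows + gradient wrt logits
softmax_ce <- function(logits, label_idx1) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  p_true <- pmax(P[cbind(seq_len(n), label_idx1)], 1e-12)
  dZ <- P
  dZ[cbind(seq_len(n), label_idx1)] <- dZ[cbind(seq_len(n), label_idx1)] - 1
  list(loss = -mean(log(p_true)), probs = P, dlogits = dZ / n)
}

# --- LSTM ------------------------------------------------------------------

# X: (B, T, D); W: (D+H, 4H) gates ordered i, f, g, o; b: (4H).
lstm_fwd <- function(X, W, b) {
  d <- dim(X); B <- d[1]; Tn <- d[2]; D <- d[3]
  H <- length(b) / 4L
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  Hs <- array(0, c(B, Tn, H))
  caches <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(B, D)
    z <- cbind(xt, h) %*% W
    z <- sweep(z, 2L, b, `+`)
    i <- 1 / (1 + exp(-z[, 1:H, drop = FALSE]))
    f <- 1 / (1 + exp(-z[, (H + 1):(2 * H), drop = FALSE]))
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- 1 / (1 + exp(-z[, (3 * H + 1):(4 * H), drop = FALSE]))
    c_new <- f * cst + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    caches[[t]] <- list(xt = xt, h_prev = h, c_prev = cst, i = i, f = f,
                        g = g, o = o, c_new = c_new, tc = tc)
    h <- h_new; cst <- c_new
    Hs[, t, ] <- h
  }
  list(out = Hs, cache = list(caches = caches, W = W, B = B, Tn = Tn,
                              D = D, H = H))
}

lstm_bwd <- function(cache, dHs) {
  W <- cache$W; B <- cache$B; Tn <- cache$Tn; D <- cache$D; H <- cache$H
  dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(4L * H)
  dX <- array(0, c(B, Tn, D))
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    cc <- cache$caches[[t]]
    dh <- dHs[, t, , drop = FALSE]; dim(dh) <- c(B, H)
    dh <- dh + dh_next
    do <- dh * cc$tc * cc$o * (1 - cc$o)
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g * cc$i * (1 - cc$i)
    df <- dc * cc$c_prev * cc$f * (1 - cc$f)
    dg <- dc * cc$i * (1 - cc$g^2)
    dz <- cbind(di, df, dg, do)
    inp <- cbind(cc$xt, cc$h_prev)
    dW <- dW + crossprod(inp, dz)
    db <- db + colSums(dz)
    dinp <- dz %*% t(W)
    dX[, t, ] <- dinp[, seq_len(D), drop = FALSE]
    dh_next <- dinp[, (D + 1L):(D + H), drop = FALSE]
    dc_next <- dc * cc$f
  }
  list(dX = dX, dW = dW, db = db)
}

# Bidirectional LSTM: concatenated forward/backward hidden states (B, T, 2H).
bilstm_fwd <- function(X, Wf, bf, Wb, bb) {
  fwd <- lstm_fwd(X, Wf, bf)
  Xr <- X[, rev(seq_len(dim(X)[2])), , drop = FALSE]
  bwd <- lstm_fwd(Xr, Wb, bb)
  Hb <- bwd$out[, rev(seq_len(dim(X)[2])), , drop = FALSE]
  d <- dim(fwd$out)
  out <- array(0, c(d[1], d[2], 2L * d[3]))
  out[, , seq_len(d[3])] <- fwd$out
  out[, , (d[3] + 1L):(2L * d[3])] <- Hb
  list(out = out, cache = list(fwd = fwd$cache, bwd = bwd$cache, H = d[3]))
}

bilstm_bwd <- function(cache, dOut) {
  H <- cache$H; Tn <- dim(dOut)[2]
  dF <- dOut[, , seq_len(H), drop = FALSE]
  dB <- dOut[, , (H + 1L):(2L * H), drop = FALSE]
  gf <- lstm_bwd(cache$fwd, dF)
  gb <- lstm_bwd(cache$bwd, dB[, rev(seq_len(Tn)), , drop = FALSE])
  dX <- gf$dX + gb$dX[, rev(seq_len(Tn)), , drop = FALSE]
  list(dX = dX, dWf = gf$dW, dbf = gf$db, dWb = gb$dW, dbb = gb$db)
}

# --- initialization --------------------------------------------------------

he_init <- function(nr, nc, fan_in = nr) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

lstm_init <- function(D, H) {
  W <- matrix(stats::rnorm((D + H) * 4L * H, sd = 1 / sqrt(D + H)),
              D + H, 4L * H)
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1     # forget-gate bias 1.0
  list(W = W, b = b)
}

# --- Adam optimizer (L2 weight decay added to the gradient) ----------------

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "list", classes = "ANY")
}

# params/grads/state are parallel nested lists of numeric arrays.
adam_step <- function(params, grads, state, lr, t, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  is_leaf_state <- function(s) {
    is.list(s) && length(s) == 2L && all(c("m", "v") %in% names(s))
  }
  walk <- function(p, g, s) {
    if (is.null(p)) return(list(p = p, s = s))
    if (is.list(p) && !is_leaf_state(s)) {
      for (k in seq_along(p)) {
        gk <- if (is.null(g) || length(g) < k) NULL else g[[k]]
        r <- walk(p[[k]], gk, s[[k]])
        p[k] <- list(r$p); s[k] <- list(r$s)
      }
      return(list(p = p, s = s))
    }
    if (is.null(g)) return(list(p = p, s = s))
    g <- g + weight_decay * p
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  walk(params, grads, state)
}
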