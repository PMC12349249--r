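# Low-level neural-network primitives with explicit forward/backward passes.
#
# Batched sequences are stored as 3D arrays [T, B, C] (time, batch, channel);
# column-major order makes the reshape [T, B, C] -> [(T*B), C] free, so every
# layer reduces to BLAS matrix products. All gradients here are verified
# against finite differences in the test suite.

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Leaky rectified linear activation
#'
#' `f(x) = max(a * x, x)` elementwise, with slope `a < 1` on the negative
#' side so gradients never vanish completely.
#'
#' @param x numeric vector, matrix or array.
#' @param a negative-side slope (default 0.01).
#' @return same shape as `x`.
#' @export
leaky_relu <- function(x, a = 0.01) {
  y <- x
  neg <- x < 0
  y[neg] <- a * x[neg]
  y
}

.lrelu_bwd <- function(dy, x, a) {
  dx <- dy
  neg <- x < 0
  dx[neg] <- a * dy[neg]
  dx
}

# ---- 1-D convolution along time --------------------------------------------

# W: [k, Cin, Cout], b: [Cout]; x: [T, B, Cin]
conv1d_fwd <- function(x, W, b, stride = 1L, pad = 0L) {
  d <- dim(x); Tn <- d[1]; B <- d[2]; Cin <- d[3]
  k <- dim(W)[1]; Cout <- dim(W)[3]
  if (pad > 0L) {
    xp <- array(0, c(Tn + 2L * pad, B, Cin))
    xp[(pad + 1L):(pad + Tn), , ] <- x
  } else xp <- x
  Tp <- dim(xp)[1]
  T_out <- (Tp - k) %/% stride + 1L
  if (T_out < 1L) stop("conv1d: kernel longer than (padded) input")
  acc <- matrix(0, T_out * B, Cout)
  for (j in seq_len(k)) {
    rows <- seq.int(j, by = stride, length.out = T_out)
    S <- xp[rows, , , drop = FALSE]
    dim(S) <- c(T_out * B, Cin)
    acc <- acc + S %*% matrix(W[j, , ], Cin, Cout)
  }
  acc <- acc + rep(b, each = T_out * B)
  dim(acc) <- c(T_out, B, Cout)
  list(y = acc,
       cache = list(xp = xp, k = k, stride = stride, pad = pad,
                    Tn = Tn, B = B, Cin = Cin, Cout = Cout, T_out = T_out))
}

conv1d_bwd <- function(dy, cache, W) {
  c_ <- cache
  dy_mat <- dy; dim(dy_mat) <- c(c_$T_out * c_$B, c_$Cout)
  db <- colSums(dy_mat)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(c_$xp))
  for (j in seq_len(c_$k)) {
    rows <- seq.int(j, by = c_$stride, length.out = c_$T_out)
    S <- c_$xp[rows, , , drop = FALSE]
    dim(S) <- c(c_$T_out * c_$B, c_$Cin)
    dW[j, , ] <- crossprod(S, dy_mat)
    dS <- dy_mat %*% t(matrix(W[j, , ], c_$Cin, c_$Cout))
    dim(dS) <- c(c_$T_out, c_$B, c_$Cin)
    dxp[rows, , ] <- dxp[rows, , , drop = FALSE] + dS
  }
  dx <- if (c_$pad > 0L)
    dxp[(c_$pad + 1L):(c_$pad + c_$Tn), , , drop = FALSE]
  else dxp
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalisation over (time x batch) per channel -------------------

bn_fwd <- function(x, gamma, beta, state, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); N <- d[1] * d[2]; C <- d[3]
  xm <- x; dim(xm) <- c(N, C)
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    # unbiased variance in the running estimate, batch variance in the pass
    state$var <- (1 - momentum) * state$var + momentum * v * N / max(1, N - 1)
  } else {
    mu <- state$mean; v <- state$var
    xc <- sweep(xm, 2L, mu)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, invstd, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  dim(y) <- d
  list(y = y, state = state,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                    d = d, train = train))
}

bn_bwd <- function(dy, cache) {
  c_ <- cache; d <- c_$d; N <- d[1] * d[2]
  dym <- dy; dim(dym) <- c(N, d[3])
  dgamma <- colSums(dym * c_$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, c_$gamma, "*")
  if (c_$train) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * c_$xhat)
    dxm <- sweep(dxhat, 2L, s1 / N) - sweep(c_$xhat, 2L, s2 / N, "*")
    dxm <- sweep(dxm, 2L, c_$invstd, "*")
  } else {
    dxm <- sweep(dxhat, 2L, c_$invstd, "*")
  }
  dim(dxm) <- d
  list(dx = dxm, dgamma = dgamma, dbeta = dbeta)
}

# ---- temporal average pooling ----------------------------------------------

pool_fwd <- function(x, width = 3L, stride = 3L) {
  d <- dim(x)
  T_out <- (d[1] - width) %/% stride + 1L
  acc <- array(0, c(T_out, d[2], d[3]))
  for (j in seq_len(width)) {
    rows <- seq.int(j, by = stride, length.out = T_out)
    acc <- acc + x[rows, , , drop = FALSE]
  }
  list(y = acc / width,
       cache = list(width = width, stride = stride, d = d, T_out = T_out))
}

pool_bwd <- function(dy, cache) {
  c_ <- cache
  dx <- array(0, c_$d)
  g <- dy / c_$width
  for (j in seq_len(c_$width)) {
    rows <- seq.int(j, by = c_$stride, length.out = c_$T_out)
    dx[rows, , ] <- dx[rows, , , drop = FALSE] + g
  }
  dx
}

# ---- squeeze-and-excitation block ------------------------------------------

init_se_params <- function(C, ratio) {
  Cr <- max(1L, as.integer(ceiling(C / ratio)))
  list(W1 = matrix(stats::rnorm(C * Cr, sd = sqrt(2 / C)), C, Cr),
       b1 = numeric(Cr),
       W2 = matrix(stats::rnorm(Cr * C, sd = sqrt(2 / Cr)), Cr, C),
       b2 = numeric(C))
}

se_fwd <- function(x, p) {
  d <- dim(x); T_ <- d[1]; B <- d[2]; C <- d[3]
  xm <- x; dim(xm) <- c(T_, B * C)
  z <- colMeans(xm); dim(z) <- c(B, C)            # squeeze: mean over time
  a1 <- sweep(z %*% p$W1, 2L, p$b1, "+")
  h1 <- pmax(a1, 0)
  a2 <- sweep(h1 %*% p$W2, 2L, p$b2, "+")
  s <- .sigmoid(a2)                               # excitation weights in (0,1)
  y <- x * rep(s, each = T_)                      # scale
  list(y = y, weights = s,
       cache = list(x = x, z = z, a1 = a1, h1 = h1, s = s, d = d))
}

se_bwd <- function(dy, cache, p) {
  c_ <- cache; d <- c_$d; T_ <- d[1]; B <- d[2]; C <- d[3]
  u <- dy * c_$x
  dim(u) <- c(T_, B * C)
  ds <- colSums(u); dim(ds) <- c(B, C)
  da2 <- ds * c_$s * (1 - c_$s)
  dW2 <- crossprod(c_$h1, da2); db2 <- colSums(da2)
  dh1 <- da2 %*% t(p$W2)
  da1 <- dh1 * (c_$a1 > 0)
  dW1 <- crossprod(c_$z, da1); db1 <- colSums(da1)
  dz <- da1 %*% t(p$W1)
  dx <- dy * rep(c_$s, each = T_) + rep(dz / T_, each = T_)
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# ---- fully connected --------------------------------------------------------

dense_fwd <- function(x, W, b) {
  list(y = sweep(x %*% W, 2L, b, "+"), cache = list(x = x))
}

dense_bwd <- function(dy, cache, W) {
  list(dx = dy %*% t(W), dW = crossprod(cache$x, dy), db = colSums(dy))
}

# ---- dropout (inverted) -----------------------------------------------------

dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, cache = NULL))
  mask <- (array(stats::runif(length(x)), dim = dim(x) %||% length(x)) >= p) / (1 - p)
  list(y = x * mask, cache = mask)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- gated recurrent unit ---------------------------------------------------

init_gru_params <- function(D, H) {
  wi <- function() matrix(stats::rnorm(D * H, sd = 1 / sqrt(D)), D, H)
  wh <- function() matrix(stats::rnorm(H * H, sd = 1 / sqrt(H)), H, H)
  list(Wr = wi(), Wz = wi(), Wh = wi(),
       Ur = wh(), Uz = wh(), Uh = wh(),
       br = numeric(H), bz = numeric(H), bh = numeric(H))
}

# One direction. x: [T, B, D]; h0: [B, H] (zeros by default). Gates:
#   r_t = sigmoid(W_r x_t + U_r h_{t-1} + b_r)
#   z_t = sigmoid(W_z x_t + U_z h_{t-1} + b_z)
#   h'_t = tanh(W_h x_t + U_h (r_t * h_{t-1}) + b_h)
#   h_t = z_t * h_{t-1} + (1 - z_t) * h'_t
gru_fwd <- function(x, p, h0 = NULL) {
  d <- dim(x); T_ <- d[1]; B <- d[2]; D <- d[3]
  H <- length(p$br)
  xm <- x; dim(xm) <- c(T_ * B, D)
  Xr <- xm %*% p$Wr; Xz <- xm %*% p$Wz; Xh <- xm %*% p$Wh
  dim(Xr) <- dim(Xz) <- dim(Xh) <- c(T_, B, H)
  h <- if (is.null(h0)) matrix(0, B, H) else h0
  Hs <- array(0, c(T_, B, H))
  steps <- vector("list", T_)
  for (t in seq_len(T_)) {
    h_prev <- h
    r <- .sigmoid(sweep(matrix(Xr[t, , ], B, H) + h_prev %*% p$Ur, 2L, p$br, "+"))
    z <- .sigmoid(sweep(matrix(Xz[t, , ], B, H) + h_prev %*% p$Uz, 2L, p$bz, "+"))
    hp <- tanh(sweep(matrix(Xh[t, , ], B, H) + (r * h_prev) %*% p$Uh, 2L, p$bh, "+"))
    h <- z * h_prev + (1 - z) * hp
    Hs[t, , ] <- h
    steps[[t]] <- list(r = r, z = z, hp = hp, h_prev = h_prev)
  }
  list(h_all = Hs, h_last = h,
       cache = list(x = x, steps = steps, d = d, H = H))
}

# dh_all: [T, B, H] upstream gradient on every hidden state (may be zeros);
# dh_last: extra gradient on the final state.
gru_bwd <- function(dh_all, dh_last, cache, p) {
  c_ <- cache; d <- c_$d; T_ <- d[1]; B <- d[2]; D <- d[3]; H <- c_$H
  g <- lapply(p, function(w) array(0, dim(w) %||% length(w)))
  xm <- c_$x; dim(xm) <- c(T_ * B, D)
  dx <- array(0, c(T_, B, D))
  dh <- if (is.null(dh_last)) matrix(0, B, H) else dh_last
  for (t in rev(seq_len(T_))) {
    st <- c_$steps[[t]]
    if (!is.null(dh_all)) dh <- dh + matrix(dh_all[t, , ], B, H)
    r <- st$r; z <- st$z; hp <- st$hp; h_prev <- st$h_prev
    dz <- dh * (h_prev - hp)
    dhp <- dh * (1 - z)
    dh_prev <- dh * z
    da_h <- dhp * (1 - hp^2)
    x_t <- matrix(c_$x[t, , ], B, D)
    g$Wh <- g$Wh + crossprod(x_t, da_h)
    g$Uh <- g$Uh + crossprod(r * h_prev, da_h)
    g$bh <- g$bh + colSums(da_h)
    drh <- da_h %*% t(p$Uh)
    dr <- drh * h_prev
    dh_prev <- dh_prev + drh * r
    da_r <- dr * r * (1 - r)
    g$Wr <- g$Wr + crossprod(x_t, da_r)
    g$Ur <- g$Ur + crossprod(h_prev, da_r)
    g$br <- g$br + colSums(da_r)
    dh_prev <- dh_prev + da_r %*% t(p$Ur)
    da_z <- dz * z * (1 - z)
    g$Wz <- g$Wz + crossprod(x_t, da_z)
    g$Uz <- g$Uz + crossprod(h_prev, da_z)
    g$bz <- g$bz + colSums(da_z)
    dh_prev <- dh_prev + da_z %*% t(p$Uz)
    dx_t <- da_h %*% t(p$Wh) + da_r %*% t(p$Wr) + da_z %*% t(p$Wz)
    dx[t, , ] <- dx_t
    dh <- dh_prev
  }
  list(dx = dx, grads = g, dh0 = dh)
}

# Bidirectional wrapper: independent parameter sets per direction; the
# backward direction reads the sequence reversed in time. h_all concatenates
# the two directions along the channel axis (forward first).
bigru_fwd <- function(x, p) {
  f <- gru_fwd(x, p$fwd)
  xr <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  b <- gru_fwd(xr, p$bwd)
  T_ <- dim(x)[1]
  h_all <- array(0, c(T_, dim(x)[2], 2L * f$cache$H))
  h_all[, , seq_len(f$cache$H)] <- f$h_all
  h_all[, , f$cache$H + seq_len(f$cache$H)] <-
    b$h_all[rev(seq_len(T_)), , , drop = FALSE]
  list(h_all = h_all, h_last = cbind(f$h_last, b$h_last),
       cache = list(f = f$cache, b = b$cache, H = f$cache$H))
}

# dh_last: [B, 2H] gradient on the concatenated final states (forward h_T,
# backward h_T). Full-sequence upstream gradients are not needed by the
# relation head, which consumes only the final states.
bigru_bwd <- function(dh_last, cache, p) {
  H <- cache$H
  bf <- gru_bwd(NULL, dh_last[, seq_len(H), drop = FALSE], cache$f, p$fwd)
  bb <- gru_bwd(NULL, dh_last[, H + seq_len(H), drop = FALSE], cache$b, p$bwd)
  dx <- bf$dx + bb$dx[rev(seq_len(dim(bb$dx)[1])), , , drop = FALSE]
  list(dx = dx, grads = list(fwd = bf$grads, bwd = bb$grads))
}

# ---- parameter-tree utilities and Adam -------------------------------------

param_map <- function(p, f) {
  if (is.list(p)) lapply(p, param_map, f = f) else f(p)
}

param_map2 <- function(p, q, f) {
  if (is.list(p)) {
    out <- vector("list", length(p)); names(out) <- names(p)
    nm <- names(p)
    by_name <- !is.null(nm) && !is.null(names(q)) && all(nzchar(nm))
    for (i in seq_along(p)) {
      qi <- if (by_name) q[[nm[i]]] else q[[i]]
      out[[i]] <- param_map2(p[[i]], qi, f)
    }
    out
  } else f(p, q)
}

zeros_like <- function(p) param_map(p, function(w) {
  z <- w; z[] <- 0; z
})

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- param_map2(state$m, state$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- param_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

init_conv_params <- function(k, Cin, Cout) {
  list(W = array(stats::rnorm(k * Cin * Cout, sd = sqrt(2 / (k * Cin))),
                 c(k, Cin, Cout)),
       b = numeric(Cout))
}

init_bn_params <- function(C) list(gamma = rep(1, C), beta = numeric(C))
init_bn_state <- function(C) list(mean = numeric(C), var = rep(1, C))
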