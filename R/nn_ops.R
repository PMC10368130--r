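# Neural-network layer primitives with hand-derived backward passes.
#
# Feature tensors of shape (T frames x N nodes x C channels) are stored as
# (T*N) x C matrices with row index (t-1)*N + n; the sequence head uses the
# same code with N = 1.  Every backward implementation is verified against
# central finite differences in the test suite.

.nn_rand <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(1 / max(fan_in, 1))), nr, nc)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- temporal convolution (zero 'same' padding along T) -------------------

tconv_init <- function(kernel, c_in, c_out) {
  list(W = array(stats::rnorm(kernel * c_in * c_out,
                              sd = sqrt(1 / (kernel * c_in))),
                 dim = c(kernel, c_in, c_out)),
       b = numeric(c_out))
}

tconv_fwd <- function(X, T_, N, par) {
  K <- dim(par$W)[1]; c_out <- dim(par$W)[3]
  h <- (K - 1) / 2
  Y <- matrix(rep(par$b, each = T_ * N), T_ * N, c_out)
  for (k in seq_len(K)) {
    o <- k - 1 - h                      # frame offset
    t_dst <- max(1, 1 - o):min(T_, T_ - o)
    rows_dst <- rep((t_dst - 1) * N, each = N) + seq_len(N)
    rows_src <- rep((t_dst + o - 1) * N, each = N) + seq_len(N)
    Y[rows_dst, ] <- Y[rows_dst, ] + X[rows_src, , drop = FALSE] %*% par$W[k, , ]
  }
  list(out = Y, X = X, T_ = T_, N = N, par = par)
}

tconv_bwd <- function(cache, dY) {
  par <- cache$par; X <- cache$X; T_ <- cache$T_; N <- cache$N
  K <- dim(par$W)[1]
  h <- (K - 1) / 2
  dX <- matrix(0, nrow(X), ncol(X))
  dW <- array(0, dim = dim(par$W))
  for (k in seq_len(K)) {
    o <- k - 1 - h
    t_dst <- max(1, 1 - o):min(T_, T_ - o)
    rows_dst <- rep((t_dst - 1) * N, each = N) + seq_len(N)
    rows_src <- rep((t_dst + o - 1) * N, each = N) + seq_len(N)
    dW[k, , ] <- crossprod(X[rows_src, , drop = FALSE], dY[rows_dst, , drop = FALSE])
    dX[rows_src, ] <- dX[rows_src, ] + dY[rows_dst, , drop = FALSE] %*% t(par$W[k, , ])
  }
  list(dX = dX, grads = list(W = dW, b = colSums(dY)))
}

# ---- (Conv)LSTM over a sequence of node-feature matrices ------------------
# Gates use dense channel maps applied per node (1x1 convolution):
#   i_t = sigmoid(Q_t Wi + h_{t-1} Ui + bi)   (same for f, o; g uses tanh)
#   c_t = f_t * c_{t-1} + i_t * g_t ;  h_t = o_t * tanh(c_t)

lstm_init <- function(c_in, c_h) {
  gates <- c("i", "f", "o", "c")
  par <- list()
  for (g in gates) {
    par[[paste0("W", g)]] <- .nn_rand(c_in, c_h, c_in)
    par[[paste0("U", g)]] <- .nn_rand(c_h, c_h, c_h)
    par[[paste0("b", g)]] <- numeric(c_h)
  }
  par
}

lstm_fwd <- function(Q, T_, N, par) {
  c_h <- ncol(par$Wi)
  H <- matrix(0, T_ * N, c_h)
  cache <- vector("list", T_)
  h_prev <- matrix(0, N, c_h); c_prev <- h_prev
  for (t in seq_len(T_)) {
    rows <- ((t - 1) * N + 1):(t * N)
    Qt <- Q[rows, , drop = FALSE]
    i <- .sigmoid(Qt %*% par$Wi + h_prev %*% par$Ui +
                    matrix(par$bi, N, c_h, byrow = TRUE))
    f <- .sigmoid(Qt %*% par$Wf + h_prev %*% par$Uf +
                    matrix(par$bf, N, c_h, byrow = TRUE))
    o <- .sigmoid(Qt %*% par$Wo + h_prev %*% par$Uo +
                    matrix(par$bo, N, c_h, byrow = TRUE))
    g <- tanh(Qt %*% par$Wc + h_prev %*% par$Uc +
                matrix(par$bc, N, c_h, byrow = TRUE))
    c_t <- f * c_prev + i * g
    tc <- tanh(c_t)
    h_t <- o * tc
    H[rows, ] <- h_t
    cache[[t]] <- list(i = i, f = f, o = o, g = g, c = c_t, tc = tc,
                       h_prev = h_prev, c_prev = c_prev, Qt = Qt)
    h_prev <- h_t; c_prev <- c_t
  }
  list(out = H, cache = cache, T_ = T_, N = N, par = par)
}

lstm_bwd <- function(fw, dH) {
  par <- fw$par; T_ <- fw$T_; N <- fw$N
  c_h <- ncol(par$Wi); c_in <- nrow(par$Wi)
  g0 <- function(nr, nc) matrix(0, nr, nc)
  grads <- list(Wi = g0(c_in, c_h), Ui = g0(c_h, c_h), bi = numeric(c_h),
                Wf = g0(c_in, c_h), Uf = g0(c_h, c_h), bf = numeric(c_h),
                Wo = g0(c_in, c_h), Uo = g0(c_h, c_h), bo = numeric(c_h),
                Wc = g0(c_in, c_h), Uc = g0(c_h, c_h), bc = numeric(c_h))
  dQ <- matrix(0, T_ * N, c_in)
  dh_next <- g0(N, c_h); dc_next <- g0(N, c_h)
  for (t in seq(T_, 1)) {
    s <- fw$cache[[t]]
    rows <- ((t - 1) * N + 1):(t * N)
    dh <- dH[rows, , drop = FALSE] + dh_next
    do_ <- dh * s$tc
    dc <- dh * s$o * (1 - s$tc^2) + dc_next
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dai <- di * s$i * (1 - s$i)
    daf <- df * s$f * (1 - s$f)
    dao <- do_ * s$o * (1 - s$o)
    dag <- dg * (1 - s$g^2)
    grads$Wi <- grads$Wi + crossprod(s$Qt, dai)
    grads$Wf <- grads$Wf + crossprod(s$Qt, daf)
    grads$Wo <- grads$Wo + crossprod(s$Qt, dao)
    grads$Wc <- grads$Wc + crossprod(s$Qt, dag)
    grads$Ui <- grads$Ui + crossprod(s$h_prev, dai)
    grads$Uf <- grads$Uf + crossprod(s$h_prev, daf)
    grads$Uo <- grads$Uo + crossprod(s$h_prev, dao)
    grads$Uc <- grads$Uc + crossprod(s$h_prev, dag)
    grads$bi <- grads$bi + colSums(dai)
    grads$bf <- grads$bf + colSums(daf)
    grads$bo <- grads$bo + colSums(dao)
    grads$bc <- grads$bc + colSums(dag)
    dQ[rows, ] <- dai %*% t(par$Wi) + daf %*% t(par$Wf) +
      dao %*% t(par$Wo) + dag %*% t(par$Wc)
    dh_next <- dai %*% t(par$Ui) + daf %*% t(par$Uf) +
      dao %*% t(par$Uo) + dag %*% t(par$Uc)
    dc_next <- dc * s$f
  }
  list(dQ = dQ, grads = grads)
}

# ---- attention map from ConvLSTM hidden state -----------------------------
# S_raw_t = tanh(H_t P) in (-1, 1); the attention map applied in the graph
# convolution is S = 1 + S_raw (neutral value 1).

attnmap_fwd <- function(H, P) {
  S_raw <- tanh(H %*% P)
  list(out = 1 + S_raw, S_raw = S_raw, H = H, P = P)
}

attnmap_bwd <- function(cache, dS) {
  dpre <- dS * (1 - cache$S_raw^2)
  list(dH = dpre %*% t(cache$P), dP = crossprod(cache$H, dpre))
}

# ---- attention-modulated graph convolution --------------------------------
# One partition: pre_t = (Amask * S_t) (Z_t W) where Amask is the fixed
# degree-normalized partition adjacency D^{-1/2} (A_k + I) D^{-1/2}; the
# elementwise product with the time-varying attention map S_t modulates the
# graph operator.  Activation (ReLU) and the sum over partitions are applied
# by the caller.

gcn_norm_adjacency <- function(A_k) {
  Ahat <- A_k + diag(nrow(A_k))
  d <- rowSums(Ahat)
  Ahat * outer(1 / sqrt(d), 1 / sqrt(d))
}

attn_gcn_fwd <- function(Z, S, T_, N, Amask, W) {
  Y <- Z %*% W
  pre <- matrix(0, T_ * N, ncol(W))
  for (t in seq_len(T_)) {
    rows <- ((t - 1) * N + 1):(t * N)
    pre[rows, ] <- (Amask * S[rows, , drop = FALSE]) %*% Y[rows, , drop = FALSE]
  }
  list(out = pre, Y = Y, Z = Z, S = S, T_ = T_, N = N, Amask = Amask, W = W)
}

attn_gcn_bwd <- function(cache, dpre) {
  T_ <- cache$T_; N <- cache$N
  dY <- matrix(0, nrow(cache$Y), ncol(cache$Y))
  dS <- matrix(0, nrow(cache$S), ncol(cache$S))
  for (t in seq_len(T_)) {
    rows <- ((t - 1) * N + 1):(t * N)
    M <- cache$Amask * cache$S[rows, , drop = FALSE]
    dYt <- crossprod(M, dpre[rows, , drop = FALSE])
    dY[rows, ] <- dYt
    dM <- tcrossprod(dpre[rows, , drop = FALSE], cache$Y[rows, , drop = FALSE])
    dS[rows, ] <- dM * cache$Amask
  }
  list(dZ = dY %*% t(cache$W), dS = dS,
       dW = crossprod(cache$Z, dY))
}

# ---- misc ------------------------------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_bwd <- function(cache, dy) dy * cache$mask

node_pool_fwd <- function(X, T_, N) {
  # mean over nodes -> T x C
  out <- matrix(0, T_, ncol(X))
  for (t in seq_len(T_))
    out[t, ] <- colMeans(X[((t - 1) * N + 1):(t * N), , drop = FALSE])
  out
}

node_pool_bwd <- function(dout, T_, N) {
  dX <- matrix(0, T_ * N, ncol(dout))
  for (t in seq_len(T_))
    dX[((t - 1) * N + 1):(t * N), ] <-
      matrix(dout[t, ] / N, N, ncol(dout), byrow = TRUE)
  dX
}

dense_fwd <- function(x, W, b) {
  list(out = x %*% W + matrix(b, nrow(x), length(b), byrow = TRUE), x = x,
       W = W)
}

dense_bwd <- function(cache, dy) {
  list(dx = dy %*% t(cache$W), dW = crossprod(cache$x, dy), db = colSums(dy))
}
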