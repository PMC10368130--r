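# Attention-extended spatial-temporal graph convolutional network for
# continuous movement-quality score regression.
#
# Architecture: temporal feature lift (channel concatenation of the raw
# sequence with its temporal convolution), three STGCN blocks (per-partition
# ConvLSTM-derived self-attention maps modulating a degree-normalized graph
# convolution, followed by three parallel temporal convolutions with
# different kernels, concatenated, plus a residual path), node pooling, a
# four-layer LSTM head and a fully connected scalar output.

#' Network configuration
#'
#' @param num_blocks Number of STGCN blocks.
#' @param lift_kernel Temporal kernel of the input feature lift (odd).
#' @param tc_kernels The three temporal-convolution kernel sizes (odd).
#' @param attn_dim Hidden width of the attention ConvLSTM.
#' @param gcn_channels Output channels of the attention-GCN stage.
#' @param tc_channels Output channels of each parallel temporal convolution
#'   (block output width is `3 * tc_channels`).
#' @param lstm_dims Output dimensions of the stacked LSTM head.
#' @param dropout Dropout rate between LSTM layers during training.
#' @param learning_rate Default optimizer learning rate (0.1, paired with
#'   batch size 4).  Training helpers default to a smaller step (see
#'   [train_assess_net()]) because 0.1 is unstable for mean-squared error on
#'   a 0-100 score scale.
#' @param batch_size Mini-batch size.
#' @return A `net_config` object.
#' @export
net_config <- function(num_blocks = 3, lift_kernel = 9, tc_kernels = c(3, 5, 7),
                       attn_dim = 8, gcn_channels = 12, tc_channels = 4,
                       lstm_dims = c(80, 40, 40, 80), dropout = 0.25,
                       learning_rate = 0.1, batch_size = 4) {
  stopifnot(all(c(lift_kernel, tc_kernels) %% 2 == 1),
            dropout >= 0, dropout < 1)
  structure(list(num_blocks = num_blocks, lift_kernel = lift_kernel,
                 tc_kernels = tc_kernels, attn_dim = attn_dim,
                 gcn_channels = gcn_channels, tc_channels = tc_channels,
                 lstm_dims = lstm_dims, dropout = dropout,
                 learning_rate = learning_rate, batch_size = batch_size),
            class = "net_config")
}

#' Normalize a model stream into a network input sequence
#'
#' Positions are centered at the torso marker and divided by the arm length
#' (sum of the estimated upper-limb segment lengths), yielding a
#' `(T*11) x 3` feature matrix in node-major frame blocks.
#'
#' @param stream Model-marker `skeleton_stream`.
#' @param arm_length Normalization length (m); `NULL` to estimate from the
#'   stream.
#' @return List: `x` (feature matrix), `T_`, `N`.
#' @export
skeleton_sequence <- function(stream, arm_length = NULL) {
  stopifnot(inherits(stream, "skeleton_stream"),
            identical(stream$joints, model_markers()))
  if (is.null(arm_length)) {
    L <- tryCatch(estimate_segment_lengths(stream, min_frames = 1),
                  error = function(e) NULL)
    arm_length <- if (is.null(L)) 0.73 else sum(L[c("LUA", "LLA", "LH", "LT")])
  }
  nT <- n_frames(stream); N <- 11
  tor <- match("TOR", stream$joints)
  x <- matrix(0, nT * N, 3)
  for (i in seq_len(nT)) {
    p <- matrix(stream$xyz[i, , ], ncol = 3)
    x[((i - 1) * N + 1):(i * N), ] <-
      sweep(p, 2, p[tor, ]) / arm_length
  }
  list(x = x, T_ = nT, N = N)
}

# partition adjacencies: A0 = I, A1 = A; Ahat_k = A_k + I, degree-normalized
.graph_masks <- function() {
  A <- build_limb_graph()$adjacency
  list(gcn_norm_adjacency(diag(nrow(A))), gcn_norm_adjacency(A))
}

#' Initialize network parameters
#'
#' @param config A [net_config()].
#' @param in_channels Input channels per node (3 for xyz).
#' @param seed Integer seed.
#' @return A `assess_net` model object (parameters + config + graph masks).
#' @export
build_network <- function(config = net_config(), in_channels = 3, seed = 1) {
  set.seed(seed)
  N <- 11
  c_lift <- 2 * in_channels
  blocks <- vector("list", config$num_blocks)
  c_in <- c_lift
  c_out <- 3 * config$tc_channels
  for (l in seq_len(config$num_blocks)) {
    attn <- lapply(1:2, function(k) {
      list(Wq = .nn_rand(c_in, config$attn_dim, c_in),
           lstm = lstm_init(config$attn_dim, config$attn_dim),
           P = .nn_rand(config$attn_dim, N, config$attn_dim))
    })
    gcn <- lapply(1:2, function(k) .nn_rand(c_in, config$gcn_channels, c_in))
    tc <- lapply(config$tc_kernels, function(k)
      tconv_init(k, config$gcn_channels, config$tc_channels))
    res <- if (c_in != c_out) .nn_rand(c_in, c_out, c_in) else NULL
    blocks[[l]] <- list(attn = attn, gcn = gcn, tc = tc, res = res)
    c_in <- c_out
  }
  lstm <- list(); c_prev <- c_out
  for (j in seq_along(config$lstm_dims)) {
    lstm[[j]] <- lstm_init(c_prev, config$lstm_dims[j])
    c_prev <- config$lstm_dims[j]
  }
  structure(list(
    params = list(lift = tconv_init(config$lift_kernel, in_channels,
                                    in_channels),
                  blocks = blocks, lstm = lstm,
                  fc = list(W = .nn_rand(c_prev, 1, c_prev), b = 50)),
    config = config, masks = .graph_masks(), in_channels = in_channels),
    class = "assess_net")
}

#' @export
print.assess_net <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, numeric(1)))
  cat(sprintf("<assess_net: %d STGCN blocks, LSTM head (%s), %d parameters>\n",
              x$config$num_blocks,
              paste(x$config$lstm_dims, collapse = ","), np))
  invisible(x)
}

# full forward pass; keep = TRUE retains caches for backprop;
# train = TRUE enables dropout (masks drawn from the current RNG stream)
.net_forward <- function(model, seq, keep = FALSE, train = FALSE,
                         attention_frozen = FALSE) {
  cfg <- model$config; p <- model$params
  T_ <- seq$T_; N <- seq$N
  cache <- list()
  lift <- tconv_fwd(seq$x, T_, N, p$lift)
  Z <- cbind(seq$x, lift$out)
  cache$lift <- if (keep) lift
  cache$blocks <- vector("list", length(p$blocks))
  for (l in seq_along(p$blocks)) {
    bp <- p$blocks[[l]]
    bcache <- list(Zin = Z)
    G <- NULL
    for (k in 1:2) {
      ap <- bp$attn[[k]]
      if (attention_frozen) {
        S <- matrix(1, T_ * N, N)
        qd <- hd <- sd_ <- NULL
      } else {
        qd <- dense_fwd(Z, ap$Wq, numeric(ncol(ap$Wq)))
        hd <- lstm_fwd(qd$out, T_, N, ap$lstm)
        sd_ <- attnmap_fwd(hd$out, ap$P)
        S <- sd_$out
      }
      gc_ <- attn_gcn_fwd(Z, S, T_, N, model$masks[[k]], bp$gcn[[k]])
      rl <- relu_fwd(gc_$out)
      G <- if (is.null(G)) rl$out else G + rl$out
      bcache[[paste0("k", k)]] <- if (keep) list(qd = qd, hd = hd, sd = sd_,
                                                 gc = gc_, rl = rl)
      bcache[[paste0("S", k)]] <- S
    }
    tc_out <- NULL
    for (m in seq_along(bp$tc)) {
      tcm <- tconv_fwd(G, T_, N, bp$tc[[m]])
      tc_out <- if (is.null(tc_out)) tcm$out else cbind(tc_out, tcm$out)
      bcache[[paste0("tc", m)]] <- if (keep) tcm
    }
    resid <- if (is.null(bp$res)) Z else Z %*% bp$res
    Z <- tc_out + resid
    bcache$G <- if (keep) G
    cache$blocks[[l]] <- bcache
  }
  pooled <- node_pool_fwd(Z, T_, N)
  cache$pool_in_dim <- ncol(Z)
  H <- pooled
  cache$lstm <- vector("list", length(p$lstm))
  cache$drop <- vector("list", length(p$lstm))
  for (j in seq_along(p$lstm)) {
    lf <- lstm_fwd(H, T_, 1, p$lstm[[j]])
    H <- lf$out
    if (train && cfg$dropout > 0 && j < length(p$lstm)) {
      mask <- matrix(stats::runif(length(H)) >= cfg$dropout,
                     nrow(H), ncol(H)) / (1 - cfg$dropout)
      H <- H * mask
      cache$drop[[j]] <- mask
    }
    cache$lstm[[j]] <- if (keep) lf
  }
  fc <- dense_fwd(matrix(colMeans(H), 1), p$fc$W, p$fc$b)  # time-mean readout
  cache$fc <- if (keep) fc
  cache$T_ <- T_; cache$N <- N; cache$H_last_dim <- ncol(H)
  list(score = drop(fc$out), cache = cache)
}

# backward pass for d(score); returns grads with the params' structure
.net_backward <- function(model, fw, dscore, attention_frozen = FALSE) {
  p <- model$params; cache <- fw$cache
  T_ <- cache$T_; N <- cache$N
  grads <- list()
  dfc <- dense_bwd(cache$fc, matrix(dscore, 1, 1))
  grads$fc <- list(W = dfc$dW, b = dfc$db)
  dH <- matrix(dfc$dx / T_, T_, cache$H_last_dim, byrow = TRUE)
  grads$lstm <- vector("list", length(p$lstm))
  for (j in seq(length(p$lstm), 1)) {
    if (!is.null(cache$drop[[j]])) dH <- dH * cache$drop[[j]]
    lb <- lstm_bwd(cache$lstm[[j]], dH)
    grads$lstm[[j]] <- lb$grads
    dH <- lb$dQ
  }
  dZ <- node_pool_bwd(dH, T_, N)
  grads$blocks <- vector("list", length(p$blocks))
  for (l in seq(length(p$blocks), 1)) {
    bp <- p$blocks[[l]]; bc <- cache$blocks[[l]]
    bg <- list()
    # residual path
    if (is.null(bp$res)) {
      dZin <- dZ
    } else {
      bg$res <- crossprod(bc$Zin, dZ)
      dZin <- dZ %*% t(bp$res)
    }
    # temporal convolutions (concatenated outputs)
    dG <- NULL
    off <- 0
    bg$tc <- vector("list", length(bp$tc))
    for (m in seq_along(bp$tc)) {
      cm <- ncol(bc[[paste0("tc", m)]]$out)
      dYm <- dZ[, (off + 1):(off + cm), drop = FALSE]
      off <- off + cm
      tb <- tconv_bwd(bc[[paste0("tc", m)]], dYm)
      bg$tc[[m]] <- tb$grads
      dG <- if (is.null(dG)) tb$dX else dG + tb$dX
    }
    bg$gcn <- vector("list", 2)
    bg$attn <- vector("list", 2)
    for (k in 1:2) {
      kc <- bc[[paste0("k", k)]]
      dpre <- relu_bwd(kc$rl, dG)
      gb <- attn_gcn_bwd(kc$gc, dpre)
      bg$gcn[[k]] <- gb$dW
      dZin <- dZin + gb$dZ
      if (!attention_frozen) {
        ab <- attnmap_bwd(kc$sd, gb$dS)
        lb <- lstm_bwd(kc$hd, ab$dH)
        db_q <- dense_bwd(kc$qd, lb$dQ)
        dZin <- dZin + db_q$dx
        bg$attn[[k]] <- list(Wq = db_q$dW, lstm = lb$grads, P = ab$dP)
      }
    }
    grads$blocks[[l]] <- bg
    dZ <- dZin
  }
  lb <- tconv_bwd(cache$lift, dZ[, (model$in_channels + 1):ncol(dZ),
                                 drop = FALSE])
  grads$lift <- lb$grads
  # note: gradient into the raw copy of the input is dropped (input, not a
  # parameter)
  grads
}

#' Predict the movement-quality score of one sequence
#'
#' @param model A trained (or freshly built) `assess_net`.
#' @param seq A [skeleton_sequence()] (or a model `skeleton_stream`).
#' @return Scalar score.
#' @export
predict_score <- function(model, seq) {
  if (inherits(seq, "skeleton_stream")) seq <- skeleton_sequence(seq)
  .net_forward(model, seq,
               attention_frozen = isTRUE(model$attention_frozen))$score
}

# ---- Adam optimizer over nested parameter lists ----------------------------

# apply f leaf-wise over two parameter trees, matching children by name
# where names exist; children missing from `b` are passed through from `a`
.tree_map2 <- function(f, a, b) {
  if (!is.list(a)) {
    if (is.null(a) || is.null(b) || !length(a) || !length(b)) return(a)
    return(f(a, b))
  }
  out <- a
  nms <- names(a)
  for (i in seq_along(a)) {
    key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
    bi <- if (is.list(b)) tryCatch(b[[key]], error = function(e) NULL) else NULL
    if (is.null(a[[i]]) || is.null(bi)) next
    out[[key]] <- .tree_map2(f, a[[i]], bi)
  }
  out
}

.tree_zero <- function(a) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) lapply(a, .tree_zero) else a * 0
}

#' Train the assessment network
#'
#' Minimizes mean squared error of the score with the Adam optimizer.
#' Deterministic for a fixed seed (initialization, shuffling and dropout all
#' derive from it).
#'
#' @param dataset List of samples, each a list with `seq`
#'   (a [skeleton_sequence()]) and `score`.
#' @param config A [net_config()].
#' @param seed Integer seed.
#' @param epochs Training epochs.
#' @param lr Learning rate (default 0.005; the 0.1 config default diverges
#'   at this loss scale and is kept only as the configuration value).
#' @param attention_frozen If `TRUE`, all attention maps are fixed at the
#'   neutral value 1 (ablation: plain STGCN).
#' @param stop_mse Optional early-stop threshold on the epoch training MSE.
#' @param clip_norm Global gradient-norm clip (stabilizes the recurrent
#'   layers); `Inf` disables.
#' @param verbose Print the loss every 10 epochs.
#' @return The trained `assess_net` with `$loss_history`.
#' @export
train_assess_net <- function(dataset, config = net_config(), seed = 1,
                             epochs = 100, lr = 0.005,
                             attention_frozen = FALSE, stop_mse = NULL,
                             clip_norm = 10, verbose = FALSE) {
  if (!length(dataset)) stop("train_assess_net: empty dataset")
  model <- build_network(config, seed = seed)
  model$attention_frozen <- attention_frozen
  p <- model$params
  m_st <- .tree_zero(p); v_st <- .tree_zero(p)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample(length(dataset))
    ep_loss <- 0
    for (start in seq(1, length(dataset), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, length(dataset))]
      gacc <- NULL
      for (i in idx) {
        s <- dataset[[i]]
        fw <- .net_forward(model, s$seq, keep = TRUE, train = TRUE,
                           attention_frozen = attention_frozen)
        err <- fw$score - s$score
        ep_loss <- ep_loss + err^2
        g <- .net_backward(model, fw, 2 * err / length(idx),
                           attention_frozen = attention_frozen)
        gacc <- if (is.null(gacc)) g else .tree_map2(`+`, gacc, g)
      }
      step <- step + 1
      if (is.finite(clip_norm)) {
        sq <- 0
        walk <- function(g) {
          if (is.list(g)) lapply(g, walk) else sq <<- sq + sum(g^2)
          invisible(NULL)
        }
        walk(gacc)
        gn <- sqrt(sq)
        if (gn > clip_norm)
          gacc <- .tree_map2(function(g, .) g * (clip_norm / gn), gacc, gacc)
      }
      m_st <- .tree_map2(function(m, g) b1 * m + (1 - b1) * g, m_st, gacc)
      v_st <- .tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, v_st, gacc)
      upd <- .tree_map2(function(m, v) lr * m / (1 - b1^step) /
                          (sqrt(v / (1 - b2^step)) + eps), m_st, v_st)
      model$params <- .tree_map2(`-`, model$params, upd)
    }
    loss_hist[ep] <- ep_loss / length(dataset)
    if (!is.finite(loss_hist[ep]))
      stop("train_assess_net: loss diverged (non-finite); lower the learning rate")
    if (verbose && ep %% 10 == 0)
      message(sprintf("epoch %d: mse %.3f", ep, loss_hist[ep]))
    if (!is.null(stop_mse) && loss_hist[ep] < stop_mse) {
      loss_hist <- loss_hist[seq_len(ep)]
      break
    }
  }
  model$loss_history <- loss_hist
  model
}

#' Joint-importance matrix from attention maps
#'
#' For each action group, the attention maps of every block and partition
#' are collected over a forward pass; a node's importance is the mean
#' absolute deviation of its outgoing attention row from that row's
#' temporal mean (how strongly the network modulates attention for the node
#' over the movement), averaged over time, blocks, partitions and
#' sequences, then min-max scaled to `[0, 1]` across the 11 nodes.  Nodes
#' that do not move produce constant attention and hence zero modulation.
#'
#' @param model Trained `assess_net`.
#' @param sequences_by_action Named list; each element a list of
#'   [skeleton_sequence()] inputs for one action.
#' @return `length(groups) x 11` matrix in `[0, 1]`, rows named by action.
#' @export
joint_importance <- function(model, sequences_by_action) {
  N <- 11
  out <- matrix(NA_real_, length(sequences_by_action), N,
                dimnames = list(names(sequences_by_action), model_markers()))
  for (g in seq_along(sequences_by_action)) {
    seqs <- sequences_by_action[[g]]
    if (!length(seqs)) {
      warning(sprintf("joint_importance: empty action group '%s'; skipped",
                      names(sequences_by_action)[g]))
      next
    }
    acc <- numeric(N)
    for (s in seqs) {
      fw <- .net_forward(model, s, keep = TRUE)
      for (bc in fw$cache$blocks) for (k in 1:2) {
        S <- bc[[paste0("S", k)]]          # (T*N) x N stacked attention maps
        # outgoing rows of node n are rows n, n+N, ... of the stacked maps
        acc <- acc + vapply(seq_len(N), function(n) {
          rows <- S[seq(n, nrow(S), by = N), , drop = FALSE]
          mean(abs(sweep(rows, 2, colMeans(rows))))
        }, numeric(1))
      }
    }
    rng <- range(acc)
    out[g, ] <- if (diff(rng) > 0) (acc - rng[1]) / diff(rng)
                else rep(0, N)
  }
  out
}

#' Score-regression accuracy metrics
#'
#' Mean absolute deviation, root-mean-square error and mean absolute
#' percentage error of predictions against ground-truth scores.
#'
#' @param pred,truth Equal-length numeric vectors; `truth` must be non-zero
#'   for the MAPE.
#' @return List with `MAD`, `RMSE`, `MAPE` (percent).
#' @export
assess_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) > 0)
  if (any(truth == 0))
    stop(sprintf("assess_metrics: MAPE undefined, truth is zero at index %d",
                 which(truth == 0)[1]))
  e <- pred - truth
  list(MAD = mean(abs(e)), RMSE = sqrt(mean(e^2)),
       MAPE = 100 * mean(abs(e) / abs(truth)))
}
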