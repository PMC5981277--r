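# Minimal CNN engine.
#
# Activations travel as dense matrices of shape (H*W*C) x N, column-major
# with rows ordered h (fastest), w, then channel; a 1-D sequence is the
# degenerate case W = 1. Convolutions are cross-correlations (no kernel
# flip): im2col is a precomputed index gather, the contraction is one BLAS
# matmul, and the backward scatter-add is a single rowsum(). Every layer is
# an environment with fwd(X, training)/bwd(dY) closures caching what its
# backward pass needs; composite layers (parallel branches, dense blocks)
# hold child chains.

glorot_init <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

new_layer <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$param_names <- character()
  e$children <- list()
  e
}

layer_conv2d <- function(in_shape, n_filters, kernel, padding = c("same", "valid")) {
  padding <- match.arg(padding)
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  kh <- kernel[1]; kw <- if (length(kernel) > 1L) kernel[2] else kernel[1]
  if (kh < 1 || kw < 1) abort("kernel must be >= 1.", class = "habsuit_config_error")
  if (padding == "same") {
    pt <- (kh - 1L) %/% 2L; pb <- kh - 1L - pt
    pl <- (kw - 1L) %/% 2L; pr <- kw - 1L - pl
  } else {
    pt <- pb <- pl <- pr <- 0L
  }
  Hp <- H + pt + pb; Wp <- W + pl + pr
  Ho <- Hp - kh + 1L; Wo <- Wp - kw + 1L
  if (Ho < 1L || Wo < 1L) {
    abort(sprintf("conv2d: input %dx%d smaller than kernel %dx%d.", H, W, kh, kw),
          class = "habsuit_shape_error")
  }
  P <- Hp * Wp * C; K <- kh * kw * C; L <- Ho * Wo
  eg <- expand.grid(h = seq_len(H), w = seq_len(W), c = seq_len(C))
  interior <- (eg$h + pt) + (eg$w + pl - 1L) * Hp + (eg$c - 1L) * Hp * Wp
  kk <- expand.grid(dh = seq_len(kh), dw = seq_len(kw), c = seq_len(C))
  ll <- expand.grid(oh = seq_len(Ho), ow = seq_len(Wo))
  idx <- outer((kk$dh - 1L) + (kk$dw - 1L) * Hp + (kk$c - 1L) * Hp * Wp,
               ll$oh + (ll$ow - 1L) * Hp, "+")
  ivec <- as.vector(idx)
  uidx <- sort(unique(ivec))

  e <- new_layer("conv2d")
  e$in_shape <- in_shape
  e$out_shape <- c(Ho, Wo, n_filters)
  e$param_names <- c("W", "b")
  e$W <- matrix(glorot_init(n_filters * K, K, kh * kw * n_filters),
                n_filters, K)
  e$b <- numeric(n_filters)
  Fn <- n_filters
  e$fwd <- function(X, training = FALSE) {
    N <- ncol(X)
    Xp <- matrix(0, P, N)
    Xp[interior, ] <- X
    Xcol <- Xp[ivec, , drop = FALSE]
    dim(Xcol) <- c(K, L * N)
    Z <- e$W %*% Xcol + e$b
    if (training) e$Xcol <- Xcol else e$Xcol <- NULL
    Y <- aperm(array(Z, c(Fn, L, N)), c(2, 1, 3))
    dim(Y) <- c(L * Fn, N)
    Y
  }
  e$bwd <- function(dY) {
    N <- ncol(dY)
    dZ <- aperm(array(dY, c(L, Fn, N)), c(2, 1, 3))
    e$db <- rowSums(dZ, dims = 1)
    dim(dZ) <- c(Fn, L * N)
    e$dW <- tcrossprod(dZ, e$Xcol)
    dXcol <- crossprod(e$W, dZ)
    dim(dXcol) <- c(K * L, N)
    rs <- rowsum(dXcol, group = ivec, reorder = TRUE)
    dXp <- matrix(0, P, N)
    dXp[uidx, ] <- rs
    e$Xcol <- NULL
    dXp[interior, , drop = FALSE]
  }
  e
}

layer_conv1d <- function(in_len, in_ch, n_filters, kernel) {
  if (in_len < kernel) {
    abort(sprintf("conv1d: input length %d shorter than kernel %d.",
                  in_len, kernel), class = "habsuit_shape_error")
  }
  e <- layer_conv2d(c(in_len, 1L, in_ch), n_filters, c(kernel, 1L), "valid")
  e$kind <- "conv1d"
  e
}

layer_relu <- function(shape) {
  e <- new_layer("relu")
  e$out_shape <- shape
  e$fwd <- function(X, training = FALSE) {
    Y <- pmax(X, 0)
    if (training) e$mask <- X > 0 else e$mask <- NULL
    Y
  }
  e$bwd <- function(dY) {
    out <- dY * e$mask
    e$mask <- NULL
    out
  }
  e
}

layer_batchnorm <- function(in_shape, momentum = 0.9, eps = 1e-5) {
  H <- in_shape[1]; W <- if (length(in_shape) > 1L) in_shape[2] else 1L
  C <- if (length(in_shape) > 2L) in_shape[3] else 1L
  HW <- H * W
  e <- new_layer("batchnorm")
  e$out_shape <- in_shape
  e$param_names <- c("gamma", "beta")
  e$gamma <- rep(1, C)
  e$beta <- rep(0, C)
  e$run_mean <- rep(0, C)
  e$run_var <- rep(1, C)
  channel_sum <- function(A, N) {
    cs <- .colSums(matrix(A, HW, C * N), HW, C * N)
    .rowSums(matrix(cs, C, N), C, N)
  }
  e$fwd <- function(X, training = FALSE) {
    N <- ncol(X)
    if (training) {
      m <- HW * N
      mu <- channel_sum(X, N) / m
      v <- channel_sum(X * X, N) / m - mu^2
      v <- pmax(v, 0)
      istd <- 1 / sqrt(v + eps)
      xhat <- (X - rep(mu, each = HW)) * rep(istd, each = HW)
      e$run_mean <- momentum * e$run_mean + (1 - momentum) * mu
      e$run_var <- momentum * e$run_var + (1 - momentum) * v
      e$xhat <- xhat
      e$istd <- istd
    } else {
      istd <- 1 / sqrt(e$run_var + eps)
      xhat <- (X - rep(e$run_mean, each = HW)) * rep(istd, each = HW)
    }
    xhat * rep(e$gamma, each = HW) + rep(e$beta, each = HW)
  }
  e$bwd <- function(dY) {
    N <- ncol(dY)
    m <- HW * N
    e$dgamma <- channel_sum(dY * e$xhat, N)
    e$dbeta <- channel_sum(dY, N)
    dX <- rep(e$gamma * e$istd, each = HW) *
      (dY - rep(e$dbeta / m, each = HW) - e$xhat * rep(e$dgamma / m, each = HW))
    e$xhat <- NULL
    dX
  }
  e
}

layer_maxpool2 <- function(in_shape) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  e <- new_layer("maxpool")
  e$out_shape <- c(Ho, Wo, C)
  e$fwd <- function(X, training = FALSE) {
    N <- ncol(X)
    A <- array(X, c(H, W, C * N))
    a11 <- A[ro, co, , drop = FALSE]; a21 <- A[re, co, , drop = FALSE]
    a12 <- A[ro, ce, , drop = FALSE]; a22 <- A[re, ce, , drop = FALSE]
    m <- pmax(a11, a21, a12, a22)
    if (training) {
      s11 <- a11 == m
      s21 <- (a21 == m) & !s11
      s12 <- (a12 == m) & !(s11 | s21)
      e$sel <- list(s11, s21, s12, !(s11 | s21 | s12))
    } else e$sel <- NULL
    dim(m) <- c(Ho * Wo * C, N)
    m
  }
  e$bwd <- function(dY) {
    N <- ncol(dY)
    G <- array(dY, c(Ho, Wo, C * N))
    dA <- array(0, c(H, W, C * N))
    dA[ro, co, ] <- G * e$sel[[1]]
    dA[re, co, ] <- G * e$sel[[2]]
    dA[ro, ce, ] <- G * e$sel[[3]]
    dA[re, ce, ] <- G * e$sel[[4]]
    e$sel <- NULL
    dim(dA) <- c(H * W * C, N)
    dA
  }
  e
}

layer_avgpool2 <- function(in_shape) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  e <- new_layer("avgpool")
  e$out_shape <- c(Ho, Wo, C)
  e$fwd <- function(X, training = FALSE) {
    N <- ncol(X)
    A <- array(X, c(H, W, C * N))
    m <- (A[ro, co, , drop = FALSE] + A[re, co, , drop = FALSE] +
            A[ro, ce, , drop = FALSE] + A[re, ce, , drop = FALSE]) / 4
    dim(m) <- c(Ho * Wo * C, N)
    m
  }
  e$bwd <- function(dY) {
    N <- ncol(dY)
    G <- array(dY / 4, c(Ho, Wo, C * N))
    dA <- array(0, c(H, W, C * N))
    dA[ro, co, ] <- G; dA[re, co, ] <- G; dA[ro, ce, ] <- G; dA[re, ce, ] <- G
    dim(dA) <- c(H * W * C, N)
    dA
  }
  e
}

layer_global_avgpool <- function(in_shape) {
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  HW <- H * W
  e <- new_layer("gap")
  e$out_shape <- c(1L, 1L, C)
  e$fwd <- function(X, training = FALSE) {
    N <- ncol(X)
    matrix(.colSums(matrix(X, HW, C * N), HW, C * N) / HW, C, N)
  }
  e$bwd <- function(dY) {
    N <- ncol(dY)
    matrix(rep(as.vector(dY), each = HW) / HW, HW * C, N)
  }
  e
}

layer_global_maxpool1d <- function(in_len, in_ch) {
  H <- in_len; C <- in_ch
  e <- new_layer("gmp1d")
  e$out_shape <- c(1L, 1L, C)
  e$fwd <- function(X, training = FALSE) {
    N <- ncol(X)
    Xm <- matrix(X, H, C * N)
    j <- max.col(t(Xm), ties.method = "first")
    if (training) e$j <- j else e$j <- NULL
    matrix(Xm[cbind(j, seq_len(C * N))], C, N)
  }
  e$bwd <- function(dY) {
    N <- ncol(dY)
    dXm <- matrix(0, H, C * N)
    dXm[cbind(e$j, seq_len(C * N))] <- as.vector(dY)
    e$j <- NULL
    dim(dXm) <- c(H * C, N)
    dXm
  }
  e
}

layer_fc <- function(in_dim, out_dim) {
  e <- new_layer("fc")
  e$out_shape <- c(out_dim)
  e$param_names <- c("W", "b")
  e$W <- matrix(glorot_init(out_dim * in_dim, in_dim, out_dim), out_dim, in_dim)
  e$b <- numeric(out_dim)
  e$fwd <- function(X, training = FALSE) {
    if (training) e$X <- X else e$X <- NULL
    e$W %*% X + e$b
  }
  e$bwd <- function(dY) {
    e$dW <- tcrossprod(dY, e$X)
    e$db <- rowSums(dY)
    e$X <- NULL
    crossprod(e$W, dY)
  }
  e
}

# parallel branches over the same input; outputs concatenated along channels
layer_parallel <- function(branches, out_shapes) {
  e <- new_layer("parallel")
  e$children <- branches
  rows <- vapply(out_shapes, prod, 0)
  e$out_shape <- c(out_shapes[[1]][1], out_shapes[[1]][2],
                   sum(vapply(out_shapes, function(s) s[3], 0)))
  e$fwd <- function(X, training = FALSE) {
    do.call(rbind, lapply(branches, function(br) chain_fwd(br, X, training)))
  }
  e$bwd <- function(dY) {
    off <- 0L
    dX <- NULL
    for (i in seq_along(branches)) {
      g <- chain_bwd(branches[[i]], dY[(off + 1L):(off + rows[i]), , drop = FALSE])
      dX <- if (is.null(dX)) g else dX + g
      off <- off + rows[i]
    }
    dX
  }
  e
}

# densely connected block: unit l sees the concatenation of the block input
# and all previous units' outputs, and appends `growth` channels
layer_dense_block <- function(in_shape, n_units, growth, bottleneck) {
  H <- in_shape[1]; W <- in_shape[2]; C0 <- in_shape[3]
  HW <- H * W
  units <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    cin <- C0 + (u - 1L) * growth
    units[[u]] <- list(
      layer_batchnorm(c(H, W, cin)),
      layer_relu(c(H, W, cin)),
      layer_conv2d(c(H, W, cin), bottleneck, c(1L, 1L), "same"),
      layer_batchnorm(c(H, W, bottleneck)),
      layer_relu(c(H, W, bottleneck)),
      layer_conv2d(c(H, W, bottleneck), growth, c(3L, 3L), "same")
    )
  }
  e <- new_layer("dense_block")
  e$children <- units
  e$out_shape <- c(H, W, C0 + n_units * growth)
  e$fwd <- function(X, training = FALSE) {
    cur <- X
    for (u in seq_len(n_units)) {
      cur <- rbind(cur, chain_fwd(units[[u]], cur, training))
    }
    cur
  }
  e$bwd <- function(dY) {
    acc <- dY
    for (u in rev(seq_len(n_units))) {
      rows_in <- HW * (C0 + (u - 1L) * growth)
      g_out <- acc[(rows_in + 1L):(rows_in + HW * growth), , drop = FALSE]
      acc <- acc[seq_len(rows_in), , drop = FALSE] +
        chain_bwd(units[[u]], g_out)
    }
    acc
  }
  e
}

chain_fwd <- function(chain, X, training = FALSE) {
  for (ly in chain) X <- ly$fwd(X, training)
  X
}

chain_bwd <- function(chain, dY) {
  for (ly in rev(chain)) dY <- ly$bwd(dY)
  dY
}

# all parameter-carrying layers, recursing into composites
collect_param_layers <- function(chain) {
  out <- list()
  for (ly in chain) {
    if (length(ly$param_names) > 0L) out <- c(out, list(ly))
    for (child in ly$children) out <- c(out, collect_param_layers(child))
  }
  out
}

n_params <- function(layers) {
  sum(vapply(layers, function(ly) {
    sum(vapply(ly$param_names, function(p) length(ly[[p]]), 0))
  }, 0))
}

# Adam with bias correction; states live on the layer environments
adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (ly in layers) {
    for (p in ly$param_names) {
      g <- ly[[paste0("d", p)]]
      mk <- paste0("adam_m_", p); vk <- paste0("adam_v_", p)
      m <- (ly[[mk]] %||% 0) * beta1 + (1 - beta1) * g
      v <- (ly[[vk]] %||% 0) * beta2 + (1 - beta2) * g * g
      ly[[mk]] <- m
      ly[[vk]] <- v
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      ly[[p]] <- ly[[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

# snapshot / restore weights and normalization statistics (for early stopping)
snapshot_params <- function(layers) {
  lapply(layers, function(ly) {
    s <- lapply(ly$param_names, function(p) ly[[p]])
    names(s) <- ly$param_names
    if (ly$kind == "batchnorm") {
      s$run_mean <- ly$run_mean
      s$run_var <- ly$run_var
    }
    s
  })
}

restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    for (p in names(snap[[i]])) layers[[i]][[p]] <- snap[[i]][[p]]
  }
  invisible(NULL)
}

softmax_probs <- function(logits) {
  mx <- apply(logits, 2, max)
  p <- exp(sweep(logits, 2, mx))
  sweep(p, 2, colSums(p), "/")
}

# cross-entropy loss and its gradient; y is an integer class index per column
softmax_ce <- function(logits, y) {
  p <- softmax_probs(logits)
  N <- ncol(logits)
  picked <- p[cbind(y, seq_len(N))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  d <- p
  d[cbind(y, seq_len(N))] <- d[cbind(y, seq_len(N))] - 1
  list(loss = loss, dlogits = d / N, probs = p)
}
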