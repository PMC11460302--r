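# Minimal convolutional network engine on base R + BLAS.
#
# Feature maps are carried as an (n_sites x channels) matrix where
# n_sites = H*W*B (2D) or L*B (1D); site index = spatial linear index plus
# (b-1)*spatial_size. All convolutions work through gather/scatter index
# tables (im2col) so the heavy lifting is dense matrix multiplication.
# Layers are environments: forward passes cache what backward needs, and
# parameter updates happen in place.

.nn_eps <- 1e-5

# ---- gather/scatter index tables -------------------------------------------

# 3x3 (2D) or length-3 (1D) same-padding neighbourhoods; 0 = out of bounds.
.nbr_conv <- function(sp) {
  if (length(sp) == 2L) {
    H <- sp[1]; W <- sp[2]
    h <- rep(seq_len(H), W); w <- rep(seq_len(W), each = H)
    offs <- expand.grid(di = -1:1, dj = -1:1)
    idx <- matrix(0L, H * W, 9L)
    for (k in 1:9) {
      hh <- h + offs$di[k]; ww <- w + offs$dj[k]
      ok <- hh >= 1L & hh <= H & ww >= 1L & ww <= W
      idx[ok, k] <- (ww[ok] - 1L) * H + hh[ok]
    }
  } else {
    L <- sp[1]
    x <- seq_len(L)
    idx <- matrix(0L, L, 3L)
    for (k in 1:3) {
      xx <- x + (k - 2L)
      ok <- xx >= 1L & xx <= L
      idx[ok, k] <- xx[ok]
    }
  }
  idx
}

# stride-2 transposed-convolution scatter targets: for each input site the
# output sites its 3 (1D) / 9 (2D) kernel taps land on; 0 = outside.
.nbr_tconv <- function(sp) {
  if (length(sp) == 2L) {
    H <- sp[1]; W <- sp[2]; H2 <- 2L * H; W2 <- 2L * W
    i <- rep(seq_len(H), W); j <- rep(seq_len(W), each = H)
    offs <- expand.grid(di = 0:2, dj = 0:2)
    idx <- matrix(0L, H * W, 9L)
    for (k in 1:9) {
      r <- 2L * i - 2L + offs$di[k]; c <- 2L * j - 2L + offs$dj[k]
      ok <- r >= 1L & r <= H2 & c >= 1L & c <= W2
      idx[ok, k] <- (c[ok] - 1L) * H2 + r[ok]
    }
  } else {
    L <- sp[1]; L2 <- 2L * L
    i <- seq_len(L)
    idx <- matrix(0L, L, 3L)
    for (k in 1:3) {
      r <- 2L * i - 2L + (k - 1L)
      ok <- r >= 1L & r <= L2
      idx[ok, k] <- r[ok]
    }
  }
  idx
}

# 2x (2D: 2x2, 1D: 2) max-pool candidate sites per output site.
.nbr_pool <- function(sp) {
  if (length(sp) == 2L) {
    H <- sp[1]; W <- sp[2]; H2 <- H %/% 2L; W2 <- W %/% 2L
    i <- rep(seq_len(H2), W2); j <- rep(seq_len(W2), each = H2)
    cand <- cbind((2L * j - 2L) * H + 2L * i - 1L,
                  (2L * j - 2L) * H + 2L * i,
                  (2L * j - 1L) * H + 2L * i - 1L,
                  (2L * j - 1L) * H + 2L * i)
  } else {
    L2 <- sp[1] %/% 2L
    i <- seq_len(L2)
    cand <- cbind(2L * i - 1L, 2L * i)
  }
  cand
}

# replicate a per-sample site index table across a batch
.batch_idx <- function(idx, spatial, B) {
  if (B == 1L) return(idx)
  out <- matrix(0L, nrow(idx) * B, ncol(idx))
  for (b in seq_len(B)) {
    rows <- (b - 1L) * nrow(idx) + seq_len(nrow(idx))
    out[rows, ] <- ifelse(idx > 0L, idx + (b - 1L) * spatial, 0L)
  }
  out
}

# cached per-shape index lookup on a layer environment
.get_idx <- function(lay, builder, sp, B, spatial_out = prod(sp)) {
  key <- paste(c(sp, B), collapse = "x")
  if (is.null(lay$idx_cache)) lay$idx_cache <- list()
  got <- lay$idx_cache[[key]]
  if (!is.null(got)) return(got)
  got <- .batch_idx(builder(sp), spatial_out, B)
  lay$idx_cache[[key]] <- got
  got
}

# ---- layer constructors ----------------------------------------------------

.xavier <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

.new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  e
}

.layer_conv <- function(c_in, c_out, taps) {
  W <- matrix(.xavier(taps * c_in, taps * c_out, taps * c_in * c_out),
              taps * c_in, c_out)
  .new_layer("conv", W = W, b = numeric(c_out), taps = taps,
             c_in = c_in, c_out = c_out, params = c("W", "b"))
}

.layer_tconv <- function(c_in, c_out, taps) {
  W <- array(.xavier(taps * c_in, taps * c_out, taps * c_in * c_out),
             dim = c(taps, c_in, c_out))
  .new_layer("tconv", W = W, b = numeric(c_out), taps = taps,
             c_in = c_in, c_out = c_out, params = c("W", "b"))
}

.layer_conv1x1 <- function(c_in, c_out) {
  W <- matrix(.xavier(c_in, c_out, c_in * c_out), c_in, c_out)
  .new_layer("conv1x1", W = W, b = numeric(c_out),
             c_in = c_in, c_out = c_out, params = c("W", "b"))
}

.layer_bn <- function(c_) {
  .new_layer("bn", gamma = rep(1, c_), beta = numeric(c_),
             run_mean = numeric(c_), run_var = rep(1, c_),
             momentum = 0.1, params = c("gamma", "beta"))
}

.layer_prelu <- function() .new_layer("prelu", alpha = 0.25, params = "alpha")

.layer_pool <- function() .new_layer("pool", params = character(0))

.layer_relu <- function() .new_layer("relu", params = character(0))

# ---- forward / backward ----------------------------------------------------

# x: (spatial*B) x C matrix; sh: list(sp = spatial dims vector, B = batch)
.lay_fwd <- function(lay, x, sh, training) {
  switch(lay$type,
    conv = {
      idx <- .get_idx(lay, .nbr_conv, sh$sp, sh$B)
      xp <- rbind(0, x)
      taps <- lay$taps; C <- ncol(x)
      xcol <- matrix(0, nrow(x), taps * C)
      for (k in seq_len(taps))
        xcol[, ((k - 1L) * C + 1L):(k * C)] <- xp[idx[, k] + 1L, , drop = FALSE]
      if (training) { lay$xcol <- xcol; lay$idx <- idx; lay$n_in <- nrow(x) }
      y <- xcol %*% lay$W
      list(x = sweep(y, 2, lay$b, "+"), sh = sh)
    },
    tconv = {
      sp_out <- 2L * sh$sp
      idx <- .get_idx(lay, .nbr_tconv, sh$sp, sh$B, spatial_out = prod(sp_out))
      n_out <- prod(sp_out) * sh$B
      yp <- matrix(0, n_out + 1L, lay$c_out)
      for (k in seq_len(lay$taps)) {
        contrib <- x %*% matrix(lay$W[k, , ], lay$c_in, lay$c_out)
        rows <- idx[, k] + 1L
        yp[rows, ] <- yp[rows, , drop = FALSE] + contrib
      }
      yp[1L, ] <- 0
      y <- yp[-1L, , drop = FALSE]
      if (training) { lay$xin <- x; lay$idx <- idx; lay$n_out <- n_out }
      list(x = sweep(y, 2, lay$b, "+"), sh = list(sp = sp_out, B = sh$B))
    },
    conv1x1 = {
      if (training) lay$xin <- x
      list(x = sweep(x %*% lay$W, 2, lay$b, "+"), sh = sh)
    },
    bn = {
      if (training) {
        mu <- colMeans(x)
        xc <- sweep(x, 2, mu)
        v <- colMeans(xc * xc)
        inv <- 1 / sqrt(v + .nn_eps)
        xhat <- sweep(xc, 2, inv, "*")
        lay$xhat <- xhat; lay$inv <- inv; lay$n <- nrow(x)
        lay$run_mean <- (1 - lay$momentum) * lay$run_mean + lay$momentum * mu
        lay$run_var <- (1 - lay$momentum) * lay$run_var + lay$momentum * v
      } else {
        xhat <- sweep(sweep(x, 2, lay$run_mean), 2,
                      1 / sqrt(lay$run_var + .nn_eps), "*")
      }
      list(x = sweep(sweep(xhat, 2, lay$gamma, "*"), 2, lay$beta, "+"),
           sh = sh)
    },
    prelu = {
      if (training) lay$xin <- x
      list(x = ifelse(x > 0, x, lay$alpha * x), sh = sh)
    },
    pool = {
      cand <- .get_idx(lay, .nbr_pool, sh$sp, sh$B,
                       spatial_out = prod(sh$sp %/% 2L))
      m <- ncol(cand)
      y <- x[cand[, 1L], , drop = FALSE]
      arg <- matrix(1L, nrow(y), ncol(y))
      for (k in 2:m) {
        xk <- x[cand[, k], , drop = FALSE]
        upd <- xk > y
        y[upd] <- xk[upd]
        arg[upd] <- k
      }
      if (training) {
        lay$cand <- cand; lay$arg <- arg; lay$n_in <- nrow(x)
      }
      list(x = y, sh = list(sp = sh$sp %/% 2L, B = sh$B))
    },
    relu = {
      if (training) lay$xin <- x
      list(x = pmax(x, 0), sh = sh)
    },
    stop("unknown layer type ", lay$type))
}

.lay_bwd <- function(lay, dy) {
  switch(lay$type,
    conv = {
      lay$gW <- crossprod(lay$xcol, dy)
      lay$gb <- colSums(dy)
      dxcol <- dy %*% t(lay$W)
      C <- lay$c_in
      dxp <- matrix(0, lay$n_in + 1L, C)
      for (k in seq_len(lay$taps)) {
        rows <- lay$idx[, k] + 1L
        dxp[rows, ] <- dxp[rows, , drop = FALSE] +
          dxcol[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
      }
      lay$xcol <- NULL
      dxp[-1L, , drop = FALSE]
    },
    tconv = {
      lay$gb <- colSums(dy)
      dyp <- rbind(0, dy)
      gW <- array(0, dim = dim(lay$W))
      dx <- matrix(0, nrow(lay$xin), lay$c_in)
      for (k in seq_len(lay$taps)) {
        dyk <- dyp[lay$idx[, k] + 1L, , drop = FALSE]
        gW[k, , ] <- crossprod(lay$xin, dyk)
        dx <- dx + dyk %*% t(matrix(lay$W[k, , ], lay$c_in, lay$c_out))
      }
      lay$gW <- gW
      lay$xin <- NULL
      dx
    },
    conv1x1 = {
      lay$gW <- crossprod(lay$xin, dy)
      lay$gb <- colSums(dy)
      dx <- dy %*% t(lay$W)
      lay$xin <- NULL
      dx
    },
    bn = {
      xhat <- lay$xhat
      lay$ggamma <- colSums(dy * xhat)
      lay$gbeta <- colSums(dy)
      dxhat <- sweep(dy, 2, lay$gamma, "*")
      n <- lay$n
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dx <- sweep(dxhat - matrix(s1 / n, n, length(s1), byrow = TRUE) -
                    xhat * matrix(s2 / n, n, length(s2), byrow = TRUE),
                  2, lay$inv, "*")
      lay$xhat <- NULL
      dx
    },
    prelu = {
      x <- lay$xin
      neg <- x <= 0
      lay$galpha <- sum(dy[neg] * x[neg])
      dx <- dy
      dx[neg] <- dx[neg] * lay$alpha
      lay$xin <- NULL
      dx
    },
    pool = {
      nC <- ncol(dy)
      n2 <- nrow(dy)
      dxv <- numeric(lay$n_in * nC)
      rowsel <- lay$cand[cbind(rep(seq_len(n2), nC), as.vector(lay$arg))]
      lin <- rowsel + rep((seq_len(nC) - 1L) * lay$n_in, each = n2)
      dxv[lin] <- dy
      matrix(dxv, lay$n_in, nC)
    },
    relu = {
      dx <- dy
      dx[lay$xin <= 0] <- 0
      lay$xin <- NULL
      dx
    })
}

# ---- network-level passes --------------------------------------------------

.seq_fwd <- function(layers, x, sh, training) {
  for (lay in layers) {
    out <- .lay_fwd(lay, x, sh, training)
    x <- out$x; sh <- out$sh
  }
  list(x = x, sh = sh)
}

.seq_bwd <- function(layers, dy) {
  for (lay in rev(layers)) dy <- .lay_bwd(lay, dy)
  dy
}

.net_layers <- function(net) c(net$encoder, unlist(net$branches))

# Array (H,W,C,B) or (L,C,B) <-> site-matrix conversion.
.to_mat <- function(x) {
  d <- dim(x)
  nd <- length(d)
  if (nd == 4L) {
    matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  } else {
    matrix(aperm(x, c(1, 3, 2)), d[1] * d[3], d[2])
  }
}

.from_mat <- function(m, sp, B) {
  C <- ncol(m)
  if (length(sp) == 2L) {
    aperm(array(m, dim = c(sp[1], sp[2], B, C)), c(1, 2, 4, 3))
  } else {
    aperm(array(m, dim = c(sp[1], B, C)), c(1, 3, 2))
  }
}

# forward through encoder + all branches; returns list of per-branch matrices
.net_fwd <- function(net, x_mat, sh, training) {
  enc <- .seq_fwd(net$encoder, x_mat, sh, training)
  outs <- lapply(net$branches, function(br)
    .seq_fwd(br, enc$x, enc$sh, training))
  list(outs = lapply(outs, `[[`, "x"),
       sh_out = outs[[1]]$sh, sh_bottleneck = enc$sh)
}

.net_bwd <- function(net, dys) {
  d_bottleneck <- NULL
  for (i in seq_along(net$branches)) {
    db <- .seq_bwd(net$branches[[i]], dys[[i]])
    d_bottleneck <- if (is.null(d_bottleneck)) db else d_bottleneck + db
  }
  invisible(.seq_bwd(net$encoder, d_bottleneck))
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(net) {
  for (lay in .net_layers(net)) {
    for (p in lay$params) {
      lay[[paste0("m_", p)]] <- lay[[p]] * 0
      lay[[paste0("v_", p)]] <- lay[[p]] * 0
    }
  }
  net$adam_t <- 0L
  invisible(net)
}

.adam_step <- function(net, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  net$adam_t <- net$adam_t + 1L
  t <- net$adam_t
  for (lay in .net_layers(net)) {
    for (p in lay$params) {
      g <- lay[[paste0("g", p)]]
      if (is.null(g)) next
      m <- lay[[paste0("m_", p)]]; v <- lay[[paste0("v_", p)]]
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      lay[[paste0("m_", p)]] <- m
      lay[[paste0("v_", p)]] <- v
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      lay[[p]] <- lay[[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(net)
}

# ---- (de)serialization of parameters ---------------------------------------

.net_state <- function(net) {
  lapply(.net_layers(net), function(lay) {
    s <- lapply(lay$params, function(p) lay[[p]])
    names(s) <- lay$params
    s$.run_mean <- lay$run_mean
    s$.run_var <- lay$run_var
    s
  })
}

.net_restore <- function(net, state) {
  lays <- .net_layers(net)
  stopifnot(length(lays) == length(state))
  for (i in seq_along(lays)) {
    for (p in lays[[i]]$params) lays[[i]][[p]] <- state[[i]][[p]]
    if (!is.null(state[[i]]$.run_mean)) {
      lays[[i]]$run_mean <- state[[i]]$.run_mean
      lays[[i]]$run_var <- state[[i]]$.run_var
    }
  }
  invisible(net)
}
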