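# Convolutional encoder-decoder separation networks (2D image-domain and
# 1D TAC-domain): architecture, multi-tracer MSE loss, Adam training loop.

#' CED configuration
#'
#' Architecture and optimisation settings for the encoder-decoder separation
#' network. The 2D defaults (depth 4, base width 24, doubling per level)
#' put the trainable-parameter count near 2e6, matching published
#' image-domain separation networks; for the 1D TAC-domain variant use
#' depth 2 (28 frames admit two 2x poolings) and base width 96, which lands
#' near 8e5. Training
#' follows Adam with learning rate 5e-4, batch size 8, up to 1500 epochs
#' with early stopping on the validation loss.
#'
#' @param n_frames input frame count L (channels of the input stack).
#' @param n_tracers number of decoder branches N (1, 2 or 3).
#' @param depth number of encoder levels (2x downsamplings).
#' @param base_width channels of the first encoder level; doubled per level.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement); ignored when no validation pairs are supplied.
#' @param seed integer seed controlling initialisation and batching.
#' @param normalize divide inputs and labels by one global activity scale
#'   (the mean absolute training-input value) during training and invert the
#'   scaling exactly on network outputs. Keeps the optimisation
#'   well-conditioned at the stated learning rate while outputs remain
#'   quantitative; set `FALSE` to train in raw activity units.
#' @return A `ced_config` list.
#' @export
ced_config <- function(n_frames = 28L, n_tracers = 3L, depth = 4L,
                       base_width = 24L, lr = 5e-4, batch_size = 8L,
                       epochs = 1500L, patience = 50L, seed = 1L,
                       normalize = TRUE) {
  stopifnot(n_frames >= 1, n_tracers %in% 1:3, depth >= 1, base_width >= 1,
            lr > 0, batch_size >= 1, epochs >= 1)
  structure(list(n_frames = as.integer(n_frames),
                 n_tracers = as.integer(n_tracers),
                 depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed), normalize = isTRUE(normalize)),
            class = "ced_config")
}

#' Build a convolutional encoder-decoder separation network
#'
#' One shared encoder and `n_tracers` tracer-specific decoder branches.
#' Each encoder level applies two 3x3 convolutions (each followed by batch
#' normalisation and PReLU) and a max-pooling downsampling followed by batch
#' normalisation and PReLU; each decoder level applies a 3x3 transposed
#' convolution (stride 2) for upsampling and two 3x3 convolutions with batch
#' normalisation and PReLU; every branch ends in a 1x1 convolution to L
#' output channels and a ReLU enforcing non-negative activity. `dims = 1`
#' replaces every 2D module with its 1D counterpart.
#'
#' @param config a [ced_config()].
#' @param dims 2 (image-domain, frames as channels) or 1 (TAC-domain).
#' @return A `ced_network` (parameters initialised by Xavier sampling under
#'   `config$seed`).
#' @export
build_ced <- function(config = ced_config(), dims = 2L) {
  stopifnot(dims %in% c(1L, 2L))
  taps <- if (dims == 2L) 9L else 3L
  L <- config$n_frames
  # 2D: frames are input/output channels over the image plane.
  # 1D: time is the (single) spatial axis, one input/output channel.
  c_io <- if (dims == 2L) L else 1L
  widths <- config$base_width * 2L^(seq_len(config$depth) - 1L)
  .with_seed(config$seed, {
    encoder <- list()
    c_prev <- c_io
    for (w in widths) {
      encoder <- c(encoder, list(
        .layer_conv(c_prev, w, taps), .layer_bn(w), .layer_prelu(),
        .layer_conv(w, w, taps), .layer_bn(w), .layer_prelu(),
        .layer_pool(), .layer_bn(w), .layer_prelu()))
      c_prev <- w
    }
    branches <- lapply(seq_len(config$n_tracers), function(i) {
      br <- list()
      c_in <- widths[config$depth]
      for (lvl in rev(seq_len(config$depth))) {
        c_out <- if (lvl > 1L) widths[lvl - 1L] else config$base_width
        br <- c(br, list(
          .layer_tconv(c_in, c_out, taps),
          .layer_conv(c_out, c_out, taps), .layer_bn(c_out), .layer_prelu(),
          .layer_conv(c_out, c_out, taps), .layer_bn(c_out), .layer_prelu()))
        c_in <- c_out
      }
      c(br, list(.layer_conv1x1(c_in, c_io), .layer_relu()))
    })
    net <- new.env(parent = emptyenv())
    net$encoder <- encoder
    net$branches <- branches
    net$config <- config
    net$dims <- as.integer(dims)
    net$trained_epochs <- 0L
    .adam_init(net)
    class(net) <- "ced_network"
    net
  })
}

#' Number of trainable parameters of a network
#' @param net a `ced_network`.
#' @return Integer parameter count (weights, biases, BN affine, PReLU).
#' @export
ced_n_params <- function(net) {
  sum(vapply(.net_layers(net), function(lay)
    sum(vapply(lay$params, function(p) length(lay[[p]]), integer(1))),
    integer(1)))
}

#' @export
print.ced_network <- function(x, ...) {
  cat(sprintf("ced_network (%dD): %d frames -> %d tracer branch(es), depth %d, base width %d\n",
              x$dims, x$config$n_frames, x$config$n_tracers,
              x$config$depth, x$config$base_width))
  cat(sprintf("  %s trainable parameters; trained %d epochs\n",
              format(ced_n_params(x), big.mark = ","), x$trained_epochs))
  invisible(x)
}

# Check input spatial size against the downsampling depth.
.check_dims <- function(net, sp) {
  if (any(sp %% 2L^net$config$depth != 0L))
    stop("input size ", paste(sp, collapse = "x"),
         " is not divisible by 2^depth = ", 2L^net$config$depth)
}

# Stack a list of (H,W,L) or (L,) examples into the batched array the
# engine consumes: (H,W,L,B) or (L,1,B).
.stack_inputs <- function(inputs, dims) {
  B <- length(inputs)
  if (dims == 2L) {
    d <- dim(inputs[[1]])
    out <- array(0, dim = c(d[1], d[2], d[3], B))
    for (b in seq_len(B)) out[, , , b] <- inputs[[b]]
  } else {
    L <- length(inputs[[1]])
    out <- array(0, dim = c(L, 1L, B))
    for (b in seq_len(B)) out[, 1L, b] <- inputs[[b]]
  }
  out
}

# forward pass on a stacked batch; returns list of per-branch stacked arrays
.ced_forward <- function(net, batch, training = FALSE) {
  d <- dim(batch)
  if (net$dims == 2L) {
    sp <- d[1:2]; B <- d[4]
  } else {
    sp <- d[1]; B <- d[3]
  }
  .check_dims(net, sp)
  res <- .net_fwd(net, .to_mat(batch), list(sp = sp, B = B), training)
  list(outs = lapply(res$outs, .from_mat, sp = sp, B = B),
       outs_mat = res$outs, sp = sp, B = B)
}

#' Train a separation network
#'
#' Minimises the summed per-tracer mean squared error
#' \deqn{L_{total} = \sum_{n=1}^{N} \frac{1}{S}\sum_{s=1}^{S}
#'   \lVert C^{(n)}_s - \hat C^{(n)}_s \rVert_2^2}
#' over training pairs (multi-tracer input, per-tracer labels) with Adam.
#' Records train/validation loss per epoch; with validation pairs, stops
#' early after `patience` epochs without improvement and restores the
#' best-validation weights. Fully seeded: initialisation and batch order
#' derive from `net$config$seed`.
#'
#' @param net a `ced_network` from [build_ced()].
#' @param train_x list of input arrays (`H x W x L` for 2D, length-L vectors
#'   for 1D).
#' @param train_y list (one element per tracer branch) of lists of label
#'   arrays matching `train_x`.
#' @param val_x,val_y optional validation pairs in the same layout.
#' @param epochs,lr,batch_size optional overrides of the config values.
#' @param verbose print a progress line every 50 epochs.
#' @return The trained network (invisibly modified in place), with
#'   `net$history` (data frame epoch/train_loss/val_loss) attached.
#' @export
train_ced <- function(net, train_x, train_y, val_x = NULL, val_y = NULL,
                      epochs = net$config$epochs, lr = net$config$lr,
                      batch_size = net$config$batch_size, verbose = FALSE) {
  stopifnot(inherits(net, "ced_network"), length(train_x) >= 1,
            length(train_y) == net$config$n_tracers)
  S <- length(train_x)
  for (yy in train_y) stopifnot(length(yy) == S)
  has_val <- !is.null(val_x) && length(val_x) > 0
  N <- net$config$n_tracers
  # one global activity scale, inverted exactly at separation time
  sc <- 1
  if (isTRUE(net$config$normalize)) {
    sc <- mean(vapply(train_x, function(a) mean(abs(a)), numeric(1)))
    if (!is.finite(sc) || sc <= 0) sc <- 1
  }
  net$norm_scale <- sc
  hist_tr <- hist_va <- numeric(0)
  best_val <- Inf; best_state <- NULL; stall <- 0L
  .with_seed(net$config$seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(S)
      ep_loss <- 0
      for (start in seq(1L, S, by = batch_size)) {
        sel <- ord[start:min(start + batch_size - 1L, S)]
        xb <- .stack_inputs(train_x[sel], net$dims) / sc
        fw <- .ced_forward(net, xb, training = TRUE)
        dys <- vector("list", N)
        for (n in seq_len(N)) {
          lab <- .to_mat(.stack_inputs(train_y[[n]][sel], net$dims)) / sc
          diff <- fw$outs_mat[[n]] - lab
          ep_loss <- ep_loss + sum(diff * diff)
          dys[[n]] <- 2 * diff / S        # d(L_total)/d(pred), Σ_s ||.||² / S
        }
        .net_bwd(net, dys)
        .adam_step(net, lr)
      }
      ep_loss <- ep_loss / S
      if (!is.finite(ep_loss))
        stop("training diverged: non-finite loss at epoch ", ep,
             " (lr = ", lr, ")")
      hist_tr <- c(hist_tr, ep_loss)
      va <- NA_real_
      if (has_val) {
        va <- ced_loss(net, val_x, val_y)
        if (va < best_val - 1e-12) {
          best_val <- va; best_state <- .net_state(net); stall <- 0L
        } else stall <- stall + 1L
      }
      hist_va <- c(hist_va, va)
      if (verbose && ep %% 50L == 0L)
        message(sprintf("epoch %d: train %.4g val %.4g", ep, ep_loss, va))
      net$trained_epochs <- net$trained_epochs + 1L
      if (has_val && stall >= net$config$patience) break
    }
  })
  if (has_val && !is.null(best_state)) .net_restore(net, best_state)
  net$history <- data.frame(epoch = seq_along(hist_tr),
                            train_loss = hist_tr, val_loss = hist_va)
  invisible(net)
}

#' Evaluate the multi-tracer MSE loss on a set of pairs
#'
#' @param net a `ced_network`.
#' @param xs list of inputs; `ys` list-per-tracer of labels.
#' @param ys labels, as in [train_ced()].
#' @return Scalar L_total (evaluation mode, running BN statistics).
#' @export
ced_loss <- function(net, xs, ys) {
  S <- length(xs)
  sc <- if (is.null(net$norm_scale)) 1 else net$norm_scale
  total <- 0
  for (s in seq_len(S)) {
    fw <- .ced_forward(net, .stack_inputs(xs[s], net$dims) / sc,
                       training = FALSE)
    for (n in seq_len(net$config$n_tracers)) {
      lab <- .to_mat(.stack_inputs(ys[[n]][s], net$dims)) / sc
      d <- fw$outs_mat[[n]] - lab
      total <- total + sum(d * d)
    }
  }
  total / S
}

#' Separate a multi-tracer image or TAC with a trained network
#'
#' @param net a `ced_network`.
#' @param input `H x W x L` dynamic image (2D nets) or length-L TAC
#'   (1D nets).
#' @param schedule optional `frame_schedule` carried into the result.
#' @return A `separation_result` with per-tracer non-negative outputs
#'   (`tracers`: arrays for 2D, vectors for 1D), named after the branch
#'   index (`tracer_1`, ...) or by `names(net$tracer_names)` when set.
#' @export
separate_ced <- function(net, input, schedule = NULL) {
  stopifnot(inherits(net, "ced_network"))
  if (net$dims == 2L) {
    d <- dim(input)
    if (is.null(d) || length(d) != 3L || d[3] != net$config$n_frames)
      stop("input must be an H x W x ", net$config$n_frames, " array")
  } else {
    if (length(input) != net$config$n_frames)
      stop("input TAC must have length ", net$config$n_frames)
  }
  sc <- if (is.null(net$norm_scale)) 1 else net$norm_scale
  fw <- .ced_forward(net, .stack_inputs(list(input), net$dims) / sc,
                     training = FALSE)
  outs <- lapply(fw$outs, function(a) {
    sc * if (net$dims == 2L) a[, , , 1L] else a[, 1L, 1L]
  })
  nms <- net$tracer_names
  names(outs) <- if (!is.null(nms)) nms
    else paste0("tracer_", seq_along(outs))
  structure(list(method = sprintf("CED %dD", net$dims), tracers = outs,
                 parametric = NULL, report = NULL, schedule = schedule,
                 specs = NULL, config = net$config),
            class = "separation_result")
}

#' Save / load a network checkpoint
#'
#' Stores parameters, configuration, dims, seed, epoch count and history.
#' @param net a `ced_network`.
#' @param path RDS file path.
#' @export
save_ced <- function(net, path) {
  saveRDS(list(state = .net_state(net), config = net$config,
               dims = net$dims, trained_epochs = net$trained_epochs,
               history = net$history, tracer_names = net$tracer_names,
               norm_scale = net$norm_scale),
          path)
  invisible(path)
}

#' @rdname save_ced
#' @export
load_ced <- function(path) {
  ck <- readRDS(path)
  net <- build_ced(ck$config, dims = ck$dims)
  .net_restore(net, ck$state)
  net$trained_epochs <- ck$trained_epochs
  net$history <- ck$history
  net$tracer_names <- ck$tracer_names
  net$norm_scale <- ck$norm_scale
  net
}
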