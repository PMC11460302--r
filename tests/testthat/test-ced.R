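# Encoder-decoder separation networks: architecture, loss, gradients,
# training behaviour.

smoke_gt <- local({
  ph <- generate_phantom(11, n_pixels = 16L)
  kin <- sample_kinetics(ph, seed = 12)
  ground_truth_images(kin, schedule = build_frame_schedule(), dt = 0.05)
})

test_that("network outputs have the right shape, are non-negative, and eval is deterministic", {
  cfg <- ced_config(n_frames = 28, n_tracers = 3, depth = 2, base_width = 4,
                    seed = 7)
  net <- build_ced(cfg, dims = 2)
  x <- smoke_gt$multi
  sep <- separate_ced(net, x)
  expect_identical(names(sep$tracers),
                   c("tracer_1", "tracer_2", "tracer_3"))
  for (a in sep$tracers) {
    expect_identical(dim(a), c(16L, 16L, 28L))
    expect_true(all(a >= 0))
  }
  sep2 <- separate_ced(net, x)
  expect_identical(sep$tracers, sep2$tracers)
  # untrained net on zero input stays non-negative
  z <- separate_ced(net, array(0, dim(x)))
  expect_true(all(vapply(z$tracers, min, numeric(1)) >= 0))
  # dimension guards
  expect_error(separate_ced(net, x[, , 1:5]), "array")
  net3 <- build_ced(ced_config(n_frames = 28, depth = 3, base_width = 2),
                    dims = 2)
  expect_error(separate_ced(net3, smoke_gt$multi[1:12, 1:12, ]),
               "divisible")
  # 1D: length-28 TAC in, three length-28 TACs out
  n1 <- build_ced(ced_config(n_frames = 28, depth = 2, base_width = 8), dims = 1)
  s1 <- separate_ced(n1, rep(1, 28))
  expect_length(s1$tracers, 3L)
  expect_true(all(vapply(s1$tracers, length, integer(1)) == 28L))
  expect_error(separate_ced(n1, rep(1, 20)), "length")
})

test_that("default trainable-parameter counts sit near the published sizes", {
  n2 <- build_ced(ced_config(), dims = 2)
  expect_gt(ced_n_params(n2), 2.1e6 / 2)
  expect_lt(ced_n_params(n2), 2.1e6 * 2)
  n1 <- build_ced(ced_config(depth = 2, base_width = 96), dims = 1)
  expect_gt(ced_n_params(n1), 7.7e5 / 2)
  expect_lt(ced_n_params(n1), 7.7e5 * 2)
})

test_that("the multi-tracer loss vanishes at the labels and sums per-tracer terms", {
  cfg <- ced_config(n_frames = 28, n_tracers = 2, depth = 2, base_width = 4,
                    seed = 9, normalize = FALSE)
  net <- build_ced(cfg, dims = 2)
  x <- smoke_gt$multi
  pred <- separate_ced(net, x)$tracers
  # labels equal to the prediction -> L_total = 0
  expect_equal(ced_loss(net, list(x), lapply(pred, list)), 0, tolerance = 1e-20)
  # loss is the sum of the two per-tracer squared errors
  y1 <- smoke_gt$singles$FDG; y2 <- smoke_gt$singles$Rb82
  want <- sum((pred[[1]] - y1)^2) + sum((pred[[2]] - y2)^2)
  expect_equal(ced_loss(net, list(x), list(list(y1), list(y2))), want,
               tolerance = 1e-10)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- ced_config(n_frames = 3, n_tracers = 2, depth = 1, base_width = 3,
                    seed = 5, normalize = FALSE)
  net <- build_ced(cfg, dims = 2)
  set.seed(9)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  labs <- list(array(runif(8 * 8 * 3), c(8, 8, 3)),
               array(runif(8 * 8 * 3), c(8, 8, 3)))
  loss_of <- function() {
    fw <- mpetsep:::.ced_forward(net, mpetsep:::.stack_inputs(list(x), 2L),
                                 training = TRUE)
    l <- 0
    for (n in 1:2) {
      lab <- mpetsep:::.to_mat(mpetsep:::.stack_inputs(labs[n], 2L))
      l <- l + sum((fw$outs_mat[[n]] - lab)^2)
    }
    list(loss = l, fw = fw)
  }
  r <- loss_of()
  dys <- lapply(1:2, function(n)
    2 * (r$fw$outs_mat[[n]] -
           mpetsep:::.to_mat(mpetsep:::.stack_inputs(labs[n], 2L))))
  mpetsep:::.net_bwd(net, dys)
  lays <- mpetsep:::.net_layers(net)
  bad <- 0L; checked <- 0L
  for (li in seq_along(lays)) {
    lay <- lays[[li]]
    followed_by_bn <- li < length(lays) && lays[[li + 1L]]$type == "bn"
    for (p in lay$params) {
      g <- lay[[paste0("g", p)]]
      n_probe <- min(length(lay[[p]]), 3L)
      for (i in seq_len(n_probe)) {
        # a conv bias feeding straight into batch norm has zero true gradient
        if (p == "b" && followed_by_bn) next
        eps <- 1e-5
        old <- lay[[p]][i]
        lay[[p]][i] <- old + eps; lp <- loss_of()$loss
        lay[[p]][i] <- old - eps; lm <- loss_of()$loss
        lay[[p]][i] <- old
        gnum <- (lp - lm) / (2 * eps)
        rel <- abs(gnum - g[i]) / max(abs(gnum), abs(g[i]), 1e-6)
        checked <- checked + 1L
        if (rel > 1e-3) bad <- bad + 1L
      }
    }
  }
  expect_gt(checked, 40L)
  expect_identical(bad, 0L)
})

test_that("one training pair is overfit: loss below 1% of initial within 500 steps", {
  labs <- lapply(smoke_gt$singles, function(a) list(a))
  cfg <- ced_config(n_frames = 28, n_tracers = 3, depth = 2, base_width = 16,
                    batch_size = 1, seed = 2)
  net <- build_ced(cfg, dims = 2)
  train_ced(net, list(smoke_gt$multi), labs, epochs = 500)
  h <- net$history$train_loss
  expect_lt(h[500] / h[1], 0.01)
  expect_true(all(is.finite(h)))
})

test_that("training is seeded-reproducible and checkpoints round-trip", {
  labs <- lapply(smoke_gt$singles, function(a) list(a))
  run <- function() {
    net <- build_ced(ced_config(n_frames = 28, n_tracers = 3, depth = 1,
                                base_width = 4, batch_size = 1, seed = 31),
                     dims = 2)
    train_ced(net, list(smoke_gt$multi), labs, epochs = 20)
    net
  }
  n1 <- run(); n2 <- run()
  expect_identical(n1$history, n2$history)
  expect_identical(separate_ced(n1, smoke_gt$multi)$tracers,
                   separate_ced(n2, smoke_gt$multi)$tracers)
  tmp <- tempfile(fileext = ".rds")
  save_ced(n1, tmp)
  n3 <- load_ced(tmp)
  expect_identical(separate_ced(n3, smoke_gt$multi)$tracers,
                   separate_ced(n1, smoke_gt$multi)$tracers)
  unlink(tmp)
})

test_that("a non-finite loss aborts with a diagnostic instead of silent NaNs", {
  labs <- lapply(smoke_gt$singles, function(a) list(a))
  labs[[2]][[1]][1, 1, 1] <- NaN
  net <- build_ced(ced_config(n_frames = 28, n_tracers = 3, depth = 1,
                              base_width = 4, batch_size = 1, seed = 1),
                   dims = 2)
  expect_error(train_ced(net, list(smoke_gt$multi), labs, epochs = 5),
               "non-finite loss")
})
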