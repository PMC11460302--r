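# Projector, count simulation, and MLEM reconstruction.

# Rotation-based oracle projector: resample the image on a rotated (t, s)
# grid by bilinear interpolation and sum over s.
.oracle_project <- function(img, theta, n_radial) {
  n <- nrow(img)
  bil <- function(cx, cy) {
    col <- cx + (n + 1) / 2; row <- cy + (n + 1) / 2
    c0 <- floor(col); r0 <- floor(row)
    fc <- col - c0; fr <- row - r0
    val <- function(rr, cc) {
      ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
      out <- numeric(length(rr))
      out[ok] <- img[cbind(rr[ok], cc[ok])]
      out
    }
    (1 - fr) * (1 - fc) * val(r0, c0) + (1 - fr) * fc * val(r0, c0 + 1) +
      fr * (1 - fc) * val(r0 + 1, c0) + fr * fc * val(r0 + 1, c0 + 1)
  }
  tgrid <- seq_len(n_radial) - (n_radial + 1) / 2
  sgrid <- seq(-n_radial, n_radial, by = 0.5)
  vapply(tgrid, function(t0) {
    cx <- t0 * cos(theta) - sgrid * sin(theta)
    cy <- t0 * sin(theta) + sgrid * cos(theta)
    sum(bil(cx, cy)) * 0.5
  }, numeric(1))
}

test_that("system matrix products match a rotation-based projector on smooth images", {
  geom <- smoke_geometry(32L)
  P <- build_system_matrix(geom)
  expect_true(all(P@x >= 0))
  n <- 32L
  cx <- rep(seq_len(n) - (n + 1) / 2, each = n)
  cy <- rep(seq_len(n) - (n + 1) / 2, times = n)
  img <- matrix(exp(-((cx - 2)^2 + (cy + 3)^2) / 32), n, n)
  sino <- matrix(as.numeric(P %*% as.vector(img)), geom$n_radial)
  for (a in c(1L, 13L, 25L, 40L)) {
    theta <- (a - 1) * pi / geom$n_angles
    want <- .oracle_project(img, theta, geom$n_radial)
    expect_lt(sqrt(sum((sino[, a] - want)^2) / sum(want^2)), 0.01)
  }
})

test_that("point sources trace sinusoids and degenerate images project to zero", {
  geom <- smoke_geometry(32L)
  P <- build_system_matrix(geom)
  img <- matrix(0, 32, 32); img[20, 26] <- 1    # row 20, col 26
  sino <- matrix(as.numeric(P %*% as.vector(img)), geom$n_radial)
  cx <- 26 - 16.5; cy <- 20 - 16.5
  for (a in seq_len(geom$n_angles)) {
    theta <- (a - 1) * pi / geom$n_angles
    t_true <- cx * cos(theta) + cy * sin(theta)
    prof <- sino[, a]
    expect_equal(sum(prof), 1)                  # unit mass at every angle
    com <- sum(prof * (seq_along(prof) - 16.5)) / sum(prof)
    expect_lt(abs(com - t_true), 0.5 + 1e-9)    # within half a bin
  }
  expect_identical(as.numeric(P %*% numeric(1024)), numeric(geom$n_radial *
                                                              geom$n_angles))
})

test_that("a centred uniform disk projects the same total at every angle", {
  geom <- smoke_geometry(32L)
  P <- build_system_matrix(geom)
  cx <- rep(seq_len(32) - 16.5, each = 32)
  cy <- rep(seq_len(32) - 16.5, times = 32)
  disk <- matrix(as.numeric(sqrt(cx^2 + cy^2) <= 10), 32, 32)
  sino <- matrix(as.numeric(P %*% as.vector(disk)), geom$n_radial)
  totals <- colSums(sino)
  expect_lt(max(abs(totals - mean(totals))) / mean(totals), 1e-6)
})

test_that("count simulation calibrates totals, background share, and linearity", {
  geom <- smoke_geometry(32L)
  P <- build_system_matrix(geom)
  act <- matrix(5, 32, 32)                      # kBq/mL everywhere
  fr <- simulate_frame_counts(act, geom, P, duration_min = 2, noisy = FALSE)
  expected_trues <- 2 * sum(act) * voxel_volume_ml(geom) * 2 * 60
  expect_equal(sum(fr$y) - sum(fr$r), expected_trues, tolerance = 1e-9)
  expect_equal(sum(fr$r) / (sum(fr$y) - sum(fr$r)), 0.2, tolerance = 1e-12)
  # doubling activity doubles expected trues exactly
  fr2 <- simulate_frame_counts(2 * act, geom, P, duration_min = 2, noisy = FALSE)
  expect_equal(sum(fr2$y) - sum(fr2$r), 2 * expected_trues, tolerance = 1e-9)
  # with background 0, expectation is exactly scale * P * x
  fr0 <- simulate_frame_counts(act, geom, P, duration_min = 2,
                               background_fraction = 0, noisy = FALSE)
  expect_equal(fr0$y, fr0$scale * as.numeric(P %*% as.vector(act)),
               tolerance = 1e-12)
  expect_true(all(fr0$r == 0))
  # zero activity -> zero counts even when noisy
  frz <- simulate_frame_counts(0 * act, geom, P, duration_min = 2, seed = 1)
  expect_true(all(frz$y == 0))
  expect_error(simulate_frame_counts(act - 10, geom, P, 1), "negative")
})

test_that("noisy totals concentrate around their Poisson mean", {
  geom <- smoke_geometry(32L)
  P <- build_system_matrix(geom)
  act <- matrix(10, 32, 32)
  mean_fr <- simulate_frame_counts(act, geom, P, duration_min = 5,
                                   noisy = FALSE)
  mu <- sum(mean_fr$y)
  expect_gt(mu, 1e4)
  for (s in 1:5) {
    noisy <- simulate_frame_counts(act, geom, P, duration_min = 5, seed = s)
    expect_lt(abs(sum(noisy$y) - mu), 4 * sqrt(mu))
    expect_true(all(noisy$y == round(noisy$y)) && all(noisy$y >= 0))
  }
  # seeded draws reproduce
  a <- simulate_frame_counts(act, geom, P, 5, seed = 7)
  b <- simulate_frame_counts(act, geom, P, 5, seed = 7)
  expect_identical(a$y, b$y)
})

test_that("MLEM is monotone in Poisson log-likelihood and converges to the truth", {
  geom <- smoke_geometry(32L)
  P <- build_system_matrix(geom)
  set.seed(31)
  truth <- matrix(runif(1024, 0, 10), 32, 32)
  sched1 <- build_frame_schedule(cbind(1, 1))
  ss <- simulate_dynamic_scan(array(truth, c(32, 32, 1)), geom, P, sched1,
                              seed = 2, noisy = TRUE)
  rec <- mlem_reconstruct(ss, P, n_iter = 128L, track_loglik = TRUE)
  ll <- attr(rec, "loglik")[1, ]
  expect_true(all(diff(ll) >= -1e-7 * abs(ll[-1])))
  expect_true(all(rec >= 0))
  # noise-free uniform disk: error decreases with iteration count
  cx <- rep(seq_len(32) - 16.5, each = 32)
  cy <- rep(seq_len(32) - 16.5, times = 32)
  disk <- matrix(8 * (sqrt(cx^2 + cy^2) <= 9), 32, 32)
  ssd <- simulate_dynamic_scan(array(disk, c(32, 32, 1)), geom, P, sched1,
                               noisy = FALSE)
  rmse <- vapply(c(8L, 32L, 128L), function(ni) {
    r <- mlem_reconstruct(ssd, P, n_iter = ni)
    sqrt(mean((r[, , 1] - disk)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
  # count conservation at convergence on noise-free data
  r128 <- mlem_reconstruct(ssd, P, n_iter = 128L)
  fr <- ssd$frames[[1]]
  fitted_counts <- fr$scale * as.numeric(P %*% as.vector(r128[, , 1])) + fr$r
  expect_lt(abs(sum(fitted_counts) - sum(fr$y)) / sum(fr$y), 0.005)
  # y = 0 with r > 0 collapses to zero after one iteration
  ss0 <- ssd
  ss0$frames[[1]]$y <- numeric(length(fr$y))
  expect_true(all(mlem_reconstruct(ss0, P, n_iter = 1L) == 0))
})

test_that("the noise-free reference is deterministic and tracks ground truth ROI TACs", {
  ex <- smoke_example(seed = 41L, n = 32L)
  geom <- smoke_geometry(32L)
  P <- build_system_matrix(geom)
  sched <- build_frame_schedule()
  gt <- ground_truth_images(ex$kinetics, schedule = sched, dt = 0.02)
  ref1 <- noise_free_reference(gt$singles$FDG, geom, P, sched, n_iter = 128L)
  ref2 <- noise_free_reference(gt$singles$FDG, geom, P, sched, n_iter = 128L)
  expect_identical(ref1, ref2)
  expect_true(all(ref1 >= 0))
  roi <- ex$phantom$roi
  tac_ref <- vapply(1:28, function(k) mean(ref1[, , k][roi]), numeric(1))
  tac_gt <- vapply(1:28, function(k) mean(gt$singles$FDG[, , k][roi]), numeric(1))
  mid <- 8:20
  expect_true(all(abs(tac_ref[mid] - tac_gt[mid]) / tac_gt[mid] < 0.10))
})

test_that("sinogram sets round-trip through serialization", {
  geom <- smoke_geometry(16L)
  P <- build_system_matrix(geom)
  sched <- build_frame_schedule(cbind(2, 0.5))
  ss <- simulate_dynamic_scan(array(1, c(16, 16, 2)), geom, P, sched, seed = 3)
  tmp <- tempfile(fileext = ".rds")
  write_sinogram_set(ss, tmp)
  expect_identical(read_sinogram_set(tmp)$frames[[1]]$y, ss$frames[[1]]$y)
  unlink(tmp)
})
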