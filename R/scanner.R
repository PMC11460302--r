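# 2D tomographic simulation and reconstruction: a parallel-beam system
# matrix, count scaling with a uniform scatter/randoms background, Poisson
# noise, and MLEM with frame-length correction.

#' Scan geometry
#'
#' Generic 2D parallel-beam geometry. The detector bin spacing equals the
#' voxel size; the default sensitivity (2 cps/kBq) sets the absolute count
#' level of the simulation together with `count_scale` in
#' [simulate_frame_counts()].
#'
#' @param n_pixels image side (square grid).
#' @param n_radial number of radial bins (default `n_pixels`).
#' @param n_angles number of projection angles over 180 degrees.
#' @param voxel_size_mm in-plane voxel size.
#' @param slice_thickness_mm slice thickness for the kBq/mL to kBq conversion
#'   (default: isotropic voxel).
#' @param sensitivity_cps_per_kbq system sensitivity (cps/kBq).
#' @return A `scan_geometry` object.
#' @export
scan_geometry <- function(n_pixels = 128L, n_radial = n_pixels,
                          n_angles = 180L, voxel_size_mm = 2.602,
                          slice_thickness_mm = voxel_size_mm,
                          sensitivity_cps_per_kbq = 2) {
  stopifnot(n_pixels > 0, n_radial > 0, n_angles > 0,
            voxel_size_mm > 0, slice_thickness_mm > 0,
            sensitivity_cps_per_kbq > 0)
  structure(list(n_pixels = as.integer(n_pixels),
                 n_radial = as.integer(n_radial),
                 n_angles = as.integer(n_angles),
                 voxel_size_mm = voxel_size_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 sensitivity_cps_per_kbq = sensitivity_cps_per_kbq),
            class = "scan_geometry")
}

#' Voxel volume in mL
#' @param geom a `scan_geometry`.
#' @return Voxel volume (mL).
#' @export
voxel_volume_ml <- function(geom)
  geom$voxel_size_mm^2 * geom$slice_thickness_mm / 1000

# CDF of the projection footprint of a unit square pixel at angle theta:
# the convolution of two boxes of widths u >= v (|cos|, |sin| sorted), a
# symmetric trapezoid of unit mass. Piecewise-quadratic, vectorized over t.
.trapezoid_cdf <- function(t, u, v) {
  h2 <- (u + v) / 2               # support half-width
  h1 <- (u - v) / 2               # plateau half-width
  out <- numeric(length(t))
  if (v < 1e-12) {                # axis-aligned: plain box of width u
    out <- pmin(pmax(t / u + 0.5, 0), 1)
    return(out)
  }
  neg <- t < 0
  ta <- abs(t)
  ramp <- ta > h1 & ta < h2
  mid <- ta <= h1
  upper <- numeric(length(t))     # F(|t|) for the upper half
  upper[ta >= h2] <- 1
  upper[ramp] <- 1 - (h2 - ta[ramp])^2 / (2 * u * v)
  upper[mid] <- 0.5 + ta[mid] / u
  out <- ifelse(neg, 1 - upper, upper)
  out
}

#' Build the parallel-beam system matrix
#'
#' Sparse projector `P` (rows: radial bin x angle; columns: image voxels).
#' The entry for (bin, voxel) at each angle is the exact integral over the
#' bin of the voxel's square footprint projected onto the detector axis (a
#' trapezoid of unit mass) — a strip-integral model for piecewise-constant
#' images. Entries are non-negative, and each voxel contributes total weight
#' 1 per angle whenever its footprint lies inside the detector, which keeps
#' per-angle totals exactly equal.
#'
#' @param geom a `scan_geometry`.
#' @param cache_path optional RDS path; if the file exists it is read back,
#'   otherwise the matrix is computed and written there.
#' @return A `dgCMatrix` of dimension `(n_radial * n_angles) x n_pixels^2`.
#' @export
build_system_matrix <- function(geom, cache_path = NULL) {
  if (!is.null(cache_path) && file.exists(cache_path)) {
    P <- readRDS(cache_path)
    stopifnot(nrow(P) == geom$n_radial * geom$n_angles)
    return(P)
  }
  n <- geom$n_pixels; nr <- geom$n_radial; na <- geom$n_angles
  # pixel centers, image-centered coordinates in bin units (bin = voxel size)
  cx <- rep(seq_len(n) - (n + 1) / 2, each = n)   # column offset
  cy <- rep(seq_len(n) - (n + 1) / 2, times = n)  # row offset
  thetas <- (seq_len(na) - 1L) * pi / na
  ii <- jj <- xx <- vector("list", na)
  J <- n * n
  jidx <- seq_len(J)
  for (a in seq_len(na)) {
    co <- cos(thetas[a]); si <- sin(thetas[a])
    u <- max(abs(co), abs(si)); v <- min(abs(co), abs(si))
    tc <- cx * co + cy * si                   # footprint centers (bin units)
    b0 <- round(tc + (nr + 1) / 2)            # nearest bin index
    base <- (a - 1L) * nr
    ia <- ja <- xa <- vector("list", 5L)
    for (k in -2:2) {
      b <- b0 + k
      d <- b - (tc + (nr + 1) / 2)            # bin center minus footprint center
      w <- .trapezoid_cdf(d + 0.5, u, v) - .trapezoid_cdf(d - 0.5, u, v)
      keep <- w > 1e-14 & b >= 1 & b <= nr
      ia[[k + 3L]] <- base + b[keep]
      ja[[k + 3L]] <- jidx[keep]
      xa[[k + 3L]] <- w[keep]
    }
    ii[[a]] <- unlist(ia); jj[[a]] <- unlist(ja); xx[[a]] <- unlist(xa)
  }
  P <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nr * na, J))
  if (!is.null(cache_path)) saveRDS(P, cache_path)
  P
}

#' Simulate the projection counts of one time frame
#'
#' The expected true counts total
#' `count_scale * sensitivity * (total activity in kBq) * duration_s` and are
#' distributed over sinogram bins proportionally to `P %*% x`. A uniform
#' background expectation `r` (scatter + randoms model) adds
#' `background_fraction` of the trues. With `noisy = TRUE` every bin is an
#' independent Poisson draw of its expectation.
#'
#' @param activity `n x n` activity image (kBq/mL, frame-averaged).
#' @param geom a `scan_geometry`.
#' @param P system matrix from [build_system_matrix()].
#' @param duration_min frame duration (min).
#' @param background_fraction background expectation as a fraction of the
#'   expected trues (default 0.2).
#' @param count_scale extra multiplier on the expected trues (default 1).
#' @param seed optional integer seed for the Poisson draw.
#' @param noisy draw Poisson counts (`TRUE`) or return expectations.
#' @return List: `y` (counts or expectations), `r` (background expectation),
#'   `scale` (expected counts per unit of `P %*% x`; converts reconstructed
#'   counts back to activity), `duration_min`.
#' @export
simulate_frame_counts <- function(activity, geom, P, duration_min,
                                  background_fraction = 0.2,
                                  count_scale = 1, seed = NULL,
                                  noisy = TRUE) {
  if (any(activity < 0)) stop("negative activity")
  if (background_fraction < 0) stop("background_fraction must be >= 0")
  q <- as.numeric(P %*% as.vector(activity))
  n_bins <- length(q)
  total_kbq <- sum(activity) * voxel_volume_ml(geom)
  T_total <- count_scale * geom$sensitivity_cps_per_kbq * total_kbq *
    duration_min * 60
  sq <- sum(q)
  scale <- if (sq > 0) T_total / sq else 0
  trues <- scale * q
  r <- rep(background_fraction * T_total / n_bins, n_bins)
  mean_y <- trues + r
  y <- if (noisy) {
    if (!is.null(seed)) .with_seed(seed, rpois(n_bins, mean_y))
    else rpois(n_bins, mean_y)
  } else mean_y
  list(y = y, r = r, scale = scale, duration_min = duration_min)
}

#' Simulate a full dynamic scan
#'
#' Applies [simulate_frame_counts()] to every frame of a dynamic activity
#' image. Per-frame seeds are derived from `seed` so realisations are
#' reproducible frame by frame.
#'
#' @param images `n x n x K` frame-averaged activity array (kBq/mL).
#' @param geom a `scan_geometry`.
#' @param P system matrix.
#' @param schedule the matching `frame_schedule`.
#' @param background_fraction,count_scale,noisy see [simulate_frame_counts()].
#' @param seed integer seed (omit for expectation-only scans).
#' @return A `sinogram_set`: list with `frames` (per-frame lists), `schedule`,
#'   `geom`, `noisy`, `seed`.
#' @export
simulate_dynamic_scan <- function(images, geom, P, schedule,
                                  background_fraction = 0.2, count_scale = 1,
                                  seed = NULL, noisy = TRUE) {
  K <- nrow(schedule)
  stopifnot(dim(images)[3] == K)
  durs <- frame_durations(schedule)
  frames <- lapply(seq_len(K), function(k)
    simulate_frame_counts(images[, , k], geom, P, durs[k],
                          background_fraction = background_fraction,
                          count_scale = count_scale,
                          seed = if (is.null(seed)) NULL else seed + 1000L * k,
                          noisy = noisy))
  structure(list(frames = frames, schedule = schedule, geom = geom,
                 noisy = noisy, seed = seed),
            class = "sinogram_set")
}

# One-frame MLEM in count space: x <- x / (P^T 1) * P^T (y / (P x + r)).
.mlem_frame <- function(y, r, P, sens, n_iter, track_loglik = FALSE) {
  J <- ncol(P)
  x <- rep(1, J)
  live <- sens > 0
  ll <- if (track_loglik) numeric(n_iter) else NULL
  for (it in seq_len(n_iter)) {
    yb <- as.numeric(P %*% x) + r
    ratio <- ifelse(yb > 0, y / yb, 0)
    upd <- as.numeric(Matrix::crossprod(P, ratio))
    x[live] <- x[live] / sens[live] * upd[live]
    x[!live] <- 0
    if (track_loglik) {
      yb2 <- as.numeric(P %*% x) + r
      ll[it] <- sum(ifelse(y > 0, y * log(yb2), 0)) - sum(yb2)
    }
  }
  list(x = x, loglik = ll)
}

#' MLEM reconstruction of a dynamic scan
#'
#' Per-frame multiplicative MLEM (uniform initialisation, no post-smoothing),
#' with the background expectation `r` taken as known. The count-space
#' solution is divided by each frame's count scale, yielding frame-length-
#' corrected activity images (kBq/mL).
#'
#' @param sinograms a `sinogram_set`.
#' @param P the system matrix used for simulation.
#' @param n_iter MLEM iterations (default 128).
#' @param track_loglik record the Poisson log-likelihood after each iteration
#'   of each frame (attribute `"loglik"`, a K x n_iter matrix).
#' @return `n x n x K` activity array (non-negative).
#' @export
mlem_reconstruct <- function(sinograms, P, n_iter = 128L,
                             track_loglik = FALSE) {
  stopifnot(inherits(sinograms, "sinogram_set"))
  geom <- sinograms$geom
  n <- geom$n_pixels
  K <- length(sinograms$frames)
  sens <- as.numeric(Matrix::crossprod(P, rep(1, nrow(P))))
  out <- array(0, dim = c(n, n, K))
  ll <- if (track_loglik) matrix(NA_real_, K, n_iter) else NULL
  for (k in seq_len(K)) {
    fr <- sinograms$frames[[k]]
    if (fr$scale == 0 || sum(fr$y) == 0) next   # no signal in this frame
    res <- .mlem_frame(fr$y, fr$r, P, sens, n_iter, track_loglik)
    out[, , k] <- matrix(res$x / fr$scale, n, n)
    if (track_loglik) ll[k, ] <- res$loglik
  }
  if (track_loglik) attr(out, "loglik") <- ll
  out
}

#' Noise-free MLEM reference reconstruction
#'
#' MLEM applied to the expectation sinograms (no Poisson sampling) of a
#' dynamic activity image; the standard reference for bias/SD evaluation.
#'
#' @param images `n x n x K` ground-truth activity array.
#' @param geom,P,schedule as in [simulate_dynamic_scan()].
#' @param background_fraction,count_scale see [simulate_frame_counts()].
#' @param n_iter MLEM iterations (default 128).
#' @return `n x n x K` activity array; bitwise reproducible.
#' @export
noise_free_reference <- function(images, geom, P, schedule,
                                 background_fraction = 0.2, count_scale = 1,
                                 n_iter = 128L) {
  ss <- simulate_dynamic_scan(images, geom, P, schedule,
                              background_fraction = background_fraction,
                              count_scale = count_scale, noisy = FALSE)
  mlem_reconstruct(ss, P, n_iter = n_iter)
}

#' Serialize / load a sinogram set
#'
#' Frames, background expectations and the schedule in one RDS file.
#' @param sinograms a `sinogram_set`.
#' @param path file path.
#' @export
write_sinogram_set <- function(sinograms, path) {
  saveRDS(sinograms, path)
  invisible(path)
}

#' @rdname write_sinogram_set
#' @export
read_sinogram_set <- function(path) readRDS(path)
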