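# Quantitative evaluation over repeated noise realisations: voxel-level and
# ROI-level bias / standard deviation / NRMSE against a noise-free
# reference, plus parametric-map estimation from separated images.

#' Voxel-level bias, SD and NRMSE over noise realisations
#'
#' With \eqn{\bar x_j} the across-realisation mean at voxel j and
#' \eqn{x^{Ref}} the reference (typically the single-tracer noise-free MLEM
#' reconstruction), over the pooled region \eqn{\Omega} (all ROI voxels of
#' all frames):
#' \deqn{Bias = 100 \sqrt{\frac{\sum_\Omega (\bar x_j - x_j^{Ref})^2}
#'   {\sum_\Omega (x_j^{Ref})^2}}, \quad
#'   SD = 100 \sqrt{\frac{\frac1R \sum_r \sum_\Omega (\bar x_j - x_j^r)^2}
#'   {\sum_\Omega (x_j^{Ref})^2}}, \quad
#'   NRMSE = \sqrt{Bias^2 + SD^2}.}
#' The squared residual inside the SD sum makes the three quantities satisfy
#' the NRMSE identity exactly.
#'
#' @param realisations list of R dynamic arrays (`n x n x K`), one per noise
#'   realisation of the separated/reconstructed image.
#' @param reference reference dynamic array of the same shape.
#' @param roi logical matrix of myocardium voxels; all frames are pooled.
#' @return A `metric_result`: list with `bias`, `sd`, `nrmse` (percent),
#'   `R`, `n_omega`.
#' @export
voxel_metrics <- function(realisations, reference, roi) {
  R <- length(realisations)
  if (R < 2) stop("need at least 2 noise realisations")
  stopifnot(is.logical(roi))
  if (!any(roi)) stop("roi is empty")
  K <- dim(reference)[3]
  sel <- which(rep(as.vector(roi), K))
  ref <- as.vector(reference)[sel]
  if (all(ref == 0)) stop("reference is zero everywhere in the roi")
  xs <- vapply(realisations, function(a) as.vector(a)[sel],
               numeric(length(sel)))
  xbar <- rowMeans(xs)
  denom <- sum(ref^2)
  bias <- 100 * sqrt(sum((xbar - ref)^2) / denom)
  sdv <- 100 * sqrt(sum((xs - xbar)^2) / R / denom)
  structure(list(bias = bias, sd = sdv, nrmse = sqrt(bias^2 + sdv^2),
                 R = R, n_omega = length(sel)),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("bias %.2f%%  SD %.2f%%  NRMSE %.2f%%  (R = %d, |Omega| = %d)\n",
              x$bias, x$sd, x$nrmse, x$R, x$n_omega))
  invisible(x)
}

#' Extract the ROI-mean TAC of a dynamic image
#'
#' @param image `n x n x K` dynamic array.
#' @param roi logical matrix.
#' @return Length-K vector: mean ROI uptake per frame.
#' @export
extract_roi_tac <- function(image, roi) {
  stopifnot(is.logical(roi), any(roi))
  K <- dim(image)[3]
  vapply(seq_len(K), function(k) mean(image[, , k][roi]), numeric(1))
}

#' ROI-TAC bias, SD and NRMSE per frame
#'
#' With \eqn{\bar c} the across-realisation mean ROI TAC and \eqn{c^{Ref}}
#' the reference ROI TAC, per frame:
#' \deqn{Bias_{TAC} = 100 |\bar c - c^{Ref}| / c^{Ref}, \quad
#'   SD_{TAC} = \frac{100}{c^{Ref}} \sqrt{\frac1R \sum_r (c^r - \bar c)^2},
#'   \quad NRMSE_{TAC} = \sqrt{Bias_{TAC}^2 + SD_{TAC}^2}.}
#' Frames with a zero reference value are flagged `NA` and excluded from the
#' summary.
#'
#' @param realisation_tacs list of R length-K TAC vectors (or an R x K
#'   matrix).
#' @param reference_tac length-K reference TAC.
#' @return A `roi_tac_metrics`: list with per-frame `bias`, `sd`, `nrmse`
#'   (percent), `R`, and `nrmse_summary` (median over valid frames).
#' @export
roi_tac_metrics <- function(realisation_tacs, reference_tac) {
  cm <- if (is.matrix(realisation_tacs)) realisation_tacs
        else do.call(rbind, realisation_tacs)
  R <- nrow(cm)
  if (R < 2) stop("need at least 2 noise realisations")
  K <- length(reference_tac)
  stopifnot(ncol(cm) == K)
  cbar <- colMeans(cm)
  valid <- reference_tac > 0
  bias <- sdv <- rep(NA_real_, K)
  bias[valid] <- 100 * abs(cbar[valid] - reference_tac[valid]) /
    reference_tac[valid]
  sdv[valid] <- 100 / reference_tac[valid] *
    sqrt(colMeans(sweep(cm, 2, cbar)^2))[valid]
  nrmse <- sqrt(bias^2 + sdv^2)
  structure(list(bias = bias, sd = sdv, nrmse = nrmse, R = R,
                 valid = valid,
                 nrmse_summary = stats::median(nrmse[valid])),
            class = "roi_tac_metrics")
}

#' Duration-weighted static image over a late time window
#'
#' Frame integration of the frames lying inside `[t_start, t_end]` (the
#' default covers the final 20 min of the standard 60-min schedule, i.e.
#' the two 10-min frames), weighted by frame duration.
#'
#' @param image `n x n x K` dynamic array.
#' @param schedule the matching `frame_schedule`.
#' @param t_start,t_end window (min).
#' @return Static `n x n` activity matrix.
#' @export
static_frame_integral <- function(image, schedule, t_start = 40, t_end = 60) {
  sel <- which(schedule$start >= t_start - 1e-9 &
                 schedule$end <= t_end + 1e-9)
  if (!length(sel)) stop("no frames inside the static window")
  durs <- frame_durations(schedule)[sel]
  out <- matrix(0, dim(image)[1], dim(image)[2])
  for (i in seq_along(sel)) out <- out + durs[i] * image[, , sel[i]]
  out / sum(durs)
}

#' Parametric maps from separated single-tracer images
#'
#' Applies the voxel-wise single-tracer compartment fit (v-STCM) to each
#' tracer's separated dynamic image to estimate parametric maps, and
#' computes the late-window static image for FDG-like tracers whose rate
#' constants are not identifiable from the scan window.
#'
#' @param separated named list of per-tracer dynamic arrays (e.g.
#'   `separation_result$tracers`).
#' @param specs matching list of [tracer_spec()].
#' @param schedule the `frame_schedule`.
#' @param roi logical matrix of voxels to fit.
#' @param config a [fit_config()].
#' @param static_window `c(t_start, t_end)` of the static integration.
#' @return List per tracer: `parametric` (maps from the v-STCM fit),
#'   `static` (static integral matrix), `report`.
#' @export
parametric_maps_from_separated <- function(separated, specs,
                                           schedule = build_frame_schedule(),
                                           roi, config = fit_config(),
                                           static_window = c(40, 60)) {
  stopifnot(length(separated) == length(specs))
  out <- vector("list", length(specs))
  names(out) <- vapply(specs, `[[`, "", "name")
  for (i in seq_along(specs)) {
    fit <- separate_image_mtcm(separated[[i]], specs[i], schedule,
                               roi = roi, config = config)
    out[[i]] <- list(parametric = fit$parametric[[1]],
                     static = static_frame_integral(separated[[i]], schedule,
                                                    static_window[1],
                                                    static_window[2]),
                     report = fit$report)
  }
  out
}

#' Write a table of separation metrics as CSV
#'
#' @param rows data frame with columns `method`, `tracer`, `bias`, `sd`,
#'   `nrmse`, `R`.
#' @param path file path.
#' @export
write_metrics_csv <- function(rows, path) {
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
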