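# Synthetic myocardium phantoms: ring-shaped label maps partitioned into
# angular sub-regions, region-wise Gaussian kinetic heterogeneity, and
# population-varied input functions.

# Evaluate code under a temporary RNG seed, restoring global RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate a synthetic myocardium label phantom
#'
#' Draws a ring-shaped (annular) myocardium on a square grid — a geometric
#' stand-in for short-axis myocardium segments — with randomized center,
#' radius and wall thickness, partitioned angularly into M sub-regions
#' (M uniform on 4..14) with jittered boundaries. Label 0 is background;
#' labels 1..M tile the ring. Deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param n_pixels image side (default 128).
#' @param voxel_size_mm voxel size (default 2.602 mm, scaled with `n_pixels`
#'   so the field of view is preserved at reduced grids).
#' @return A `phantom_label_map`: list with `labels` (integer matrix),
#'   `roi` (logical matrix, labels > 0), `n_regions`, `voxel_size_mm`, `seed`.
#' @export
generate_phantom <- function(seed, n_pixels = 128L,
                             voxel_size_mm = 2.602 * 128 / n_pixels) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  n <- as.integer(n_pixels)
  .with_seed(seed, {
    M <- sample(4:14, 1L)
    cx <- n / 2 + runif(1, -n / 16, n / 16)
    cy <- n / 2 + runif(1, -n / 16, n / 16)
    r_out <- runif(1, 0.28, 0.38) * n
    thick <- runif(1, 0.12, 0.20) * n
    r_in <- max(r_out - thick, 0.06 * n)
    # angular boundaries: equally spaced with jitter, strictly increasing
    base <- 2 * pi * (0:(M - 1)) / M
    jit <- runif(M, -0.25, 0.25) * 2 * pi / M
    bounds <- sort(base + jit)
    rot <- runif(1, 0, 2 * pi)

    xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
    ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
    dx <- xs - cx; dy <- ys - cy
    r <- sqrt(dx^2 + dy^2)
    ang <- (atan2(dy, dx) + rot) %% (2 * pi)
    ring <- r >= r_in & r <= r_out
    lab <- matrix(0L, n, n)
    idx <- findInterval(ang[ring], bounds)
    idx[idx == 0L] <- M                 # angles before the first boundary wrap
    lab[ring] <- idx
    # drop empty labels (possible on tiny grids) and relabel contiguously
    present <- sort(unique(lab[lab > 0L]))
    lab[lab > 0L] <- match(lab[lab > 0L], present)
    structure(list(labels = lab, roi = lab > 0L,
                   n_regions = length(present),
                   voxel_size_mm = voxel_size_mm, seed = as.integer(seed)),
              class = "phantom_label_map")
  })
}

#' @export
print.phantom_label_map <- function(x, ...) {
  cat(sprintf("phantom_label_map: %dx%d, %d sub-regions, %d ROI voxels, %.3f mm voxels\n",
              nrow(x$labels), ncol(x$labels), x$n_regions, sum(x$roi),
              x$voxel_size_mm))
  invisible(x)
}

#' Sample heterogeneous kinetic parameters over a phantom
#'
#' Each sub-region receives one independent draw per tracer per rate constant
#' from `|N(mu, (cv * mu)^2)|` around the population means (absolute value
#' taken after sampling), held constant within the region. One shared blood
#' fraction VB is drawn once per phantom. Background voxels carry zeros.
#'
#' @param phantom a `phantom_label_map`.
#' @param specs list of [tracer_spec()]; their `kinetics` provide the means.
#' @param cv coefficient of variation (default 0.1).
#' @param seed integer seed.
#' @return A `kinetic_param_map`: list with `region_params` (per tracer, an
#'   `n_regions x 4` matrix of K1, k2, k3, k4), `VB` (scalar), `maps`
#'   (per tracer, list of per-voxel parameter matrices), `VB_map`, and the
#'   phantom.
#' @export
sample_kinetics <- function(phantom, specs = default_tracers(), cv = 0.1,
                            seed = 1L) {
  stopifnot(inherits(phantom, "phantom_label_map"))
  if (cv < 0) stop("cv must be >= 0")
  M <- phantom$n_regions
  .with_seed(seed, {
    VB0 <- specs[[1]]$kinetics$VB
    VB <- min(abs(rnorm(1, VB0, cv * VB0)), 1)
    region_params <- lapply(specs, function(sp) {
      mu <- with(sp$kinetics, c(K1 = K1, k2 = k2, k3 = k3, k4 = k4))
      m <- sapply(mu, function(m0)
        if (m0 == 0) numeric(M) else abs(rnorm(M, m0, cv * m0)))
      matrix(m, nrow = M, dimnames = list(NULL, names(mu)))
    })
    names(region_params) <- vapply(specs, `[[`, "", "name")
    lab <- phantom$labels
    expand <- function(v) {
      out <- matrix(0, nrow(lab), ncol(lab))
      out[lab > 0L] <- v[lab[lab > 0L]]
      out
    }
    maps <- lapply(region_params, function(rp)
      lapply(setNames(colnames(rp), colnames(rp)), function(p) expand(rp[, p])))
    VB_map <- matrix(0, nrow(lab), ncol(lab)); VB_map[phantom$roi] <- VB
    structure(list(region_params = region_params, VB = VB, maps = maps,
                   VB_map = VB_map, phantom = phantom, cv = cv,
                   seed = as.integer(seed)),
              class = "kinetic_param_map")
  })
}

#' Population variation of Feng input parameters
#'
#' Each Feng parameter is independently resampled as
#' `sign(mu) * |N(|mu|, (cv |mu|)^2)|` (absolute value after sampling, sign
#' preserved so eigenvalues stay negative). Deterministic per seed.
#'
#' @param base a [feng_aif_params()] object (population means).
#' @param cv coefficient of variation (default 0.1).
#' @param seed integer seed.
#' @return A new [feng_aif_params()] object.
#' @export
sample_population_aif <- function(base, cv = 0.1, seed = 1L) {
  stopifnot(inherits(base, "feng_aif_params"))
  if (cv < 0) stop("cv must be >= 0")
  .with_seed(seed, {
    draw <- function(mu)
      if (mu == 0) 0 else sign(mu) * abs(rnorm(1, abs(mu), cv * abs(mu)))
    feng_aif_params(A1 = draw(base$A1), A2 = draw(base$A2), A3 = draw(base$A3),
                    p1 = draw(base$p1), p2 = draw(base$p2), p3 = draw(base$p3),
                    tau = draw(base$tau))
  })
}

#' Per-example tracer specs with population-varied input functions
#'
#' @param specs base tracer specs.
#' @param cv coefficient of variation for the AIF parameters.
#' @param seed integer seed (one sub-seed per tracer is derived from it).
#' @return List of [tracer_spec()] with resampled `aif` fields.
#' @export
vary_tracer_aifs <- function(specs, cv = 0.1, seed = 1L) {
  out <- specs
  for (i in seq_along(out))
    out[[i]]$aif <- sample_population_aif(out[[i]]$aif, cv = cv,
                                          seed = seed * 131L + i)
  out
}

#' Ground-truth dynamic activity images for one phantom example
#'
#' Synthesizes the frame-averaged single-tracer and multi-tracer activity
#' images from a sampled kinetic parameter map. Kinetics are constant within
#' each sub-region, so time-activity curves are computed once per region and
#' broadcast to voxels. Images are frame-length-corrected activity (kBq/mL),
#' non-decay-corrected. The multi-tracer image is by construction the sum of
#' the single-tracer images.
#'
#' @param kin a `kinetic_param_map`.
#' @param specs tracer specs (population or example-varied AIFs).
#' @param schedule a `frame_schedule`.
#' @param dt dense convolution step (min).
#' @return List with `singles` (list per tracer of `n x n x K` arrays),
#'   `multi` (their sum), `schedule`.
#' @export
ground_truth_images <- function(kin, specs = default_tracers(),
                                schedule = build_frame_schedule(), dt = 0.01) {
  stopifnot(inherits(kin, "kinetic_param_map"))
  ph <- kin$phantom
  lab <- ph$labels
  n <- nrow(lab)
  K <- nrow(schedule)
  tg <- dense_time_grid(schedule, dt = dt)
  VB <- kin$VB
  singles <- vector("list", length(specs))
  names(singles) <- vapply(specs, `[[`, "", "name")
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    S_i <- blood_input(specs[i], tg)
    blood_frames <- frame_average(S_i, tg, schedule)
    rp <- kin$region_params[[i]]
    img <- array(0, dim = c(n, n, K))
    for (m in seq_len(ph$n_regions)) {
      cp <- compartment_params(rp[m, "K1"], rp[m, "k2"], rp[m, "k3"],
                               rp[m, "k4"], VB)
      tac <- tissue_tac(sp, cp, tg, dt = dt)
      fr <- VB * blood_frames + (1 - VB) * frame_average(tac, tg, schedule)
      mask <- lab == m
      for (k in seq_len(K)) img[, , k][mask] <- fr[k]
    }
    singles[[i]] <- img
  }
  multi <- Reduce(`+`, singles)
  list(singles = singles, multi = multi, schedule = schedule)
}

#' Build a dataset of simulated phantom examples
#'
#' Generates `n_train + n_val + n_test` independent examples. Each example
#' gets its own phantom geometry, region kinetics, and population-varied
#' input functions, all derived deterministically from disjoint per-example
#' seeds. Ground-truth single- and multi-tracer dynamic images are produced
#' through the kinetics module.
#'
#' @param n_train,n_val,n_test split sizes (defaults 120/10/10).
#' @param seed base seed; per-example seeds are `seed + 17 * index`.
#' @param specs base tracer specs.
#' @param schedule frame schedule.
#' @param n_pixels image side.
#' @param cv coefficient of variation for kinetics and AIF population spread.
#' @param dt dense convolution step (min).
#' @param dir optional output directory; if given, each example is written to
#'   `example_<idx>.rds` and only the manifest is returned.
#' @return A `mpet_dataset`: list with `examples` (list of example lists,
#'   unless `dir` given), `manifest` (data frame: index, split, seed, path),
#'   `schedule`, `specs`.
#' @export
build_dataset <- function(n_train = 120L, n_val = 10L, n_test = 10L,
                          seed = 1L, specs = default_tracers(),
                          schedule = build_frame_schedule(),
                          n_pixels = 128L, cv = 0.1, dt = 0.01, dir = NULL) {
  n_tot <- n_train + n_val + n_test
  split <- rep(c("train", "val", "test"), times = c(n_train, n_val, n_test))
  seeds <- as.integer(seed + 17L * seq_len(n_tot))
  if (anyDuplicated(seeds)) stop("per-example seeds overlap across splits")
  manifest <- data.frame(index = seq_len(n_tot), split = split, seed = seeds,
                         path = NA_character_)
  examples <- if (is.null(dir)) vector("list", n_tot) else NULL
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_tot)) {
    ph <- generate_phantom(seeds[i], n_pixels = n_pixels)
    kin <- sample_kinetics(ph, specs = specs, cv = cv, seed = seeds[i] + 7L)
    ex_specs <- vary_tracer_aifs(specs, cv = cv, seed = seeds[i])
    gt <- ground_truth_images(kin, ex_specs, schedule, dt = dt)
    ex <- list(index = i, split = split[i], seed = seeds[i],
               phantom = ph, kinetics = kin, specs = ex_specs,
               ground_truth = gt)
    if (is.null(dir)) {
      examples[[i]] <- ex
    } else {
      p <- file.path(dir, sprintf("example_%03d.rds", i))
      saveRDS(ex, p)
      manifest$path[i] <- p
    }
  }
  out <- structure(list(examples = examples, manifest = manifest,
                        schedule = schedule, specs = specs,
                        n_pixels = as.integer(n_pixels), cv = cv, dt = dt,
                        seed = as.integer(seed)),
                   class = "mpet_dataset")
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", digits = NA)
  }
  out
}

#' Fetch dataset examples by split
#' @param dataset an `mpet_dataset`.
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @return List of example lists.
#' @export
dataset_split <- function(dataset, split) {
  idx <- which(dataset$manifest$split == split)
  if (!is.null(dataset$examples)) return(dataset$examples[idx])
  lapply(dataset$manifest$path[idx], readRDS)
}
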