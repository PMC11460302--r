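# End-to-end orchestration: dataset synthesis -> projection/noise -> MLEM ->
# separation (compartment-model and learned) -> bias/SD/NRMSE evaluation.

#' Experiment configuration
#'
#' Bundles every knob of the simulation study. The defaults reproduce the
#' full-scale study conditions: 128x128 grid with 2.602 mm voxels, the
#' staggered injection protocol (FDG -60 min, Rb82 +5 min, sestamibi
#' +15 min), the 28-frame 60-min schedule, 120/10/10 train/val/test
#' examples, R = 20 noise realisations of each test example, 128 MLEM
#' iterations, and CED training for up to 1500 epochs (Adam, lr 5e-4,
#' batch 8). `count_scale` defaults to `(n_pixels/128)^2` so per-voxel count
#' statistics are preserved when the grid is scaled down.
#'
#' @param n_pixels image side.
#' @param n_train,n_val,n_test dataset split sizes.
#' @param n_realisations noise realisations R per test example.
#' @param mlem_iter MLEM iterations.
#' @param n_angles projection angles over 180 degrees.
#' @param background_fraction scatter/randoms background as a fraction of
#'   expected trues.
#' @param count_scale multiplier on expected true counts.
#' @param methods separation methods to run; subset of
#'   `c("v-MTCM", "ROI-MTCM", "CED-2D", "CED-1D")`.
#' @param specs tracer specs (protocol).
#' @param schedule frame schedule.
#' @param fit a [fit_config()] for the compartment fits.
#' @param ced_epochs,ced_depth,ced_base_width,ced_patience CED 2D settings
#'   (the 1D net uses depth 2 / base width 96).
#' @param cv population coefficient of variation (kinetics and AIFs).
#' @param dt dense convolution step for ground-truth synthesis (min).
#' @param seed master seed; all stage seeds derive from it.
#' @param output_dir optional directory for metrics CSV + manifest JSON.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_pixels = 128L, n_train = 120L, n_val = 10L,
                              n_test = 10L, n_realisations = 20L,
                              mlem_iter = 128L, n_angles = 180L,
                              background_fraction = 0.2,
                              count_scale = (n_pixels / 128)^2,
                              methods = c("v-MTCM", "ROI-MTCM",
                                          "CED-2D", "CED-1D"),
                              specs = default_tracers(),
                              schedule = build_frame_schedule(),
                              fit = fit_config(),
                              ced_epochs = 1500L, ced_depth = 4L,
                              ced_base_width = 24L, ced_patience = 50L,
                              cv = 0.1, dt = 0.01, seed = 1L,
                              output_dir = NULL) {
  stopifnot(n_pixels %% 2L^2 == 0, n_realisations >= 2, n_test >= 1)
  structure(list(n_pixels = as.integer(n_pixels), n_train = as.integer(n_train),
                 n_val = as.integer(n_val), n_test = as.integer(n_test),
                 n_realisations = as.integer(n_realisations),
                 mlem_iter = as.integer(mlem_iter),
                 n_angles = as.integer(n_angles),
                 background_fraction = background_fraction,
                 count_scale = count_scale, methods = methods,
                 specs = specs, schedule = schedule, fit = fit,
                 ced_epochs = as.integer(ced_epochs),
                 ced_depth = as.integer(ced_depth),
                 ced_base_width = as.integer(ced_base_width),
                 ced_patience = as.integer(ced_patience),
                 cv = cv, dt = dt, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Reduced-scale preset of the experiment
#'
#' A small configuration exercising every stage end to end on one CPU in
#' minutes: 16x16 grid, 2 training / 1 validation / 1 test example, 3 noise
#' realisations, 30 MLEM iterations, a depth-2/width-16 CED trained for a
#' few hundred epochs, and a capped fit iteration budget with a 0.05-min
#' model grid.
#'
#' @param seed master seed.
#' @param ... overrides passed on to [experiment_config()].
#' @return An `experiment_config`.
#' @export
smoke_experiment_config <- function(seed = 1L, ...) {
  args <- list(n_pixels = 16L, n_train = 6L, n_val = 1L, n_test = 1L,
               n_realisations = 3L, mlem_iter = 30L, n_angles = 24L,
               fit = fit_config(max_iter = 150L, dt = 0.05),
               ced_epochs = 1500L, ced_depth = 2L, ced_base_width = 16L,
               ced_patience = 100L, dt = 0.05, seed = seed)
  do.call(experiment_config, modifyList(args, list(...)))
}

# noisy (or mean) dynamic MLEM reconstruction of one ground-truth image
.recon_dynamic <- function(images, geom, P, config, seed, noisy = TRUE) {
  ss <- simulate_dynamic_scan(images, geom, P, config$schedule,
                              background_fraction = config$background_fraction,
                              count_scale = config$count_scale,
                              seed = seed, noisy = noisy)
  mlem_reconstruct(ss, P, n_iter = config$mlem_iter)
}

# assemble training/validation reconstruction pairs for the CED nets
.build_pairs <- function(examples, geom, P, config, seed_base) {
  xs <- list(); ys <- lapply(config$specs, function(s) list())
  names(ys) <- names(config$specs)
  roi_tacs_x <- list(); roi_tacs_y <- lapply(config$specs, function(s) list())
  names(roi_tacs_y) <- names(config$specs)
  for (i in seq_along(examples)) {
    ex <- examples[[i]]
    sd <- seed_base + 97L * i
    multi_rec <- .recon_dynamic(ex$ground_truth$multi, geom, P, config, sd)
    xs[[i]] <- multi_rec
    roi_tacs_x[[i]] <- extract_roi_tac(multi_rec, ex$phantom$roi)
    for (nm in names(config$specs)) {
      single_rec <- .recon_dynamic(ex$ground_truth$singles[[nm]], geom, P,
                                   config, sd + match(nm, names(config$specs)))
      ys[[nm]][[i]] <- single_rec
      roi_tacs_y[[nm]][[i]] <- extract_roi_tac(single_rec, ex$phantom$roi)
    }
  }
  list(xs = xs, ys = ys, roi_x = roi_tacs_x, roi_y = roi_tacs_y)
}

#' Run the full simulation-separation-evaluation experiment
#'
#' Generates the dataset, simulates and reconstructs every scan, trains the
#' requested learned separators on the training reconstructions, separates
#' each test-example noise realisation with every requested method, and
#' evaluates voxel-level and ROI-level bias/SD/NRMSE against the
#' single-tracer noise-free MLEM references.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress.
#' @return An `experiment_result`: list with `metrics` (data frame: method,
#'   tracer, level, bias, sd, nrmse, R), `roi_metrics`, `networks`
#'   (trained CED nets, if any), `test_details`, `config`, `manifest`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", what, conditionMessage(e)), call. = FALSE))
  }
  specs <- config$specs
  tr_names <- names(specs)
  sched <- config$schedule

  say("dataset: %d examples at %dx%d",
      config$n_train + config$n_val + config$n_test,
      config$n_pixels, config$n_pixels)
  ds <- stage("dataset",
    build_dataset(config$n_train, config$n_val, config$n_test,
                  seed = config$seed, specs = specs, schedule = sched,
                  n_pixels = config$n_pixels, cv = config$cv, dt = config$dt))

  # in-plane voxels scale with the grid; the slice stays 2.602 mm thick so
  # (with count_scale = (n/128)^2) per-voxel count statistics match the
  # full-scale study
  geom <- scan_geometry(n_pixels = config$n_pixels,
                        n_angles = config$n_angles,
                        voxel_size_mm = 2.602 * 128 / config$n_pixels,
                        slice_thickness_mm = 2.602)
  P <- stage("projector", build_system_matrix(geom))

  train_ex <- dataset_split(ds, "train")
  val_ex <- dataset_split(ds, "val")
  test_ex <- dataset_split(ds, "test")
  # a sweep over training-set sizes trains on a prefix while the dataset
  # (and hence the test examples) stays fixed
  if (!is.null(config$train_subset))
    train_ex <- train_ex[seq_len(min(config$train_subset, length(train_ex)))]

  nets <- list()
  pairs <- NULL
  need_2d <- "CED-2D" %in% config$methods
  need_1d <- "CED-1D" %in% config$methods
  if (need_2d || need_1d) {
    say("reconstructing training pairs")
    pairs <- stage("training-pairs",
      .build_pairs(train_ex, geom, P, config, config$seed * 7L))
    vpairs <- stage("validation-pairs",
      if (length(val_ex)) .build_pairs(val_ex, geom, P, config,
                                       config$seed * 7L + 50000L) else NULL)
    if (need_2d) {
      say("training CED 2D")
      cfg2 <- ced_config(n_frames = nrow(sched), n_tracers = length(specs),
                        depth = config$ced_depth,
                        base_width = config$ced_base_width,
                        epochs = config$ced_epochs,
                        patience = config$ced_patience,
                        seed = config$seed + 11L)
      net2 <- build_ced(cfg2, dims = 2)
      net2$tracer_names <- tr_names
      stage("ced2d-training",
        train_ced(net2, pairs$xs, unname(pairs$ys),
                  val_x = vpairs$xs, val_y = if (!is.null(vpairs)) unname(vpairs$ys)))
      nets$ced2d <- net2
    }
    if (need_1d) {
      say("training CED 1D")
      cfg1 <- ced_config(n_frames = nrow(sched), n_tracers = length(specs),
                        depth = 2L, base_width = 96L,
                        epochs = config$ced_epochs,
                        patience = config$ced_patience,
                        seed = config$seed + 13L)
      net1 <- build_ced(cfg1, dims = 1)
      net1$tracer_names <- tr_names
      stage("ced1d-training",
        train_ced(net1, pairs$roi_x, unname(pairs$roi_y),
                  val_x = vpairs$roi_x,
                  val_y = if (!is.null(vpairs)) unname(vpairs$roi_y)))
      nets$ced1d <- net1
    }
  }

  say("evaluating %d test example(s) x %d realisations",
      length(test_ex), config$n_realisations)
  # per method/tracer: list over test examples of lists over realisations
  voxel_store <- list()
  roi_store <- list()
  add_vox <- function(method, tracer, ex_i, img) {
    key <- paste(method, tracer, ex_i, sep = "|")
    voxel_store[[key]] <<- c(voxel_store[[key]], list(img))
  }
  add_roi <- function(method, tracer, ex_i, tacv) {
    key <- paste(method, tracer, ex_i, sep = "|")
    roi_store[[key]] <<- c(roi_store[[key]], list(tacv))
  }
  references <- list()
  test_details <- list()

  for (ei in seq_along(test_ex)) {
    ex <- test_ex[[ei]]
    roi <- ex$phantom$roi
    # single-tracer noise-free MLEM references
    refs <- lapply(tr_names, function(nm)
      stage("reference",
        .recon_dynamic(ex$ground_truth$singles[[nm]], geom, P, config,
                       seed = NULL, noisy = FALSE)))
    names(refs) <- tr_names
    references[[ei]] <- refs
    for (r in seq_len(config$n_realisations)) {
      sd <- config$seed * 13L + 7919L * ei + 101L * r
      multi_rec <- stage("test-recon",
        .recon_dynamic(ex$ground_truth$multi, geom, P, config, sd))
      roi_tac_multi <- extract_roi_tac(multi_rec, roi)
      if ("v-MTCM" %in% config$methods) {
        # compartment fitting assumes the example's true AIFs are known
        sep <- stage("v-MTCM",
          separate_image_mtcm(multi_rec, ex$specs, sched, roi = roi,
                              config = config$fit))
        for (nm in tr_names) {
          add_vox("v-MTCM", nm, ei, sep$tracers[[nm]])
          add_roi("v-MTCM", nm, ei, extract_roi_tac(sep$tracers[[nm]], roi))
        }
      }
      if ("ROI-MTCM" %in% config$methods) {
        fit <- stage("ROI-MTCM",
          fit_roi_mtcm(roi_tac_multi, ex$specs, sched, config = config$fit))
        sep_tacs <- predict(fit)
        for (nm in tr_names) add_roi("ROI-MTCM", nm, ei, sep_tacs[[nm]])
      }
      if (need_2d) {
        sep <- stage("CED-2D", separate_ced(nets$ced2d, multi_rec, sched))
        for (nm in tr_names) {
          add_vox("CED-2D", nm, ei, sep$tracers[[nm]])
          add_roi("CED-2D", nm, ei, extract_roi_tac(sep$tracers[[nm]], roi))
        }
      }
      if (need_1d) {
        sep <- stage("CED-1D", separate_ced(nets$ced1d, roi_tac_multi, sched))
        for (nm in tr_names) add_roi("CED-1D", nm, ei, sep$tracers[[nm]])
      }
      # the unseparated noisy single-tracer MLEM, as the denoising baseline
      for (nm in tr_names) {
        single_rec <- stage("single-recon",
          .recon_dynamic(ex$ground_truth$singles[[nm]], geom, P, config,
                         sd + match(nm, tr_names)))
        add_vox("noisy-MLEM", nm, ei, single_rec)
        add_roi("noisy-MLEM", nm, ei, extract_roi_tac(single_rec, roi))
      }
    }
    test_details[[ei]] <- list(index = ex$index, seed = ex$seed, roi = roi)
  }

  say("computing metrics")
  vox_methods <- intersect(c(config$methods, "noisy-MLEM"),
                           c("v-MTCM", "CED-2D", "noisy-MLEM"))
  metrics <- do.call(rbind, lapply(vox_methods, function(me) {
    do.call(rbind, lapply(tr_names, function(nm) {
      per_ex <- vapply(seq_along(test_ex), function(ei) {
        reals <- voxel_store[[paste(me, nm, ei, sep = "|")]]
        m <- voxel_metrics(reals, references[[ei]][[nm]],
                           test_details[[ei]]$roi)
        c(m$bias, m$sd, m$nrmse)
      }, numeric(3))
      data.frame(method = me, tracer = nm, level = "voxel",
                 bias = median(per_ex[1, ]), sd = median(per_ex[2, ]),
                 nrmse = median(per_ex[3, ]), R = config$n_realisations)
    }))
  }))
  roi_methods <- intersect(c(config$methods, "noisy-MLEM"),
                           c("v-MTCM", "ROI-MTCM", "CED-2D", "CED-1D",
                             "noisy-MLEM"))
  roi_metrics <- do.call(rbind, lapply(roi_methods, function(me) {
    do.call(rbind, lapply(tr_names, function(nm) {
      per_ex <- vapply(seq_along(test_ex), function(ei) {
        reals <- roi_store[[paste(me, nm, ei, sep = "|")]]
        ref_tac <- extract_roi_tac(references[[ei]][[nm]],
                                   test_details[[ei]]$roi)
        roi_tac_metrics(reals, ref_tac)$nrmse_summary
      }, numeric(1))
      data.frame(method = me, tracer = nm, level = "roi-tac",
                 nrmse = median(per_ex), R = config$n_realisations)
    }))
  }))

  manifest <- list(seed = config$seed,
                   example_seeds = ds$manifest$seed,
                   splits = ds$manifest$split,
                   methods = config$methods,
                   n_pixels = config$n_pixels,
                   n_realisations = config$n_realisations,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  out <- structure(list(metrics = metrics, roi_metrics = roi_metrics,
                        networks = nets, references = references,
                        test_details = test_details, dataset = ds,
                        config = config, manifest = manifest),
                   class = "experiment_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_csv(metrics, file.path(config$output_dir, "metrics.csv"))
    write_metrics_csv(roi_metrics,
                      file.path(config$output_dir, "roi_metrics.csv"))
    jsonlite::write_json(manifest, file.path(config$output_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result: voxel-level NRMSE (%) medians over test examples\n")
  print(x$metrics[, c("method", "tracer", "nrmse")], row.names = FALSE)
  invisible(x)
}

#' NRMSE as a function of the number of training examples
#'
#' Retrains the image-domain separator for each training-set size on the
#' first `size` training examples and evaluates the voxel NRMSE of each
#' tracer on the fixed test set.
#'
#' @param config an [experiment_config()] (its `methods` are overridden to
#'   `"CED-2D"`).
#' @param sizes vector of training-set sizes.
#' @param verbose print stage progress.
#' @return Data frame: size, tracer, nrmse — `length(sizes) * n_tracers`
#'   rows.
#' @export
training_size_sweep <- function(config, sizes, verbose = FALSE) {
  stopifnot(all(sizes >= 1))
  if (any(sizes > config$n_train))
    stop("size exceeds the available training examples (", config$n_train, ")")
  rows <- list()
  for (s in sizes) {
    cfg <- config
    cfg$train_subset <- as.integer(s)
    cfg$methods <- "CED-2D"
    res <- run_experiment(cfg, verbose = verbose)
    m <- res$metrics[res$metrics$method == "CED-2D", ]
    rows[[length(rows) + 1L]] <- data.frame(size = s, tracer = m$tracer,
                                            nrmse = m$nrmse)
  }
  do.call(rbind, rows)
}
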