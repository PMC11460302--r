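#' @importFrom stats approx approxfun filter rnorm runif rpois setNames nlminb
#' @importFrom utils read.csv write.csv modifyList
#' @importFrom Rcpp evalCpp
#' @useDynLib mpetsep, .registration = TRUE
NULL

# ---- domain types ----------------------------------------------------------

#' Feng arterial input function parameters
#'
#' Parameter set for the standard four-exponential Feng plasma input model
#' \deqn{A(t) = (A_1 (t-\tau) - A_2 - A_3) e^{p_1 (t-\tau)} +
#'       A_2 e^{p_2 (t-\tau)} + A_3 e^{p_3 (t-\tau)}, \quad t > \tau}
#' and \eqn{A(t) = 0} for \eqn{t \le \tau}.
#'
#' @param A1 linear-rise coefficient (kBq/mL/min).
#' @param A2,A3 washout amplitudes (kBq/mL).
#' @param p1,p2,p3 eigenvalues (1/min), all negative; by convention
#'   `p1 < p2 <= p3 < 0` (fastest component first).
#' @param tau appearance delay (min); the input is identically zero up to `tau`.
#' @return An object of class `feng_aif_params`.
#' @export
feng_aif_params <- function(A1, A2, A3, p1, p2, p3, tau = 0) {
  x <- c(A1 = A1, A2 = A2, A3 = A3, p1 = p1, p2 = p2, p3 = p3, tau = tau)
  if (!all(is.finite(x)))
    stop("all Feng AIF parameters must be finite")
  if (any(c(p1, p2, p3) > 0))
    stop("Feng eigenvalues p1..p3 must be <= 0 (decaying exponentials)")
  structure(as.list(x), class = "feng_aif_params")
}

#' Two-tissue compartment parameters
#'
#' Rate constants of the two-tissue compartment model. `k4 = 0` selects the
#' irreversible topology (no release from the bound compartment).
#'
#' @param K1 delivery rate (cc/min/g).
#' @param k2 efflux rate (1/min).
#' @param k3 binding rate (1/min).
#' @param k4 release rate (1/min); 0 for the irreversible model.
#' @param VB fractional blood volume in the voxel, in (0, 1].
#' @return An object of class `compartment_params`.
#' @export
compartment_params <- function(K1, k2, k3, k4 = 0, VB = 0.38) {
  x <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4)
  if (!all(is.finite(x)) || any(x < 0))
    stop("rate constants must be finite and >= 0")
  if (!is.finite(VB) || VB <= 0 || VB > 1)
    stop("VB must lie in (0, 1]")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, VB = VB,
                 irreversible = (k4 == 0)),
            class = "compartment_params")
}

#' Tracer specification
#'
#' Bundles everything needed to synthesize one tracer's signal: radioactive
#' decay constant, injection time relative to scan start (negative for a
#' pre-scan injection), the plasma input model and the tissue kinetics.
#'
#' @param name tracer label, e.g. `"FDG"`.
#' @param lambda decay constant (1/min), `log(2) / half-life`.
#' @param injection_time injection time (min) relative to scan start.
#' @param aif a [feng_aif_params()] object.
#' @param kinetics a [compartment_params()] object (population mean kinetics).
#' @return An object of class `tracer_spec`.
#' @export
tracer_spec <- function(name, lambda, injection_time, aif, kinetics) {
  stopifnot(is.character(name), length(name) == 1L,
            is.finite(lambda), lambda > 0,
            is.finite(injection_time),
            inherits(aif, "feng_aif_params"),
            inherits(kinetics, "compartment_params"))
  structure(list(name = name, lambda = lambda,
                 injection_time = injection_time,
                 aif = aif, kinetics = kinetics),
            class = "tracer_spec")
}

#' Default triple-tracer protocol
#'
#' The staggered triple-tracer cardiac protocol: [18F]FDG injected 60 min
#' before the scan starts (off-bed uptake), 82Rb at +5 min and
#' [99mTc]sestamibi at +15 min into the 60-min dynamic scan. Kinetic means
#' are literature myocardium values (FDG and Rb irreversible, sestamibi
#' reversible two-tissue); decay constants are log(2)/109.7, log(2)/1.26 and
#' log(2)/52 per minute. The Feng input parameters are package defaults whose
#' peak times and tails qualitatively match published cardiac input functions;
#' they are exposed here so users can substitute their own.
#'
#' @return Named list of three [tracer_spec()] objects: `FDG`, `Rb82`,
#'   `sestamibi`.
#' @export
default_tracers <- function() {
  list(
    FDG = tracer_spec(
      "FDG", lambda = log(2) / 109.7, injection_time = -60,
      aif = feng_aif_params(A1 = 851.1, A2 = 21.88, A3 = 20.81,
                            p1 = -4.1339, p2 = -0.1191, p3 = -0.0104),
      kinetics = compartment_params(K1 = 0.6, k2 = 1.2, k3 = 0.1,
                                    k4 = 0, VB = 0.38)),
    Rb82 = tracer_spec(
      "Rb82", lambda = log(2) / 1.26, injection_time = 5,
      aif = feng_aif_params(A1 = 2500, A2 = 150, A3 = 50,
                            p1 = -6.0, p2 = -1.0, p3 = -0.02),
      kinetics = compartment_params(K1 = 1.4822, k2 = 0.3159, k3 = 0.004,
                                    k4 = 0, VB = 0.38)),
    sestamibi = tracer_spec(
      "sestamibi", lambda = log(2) / 52, injection_time = 15,
      aif = feng_aif_params(A1 = 2000, A2 = 80, A3 = 15,
                            p1 = -5.0, p2 = -0.8, p3 = -0.015),
      kinetics = compartment_params(K1 = 0.4, k2 = 0.094, k3 = 0.02,
                                    k4 = 0.007, VB = 0.38))
  )
}

# ---- frame schedule --------------------------------------------------------

#' Default 28-frame schedule blocks
#'
#' Block description of the 60-min dynamic schedule:
#' 1x5, 4x0.25, 2x0.5, 3x1, 1x2, 1x3, 4x0.25, 2x0.5, 3x1, 1x2, 1x3,
#' 3x5, 2x10 minutes. The two bursts of short frames follow the 82Rb and
#' sestamibi injections at 5 and 15 min.
#'
#' @return A two-column matrix with columns `count` and `duration` (min).
#' @export
default_frame_blocks <- function() {
  cbind(count    = c(1, 4, 2, 3, 1, 1, 4, 2, 3, 1, 1, 3, 2),
        duration = c(5, 0.25, 0.5, 1, 2, 3, 0.25, 0.5, 1, 2, 3, 5, 10))
}

#' Build a contiguous frame schedule from (count, duration) blocks
#'
#' @param blocks two-column matrix-like of positive integer counts and
#'   positive durations (min). Default: [default_frame_blocks()].
#' @return A `frame_schedule` data frame with columns `start` and `end`
#'   (min, half-open intervals), contiguous from 0.
#' @export
build_frame_schedule <- function(blocks = default_frame_blocks()) {
  blocks <- as.matrix(blocks)
  if (nrow(blocks) == 0L) {
    sched <- data.frame(start = numeric(0), end = numeric(0))
    class(sched) <- c("frame_schedule", "data.frame")
    return(sched)
  }
  counts <- blocks[, 1]; durs <- blocks[, 2]
  if (any(counts != round(counts)) || any(counts <= 0))
    stop("frame counts must be positive integers")
  if (any(durs <= 0)) stop("frame durations must be positive")
  d <- rep(durs, times = counts)
  ends <- cumsum(d)
  sched <- data.frame(start = c(0, ends[-length(ends)]), end = ends)
  class(sched) <- c("frame_schedule", "data.frame")
  sched
}

#' Frame durations of a schedule
#' @param schedule a `frame_schedule`.
#' @return Numeric vector of frame durations (min).
#' @export
frame_durations <- function(schedule) schedule$end - schedule$start

#' Frame mid-times of a schedule
#' @param schedule a `frame_schedule`.
#' @return Numeric vector of frame midpoints (min).
#' @export
frame_midpoints <- function(schedule) (schedule$start + schedule$end) / 2

# ---- Feng input function ---------------------------------------------------

#' Evaluate a Feng arterial input function
#'
#' @param params a [feng_aif_params()] object.
#' @param t time grid (min), sorted ascending.
#' @return Plasma concentration (kBq/mL, decay-corrected) at `t`; exactly 0
#'   for `t <= tau`.
#' @export
feng_aif <- function(params, t) {
  stopifnot(inherits(params, "feng_aif_params"))
  if (is.unsorted(t)) stop("time grid must be sorted ascending")
  u <- t - params$tau
  a <- with(params,
            (A1 * u - A2 - A3) * exp(p1 * u) +
              A2 * exp(p2 * u) + A3 * exp(p3 * u))
  a[u <= 0] <- 0
  a
}

# ---- impulse response ------------------------------------------------------

#' Two-tissue compartment impulse response
#'
#' Closed-form tissue impulse response. Irreversible (`k4 = 0`):
#' \deqn{R(t) = K_1\left[\frac{k_3}{k_2+k_3} +
#'   \frac{k_2}{k_2+k_3} e^{-(k_2+k_3)t}\right].}
#' Reversible: \deqn{R(t) = \frac{K_1}{\alpha_2-\alpha_1}
#'   \left[(k_3+k_4-\alpha_1)e^{-\alpha_1 t} +
#'         (\alpha_2-k_3-k_4)e^{-\alpha_2 t}\right]}
#' with \eqn{\alpha_{1,2} = ((k_2+k_3+k_4) \mp
#'   \sqrt{(k_2+k_3+k_4)^2 - 4 k_2 k_4})/2}.
#'
#' @param params a [compartment_params()] object.
#' @param t time grid (min, tracer time since injection).
#' @return `R(t)` at `t`; `R(0) = K1` exactly.
#' @export
impulse_response <- function(params, t) {
  stopifnot(inherits(params, "compartment_params"))
  co <- .ir_coefs(params)
  out <- co$b0 + co$b1 * exp(-co$a1 * t) + co$b2 * exp(-co$a2 * t)
  out[t == 0] <- params$K1            # b0 + b1 + b2 = K1 up to rounding
  out
}

# Decompose R(t) = b0 + b1 e^{-a1 t} + b2 e^{-a2 t}. Shared by impulse_response
# and the convolution kernels in tissue_tac.
.ir_coefs <- function(p) {
  K1 <- p$K1; k2 <- p$k2; k3 <- p$k3; k4 <- p$k4
  if (k4 == 0) {                              # irreversible
    s <- k2 + k3
    if (s == 0) return(list(b0 = K1, b1 = 0, b2 = 0, a1 = 0, a2 = 0))
    list(b0 = K1 * k3 / s, b1 = K1 * k2 / s, b2 = 0, a1 = s, a2 = 0)
  } else {                                    # reversible
    s <- k2 + k3 + k4
    disc <- s^2 - 4 * k2 * k4
    disc <- max(disc, 0)
    rt <- sqrt(disc)
    a1 <- (s - rt) / 2
    a2 <- (s + rt) / 2
    if (a2 - a1 < 1e-12) a2 <- a1 + 1e-12     # degenerate repeated root
    list(b0 = 0,
         b1 = K1 * (k3 + k4 - a1) / (a2 - a1),
         b2 = K1 * (a2 - k3 - k4) / (a2 - a1),
         a1 = a1, a2 = a2)
  }
}

# ---- dense-grid convolution machinery --------------------------------------

# Trapezoid-rule convolution of a sampled signal A (uniform step dt) with
# exp(-alpha t), via the O(n) recursion
#   y_i = e^{-alpha dt} y_{i-1} + (dt/2)(A_i + e^{-alpha dt} A_{i-1}),
# which is exactly the trapezoid quadrature of the convolution integral.
# Compiled: this is the hot loop of every kinetic model evaluation.
.conv_exp <- function(A, dt, alpha) conv_exp_cpp(A, dt, alpha)

# Cumulative trapezoid integral on a uniform grid.
.cumtrapz <- function(A, dt) cumtrapz_cpp(A, dt)

# Convolution A (x) R on a uniform grid via the exponential decomposition of R.
.conv_ir <- function(A, dt, co) {
  out <- numeric(length(A))
  if (co$b0 != 0) out <- out + co$b0 * .cumtrapz(A, dt)
  if (co$b1 != 0) out <- out + co$b1 * .conv_exp(A, dt, co$a1)
  if (co$b2 != 0) out <- out + co$b2 * .conv_exp(A, dt, co$a2)
  out
}

# ---- TAC synthesis ---------------------------------------------------------

#' Single-tracer tissue time-activity curve
#'
#' Computes the extravascular tissue term \eqn{[A \otimes R](\tau)
#' e^{-\lambda \tau}} (non-decay-corrected, without the `1 - VB` factor) on a
#' scan-time grid. Tracer time is \eqn{\tau = t - t_{inj}}; the curve is zero
#' before injection. The convolution runs on a dense uniform sub-grid
#' (`dt`, default 0.01 min) from the injection onward and is then sampled at
#' `t` by linear interpolation.
#'
#' @param spec a [tracer_spec()].
#' @param params [compartment_params()] for this voxel/region; defaults to the
#'   spec's population means.
#' @param t scan-time grid (min), sorted.
#' @param dt dense convolution step (min).
#' @return Numeric tissue activity (kBq/mL) at `t`.
#' @export
tissue_tac <- function(spec, params = spec$kinetics, t, dt = 0.01) {
  stopifnot(inherits(spec, "tracer_spec"))
  if (is.unsorted(t)) stop("time grid must be sorted ascending")
  tau_q <- t - spec$injection_time
  tmax <- max(tau_q)
  if (tmax <= 0) return(numeric(length(t)))
  n <- ceiling(tmax / dt + 1e-9)
  tau <- seq(0, by = dt, length.out = n + 1L)
  A <- feng_aif(spec$aif, tau)
  ct <- .conv_ir(A, dt, .ir_coefs(params)) * exp(-spec$lambda * tau)
  out <- approx(tau, ct, xout = tau_q, yleft = 0, rule = 2)$y
  out[tau_q <= 0] <- 0
  out
}

#' Whole-blood input signal S(t)
#'
#' Total non-decay-corrected activity concentration in whole blood at scan
#' time `t`, modeled as the sum over tracers of the plasma input evaluated at
#' tracer time and decayed: \eqn{S(t) = \sum_n A^{(n)}(t - t_n)
#' e^{-\lambda_n (t - t_n)}} (whole-blood/plasma ratio 1).
#'
#' @param specs list of [tracer_spec()] objects.
#' @param t scan-time grid (min).
#' @return Numeric blood activity (kBq/mL) at `t`.
#' @export
blood_input <- function(specs, t) {
  out <- numeric(length(t))
  for (sp in specs) {
    tau <- t - sp$injection_time
    ord <- order(tau)                 # feng_aif requires sorted input
    a <- feng_aif(sp$aif, tau[ord])
    a <- a[order(ord)]
    out <- out + a * exp(-sp$lambda * pmax(tau, 0))
  }
  out
}

#' Multi-tracer time-activity curve
#'
#' The mixed-voxel model
#' \deqn{C_{Multi}(t) = V_B S(t) + (1 - V_B) \sum_n
#'   [A^{(n)} \otimes R^{(n)}](t) e^{-\lambda_n t}}
#' with a single shared blood fraction `VB` across tracers.
#'
#' @param specs list of [tracer_spec()] objects.
#' @param params_list list of [compartment_params()], one per tracer
#'   (defaults to each spec's means).
#' @param VB shared blood volume fraction; default taken from the first
#'   tracer's kinetics.
#' @param t scan-time grid (min).
#' @param dt dense convolution step (min).
#' @return Numeric mixed activity (kBq/mL) at `t`, non-decay-corrected.
#' @export
multi_tracer_tac <- function(specs, params_list = lapply(specs, `[[`, "kinetics"),
                             VB = params_list[[1]]$VB, t, dt = 0.01) {
  if (length(specs) != length(params_list))
    stop("specs and params_list must have the same length")
  tis <- numeric(length(t))
  for (i in seq_along(specs))
    tis <- tis + tissue_tac(specs[[i]], params_list[[i]], t, dt = dt)
  VB * blood_input(specs, t) + (1 - VB) * tis
}

# ---- frame integration -----------------------------------------------------

#' Average a densely sampled TAC over scan frames
#'
#' Frame value \eqn{k} is the frame-duration-normalised integral
#' \eqn{\frac{1}{t_{k,e}-t_{k,s}} \int_{t_{k,s}}^{t_{k,e}} C(\tau) d\tau}
#' (trapezoid rule on the dense grid), i.e. the frame-length-corrected
#' activity a reconstruction of that frame estimates.
#'
#' @param values TAC samples on `t`.
#' @param t dense time grid (min) covering every frame.
#' @param schedule a `frame_schedule`.
#' @return Numeric vector, one mean activity per frame.
#' @export
frame_average <- function(values, t, schedule) {
  if (length(values) != length(t)) stop("values and t must match")
  if (nrow(schedule) == 0L) return(numeric(0))
  eps <- 1e-9
  if (min(schedule$start) < min(t) - eps || max(schedule$end) > max(t) + eps)
    stop("frame schedule extends beyond the dense time grid")
  n <- length(t)
  cum <- c(0, cumsum(diff(t) * (values[-1] + values[-n]) / 2))
  Fi <- approxfun(t, cum, rule = 2)
  (Fi(schedule$end) - Fi(schedule$start)) / frame_durations(schedule)
}

#' Dense time grid spanning a frame schedule
#' @param schedule a `frame_schedule`.
#' @param dt grid step (min).
#' @return Uniform grid from the schedule start to its end, step `dt`.
#' @export
dense_time_grid <- function(schedule, dt = 0.01) {
  t0 <- if (nrow(schedule)) min(schedule$start) else 0
  t1 <- if (nrow(schedule)) max(schedule$end) else 0
  seq(t0, t1, by = dt)
}

# ---- decay correction utility ---------------------------------------------

#' Decay-correct a TAC to injection time
#'
#' Multiplies by \eqn{e^{+\lambda (t - t_{inj})}}. All curves synthesized by
#' this package are non-decay-corrected; this utility is opt-in.
#'
#' @param values activity values at `t`.
#' @param t scan-time grid (min).
#' @param lambda decay constant (1/min).
#' @param injection_time injection time (min, scan clock).
#' @return Decay-corrected values.
#' @export
decay_correct <- function(values, t, lambda, injection_time = 0) {
  values * exp(lambda * (t - injection_time))
}

# ---- serialization ---------------------------------------------------------

#' Write / read a frame schedule as a JSON sidecar
#'
#' Serialized as a list of `[start_min, end_min]` pairs.
#' @param schedule a `frame_schedule`.
#' @param path file path.
#' @export
write_frame_schedule_json <- function(schedule, path) {
  jsonlite::write_json(unname(apply(as.matrix(schedule), 1, c, simplify = FALSE)),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_frame_schedule_json
#' @export
read_frame_schedule_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(m)) m <- do.call(rbind, m)
  sched <- data.frame(start = m[, 1], end = m[, 2])
  class(sched) <- c("frame_schedule", "data.frame")
  sched
}

#' Write / read a frame-sampled TAC as CSV
#'
#' Columns: `time_start`, `time_end`, `value_kBq_per_mL`.
#' @param values frame values (kBq/mL).
#' @param schedule the matching `frame_schedule`.
#' @param path file path.
#' @export
write_tac_csv <- function(values, schedule, path) {
  stopifnot(length(values) == nrow(schedule))
  write.csv(data.frame(time_start = schedule$start, time_end = schedule$end,
                       value_kBq_per_mL = values),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  df <- read.csv(path)
  sched <- data.frame(start = df$time_start, end = df$time_end)
  class(sched) <- c("frame_schedule", "data.frame")
  list(values = df$value_kBq_per_mL, schedule = sched)
}
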