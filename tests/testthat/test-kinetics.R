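# Compartmental kinetics: input function, impulse responses, TAC synthesis,
# frame integration.

test_that("Feng input is zero up to the appearance delay and for zero amplitudes", {
  p <- feng_aif_params(A1 = 851.1, A2 = 21.88, A3 = 20.81,
                       p1 = -4.1339, p2 = -0.1191, p3 = -0.0104, tau = 0.5)
  expect_identical(feng_aif(p, c(0, 0.25, 0.5)), c(0, 0, 0))
  p0 <- feng_aif_params(0, 0, 0, -1, -1, -1, tau = 0.2)
  expect_identical(feng_aif(p0, seq(0, 10, by = 0.5)), numeric(21))
  expect_error(feng_aif_params(NA, 1, 1, -1, -1, -1), "finite")
})

test_that("Feng input peak matches a dense-grid oracle and stays non-negative", {
  for (sp in default_tracers()) {
    tt <- seq(0, 120, length.out = 10000)
    a <- feng_aif(sp$aif, tt)
    expect_true(all(a >= 0), label = paste(sp$name, "AIF non-negative"))
    # peak of the analytic linear-rise term: d/du[(A1 u)e^{p1 u}] ~ 0 at
    # u = -1/p1 plus slower terms; compare analytic evaluation against the
    # dense grid argmax to within one grid step
    peak_dense <- tt[which.max(a)]
    finer <- seq(max(0, peak_dense - 0.05), peak_dense + 0.05,
                 length.out = 4001)
    peak_finer <- finer[which.max(feng_aif(sp$aif, finer))]
    expect_lt(abs(peak_dense - peak_finer), 120 / 9999)
  }
})

test_that("impulse response closed forms are exact at t = 0 and t -> Inf", {
  fdg <- compartment_params(K1 = 0.6, k2 = 1.2, k3 = 0.1)
  expect_identical(impulse_response(fdg, 0), 0.6)
  # irreversible plateau K1 k3 / (k2 + k3)
  expect_equal(impulse_response(fdg, 1e4), 0.6 * 0.1 / 1.3, tolerance = 1e-12)
  mono <- impulse_response(fdg, seq(0, 60, by = 0.1))
  expect_true(all(diff(mono) <= 1e-12))
  # reversible model decays to 0
  ses <- compartment_params(0.4, 0.094, 0.02, 0.007)
  expect_identical(impulse_response(ses, 0), 0.4)
  expect_lt(impulse_response(ses, 1e4), 1e-6)
  expect_error(compartment_params(-0.1, 1, 1), ">= 0")
})

test_that("impulse response agrees with an ODE-solver oracle over random draws", {
  skip_if_not_installed("deSolve")
  # oracle: integrate the two-tissue state equations with a delta input,
  # i.e. homogeneous dynamics from C1(0) = K1
  ode_response <- function(p, times) {
    rhs <- function(t, y, parms) {
      list(c(-(p$k2 + p$k3) * y[1] + p$k4 * y[2],
             p$k3 * y[1] - p$k4 * y[2]))
    }
    sol <- deSolve::ode(y = c(C1 = p$K1, C2 = 0), times = times, func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    rowSums(sol[, c("C1", "C2")])
  }
  means <- table1_means()
  set.seed(42)
  times <- seq(0, 60, by = 0.5)
  for (i in 1:100) {
    base <- means[[sample(3, 1)]]
    f <- runif(4, 0.5, 1.5)     # Table-1 means +/- 50%
    p <- compartment_params(base$K1 * f[1], base$k2 * f[2],
                            base$k3 * f[3], base$k4 * f[4])
    got <- impulse_response(p, times)
    want <- ode_response(p, times)
    expect_lt(max(abs(got - want)) / max(want), 1e-6)
  }
})

test_that("tissue TAC handles degenerate inputs and matches a refined-grid oracle", {
  specs <- default_tracers()
  t <- seq(0, 60, by = 0.25)
  # zero AIF -> zero TAC
  z <- specs$FDG
  z$aif <- feng_aif_params(0, 0, 0, -1, -1, -1)
  expect_identical(tissue_tac(z, t = t), numeric(length(t)))
  # lambda ~ 0, R = K1 constant, A = 1 - e^{-50 t} (the Feng form is pinned
  # to 0 at onset) -> K1 * (t - (1 - e^{-50 t})/50) integral ramp
  ramp <- tracer_spec("ramp", lambda = 1e-12, injection_time = 0,
                      aif = feng_aif_params(0, 1, 0, -50, 0, 0),
                      kinetics = compartment_params(2, 0, 0, 0, 0.5))
  got <- tissue_tac(ramp, t = t)
  want <- 2 * (t - (1 - exp(-50 * t)) / 50)
  expect_equal(got, want, tolerance = 1e-3)
  # pre-injection times return zero, not an error
  rb <- specs$Rb82
  expect_identical(tissue_tac(rb, t = c(0, 1, 4.99))[1:3], c(0, 0, 0))
  # grid refinement oracle: dt = 0.001 reference
  for (sp in specs[c("FDG", "sestamibi")]) {
    coarse <- tissue_tac(sp, t = t, dt = 0.01)
    fine <- tissue_tac(sp, t = t, dt = 0.001)
    expect_lt(max(abs(coarse - fine)) / max(fine), 1e-3)
  }
})

test_that("multi-tracer TAC is the superposition of single-tracer TACs", {
  specs <- default_tracers()
  t <- seq(0, 60, by = 0.25)
  pars <- lapply(specs, `[[`, "kinetics")
  VB <- 0.38
  triple <- multi_tracer_tac(specs, pars, VB = VB, t = t)
  singles <- lapply(seq_along(specs), function(i)
    multi_tracer_tac(specs[i], pars[i], VB = VB, t = t))
  expect_equal(triple, Reduce(`+`, singles), tolerance = 1e-12)
  # VB = 1 -> pure blood; single tracer with VB = 0 -> pure tissue
  expect_equal(multi_tracer_tac(specs, pars, VB = 1, t = t),
               blood_input(specs, t), tolerance = 1e-14)
  expect_equal(multi_tracer_tac(specs[1], pars[1], VB = 1e-15, t = t),
               tissue_tac(specs$FDG, t = t), tolerance = 1e-9)
  expect_error(multi_tracer_tac(specs, pars[1:2], t = t), "length")
})

test_that("suppressing radioactive decay never decreases a TAC", {
  specs <- default_tracers()
  t <- seq(0, 60, by = 0.5)
  for (sp in specs) {
    nodecay <- sp; nodecay$lambda <- 1e-15
    expect_true(all(tissue_tac(nodecay, t = t) >=
                      tissue_tac(sp, t = t) - 1e-12))
  }
})

test_that("frame averaging reproduces trivial cases and a quadrature oracle", {
  sched <- build_frame_schedule(cbind(c(2, 1), c(1, 2)))  # [0,1) [1,2) [2,4)
  t <- seq(0, 4, by = 0.01)
  expect_equal(frame_average(rep(3, length(t)), t, sched), c(3, 3, 3))
  # linear TAC C(t) = t on [0, 2] averages to the midpoint
  sched2 <- build_frame_schedule(cbind(1, 2))
  expect_equal(frame_average(t, t, sched2), 1.0)
  # arbitrary smooth TAC vs adaptive quadrature
  f <- function(x) exp(-0.3 * x) * (1 + sin(x))
  sched3 <- build_frame_schedule(default_frame_blocks())
  tg <- dense_time_grid(sched3, dt = 0.005)
  got <- frame_average(f(tg), tg, sched3)
  want <- mapply(function(a, b)
    stats::integrate(f, a, b, rel.tol = 1e-10)$value / (b - a),
    sched3$start, sched3$end)
  expect_lt(max(abs(got - want) / abs(want)), 1e-4)
  expect_error(frame_average(t, t, build_frame_schedule(cbind(1, 10))),
               "beyond")
})

test_that("frame averages of the default schedule conserve the time integral", {
  specs <- default_tracers()
  sched <- build_frame_schedule()
  tg <- dense_time_grid(sched, dt = 0.01)
  C <- multi_tracer_tac(specs, t = tg)
  fa <- frame_average(C, tg, sched)
  total_from_frames <- sum(fa * frame_durations(sched))
  n <- length(tg)
  total_trapz <- sum(diff(tg) * (C[-1] + C[-n]) / 2)
  expect_lt(abs(total_from_frames - total_trapz) / total_trapz, 1e-4)
})

test_that("the default schedule has 28 contiguous frames over 60 minutes", {
  sched <- build_frame_schedule()
  expect_identical(nrow(sched), 28L)
  expect_equal(max(sched$end), 60)
  expect_equal(sched$start[-1], sched$end[-28])
  expect_true(all(frame_durations(sched) > 0))
  # short-frame burst after the sestamibi injection: frame 16 is 15 s
  expect_equal(unlist(sched[16, ]), c(start = 15.75, end = 16))
  # trivial and empty block specs
  expect_equal(as.matrix(build_frame_schedule(cbind(2, 0.5))),
               cbind(start = c(0, 0.5), end = c(0.5, 1)),
               ignore_attr = "dimnames")
  expect_identical(nrow(build_frame_schedule(cbind(numeric(0), numeric(0)))), 0L)
})

test_that("schedule and TAC round-trip through their sidecar formats", {
  sched <- build_frame_schedule()
  tmp <- tempfile(fileext = ".json")
  write_frame_schedule_json(sched, tmp)
  back <- read_frame_schedule_json(tmp)
  expect_equal(back$start, sched$start)
  expect_equal(back$end, sched$end)
  vals <- seq_len(28) / 7
  tmp2 <- tempfile(fileext = ".csv")
  write_tac_csv(vals, sched, tmp2)
  rt <- read_tac_csv(tmp2)
  expect_equal(rt$values, vals)
  expect_equal(rt$schedule$end, sched$end)
  unlink(c(tmp, tmp2))
})
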