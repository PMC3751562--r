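test_that("one noise-free step from rest matches the hand computation", {
  # predictor lifts A to 0.02; corrector averages the two drifts
  s1 <- heun_maruyama_step(initial_states(tri, "embryo") * 0, tri,
                           model_params(), dt = 0.02)
  expect_equal(unname(s1[, "A"]), rep(0.0198, 3))
  expect_equal(unname(s1[, "X"]), rep(0.01 * 0.02^3, 3))  # 8e-8
  expect_equal(unname(s1[, "Y"]), rep(0.01 * 0.02^3, 3))
  expect_equal(unname(s1[, "Z"]), rep(0, 3))
})

test_that("zero noise amplitude reproduces the deterministic step bitwise", {
  p0 <- model_params(eta_x = 0, eta_y = 0)
  s <- initial_states(tri, "adult")
  set.seed(1)
  noisy <- heun_maruyama_step(s, tri, p0, 0.02, noise = cbind(rnorm(3),
                                                              rnorm(3)))
  det <- heun_maruyama_step(s, tri, p0, 0.02)
  expect_identical(noisy, det)
})

test_that("equal seeds give bitwise-identical trajectories", {
  tis <- hex_lattice(6, 6, density = 0.8, seed = 3)
  cfg <- sim_config(t_end = 5, seed = 42, record_every = 10)
  t1 <- simulate_tissue(tis, initial_states(tis, "adult"), p_ref, cfg)
  t2 <- simulate_tissue(tis, initial_states(tis, "adult"), p_ref, cfg)
  expect_identical(t1$states, t2$states)
})

test_that("compiled and reference engines agree", {
  tis <- hex_lattice(5, 6, density = 0.9, seed = 8)
  init <- initial_states(tis, "embryo")
  for (noise in c(TRUE, FALSE)) {
    c1 <- sim_config(t_end = 2, seed = 7, record_every = 25,
                     noise_on = noise, engine = "cpp")
    c2 <- sim_config(t_end = 2, seed = 7, record_every = 25,
                     noise_on = noise, engine = "r")
    t1 <- simulate_tissue(tis, init, p_ref, c1)
    t2 <- simulate_tissue(tis, init, p_ref, c2)
    expect_equal(t1$states, t2$states, tolerance = 1e-12)
    expect_equal(t1$times, t2$times)
  }
})

test_that("noise-free integration matches an adaptive ODE reference", {
  skip_if_not_installed("deSolve")
  f <- function(t, y, parms) list(coupled_drift(y, tri, parms))
  scenarios <- list(
    list(init = "adult", p = model_params()),        # stable acinar
    list(init = "adult", p = model_params(b = 0)),   # dedifferentiation
    list(init = "embryo", p = model_params()))       # development core
  for (sc in scenarios) {
    init <- initial_states(tri, sc$init)
    cfg <- sim_config(t_end = 50, noise_on = FALSE, seed = NULL,
                      record_every = 2500)
    tr <- simulate_tissue(tri, init, sc$p, cfg)
    ref <- deSolve::lsoda(as.vector(t(init)), c(0, 50), f, sc$p,
                          rtol = 1e-10, atol = 1e-12)
    expect_lt(max(abs(final_states(tr) -
                        matrix(ref[2, -1], ncol = 4, byrow = TRUE))),
              1e-4)
  }
})

test_that("stepper reproduces the OU stationary variance at dt = 0.02", {
  # dV = -V dt + eta dW has stationary variance eta^2 / 2; 4000
  # independent chains integrated well past the relaxation time
  set.seed(2024)
  eta <- 1; dt <- 0.02; m <- 4000
  y <- rep(0, m)
  g <- eta * sqrt(dt)
  for (k in seq_len(1500))
    y <- pancfate:::hm_step_generic(function(v) -v, y, dt, g * rnorm(m),
                                    lower = -Inf)
  v <- var(y)
  se <- v * sqrt(2 / (m - 1))
  expect_lt(abs(v - eta^2 / 2), 3 * se)
})

test_that("noise-free dynamics preserve cell symmetry", {
  for (tis in list(tri, hex_lattice(6, 6))) {
    cfg <- sim_config(t_end = 30, noise_on = FALSE, seed = NULL,
                      record_every = 100)
    tr <- simulate_tissue(tis, initial_states(tis, "embryo"), p_ref, cfg)
    for (k in seq_along(tr$times)) {
      st <- tr$states[, , k, drop = TRUE]
      expect_equal(max(apply(st, 2, function(v) diff(range(v)))), 0)
    }
  }
})

test_that("states stay non-negative and clamping is a bounded guard", {
  tis <- hex_lattice(8, 8)
  cfg <- sim_config(t_end = 30, seed = 5, record_every = 50, t_pre = 5)
  sched <- data.frame(time = 0, parameter = "b", value = 0)
  tr <- simulate_tissue(tis, initial_states(tis, "adult"), p_ref, cfg,
                        schedule = sched)
  expect_true(all(tr$states >= 0))
  # clamp events only shave off noise-scale undershoots below zero
  expect_lt(tr$clamp_max, 0.005)
  # and never occur without noise
  cfg0 <- sim_config(t_end = 30, noise_on = FALSE, seed = NULL)
  tr0 <- simulate_tissue(tis, initial_states(tis, "adult"), p_ref, cfg0)
  expect_equal(tr0$clamped_fraction, 0)
})

test_that("schedules apply overrides and record events", {
  cfg <- sim_config(t_end = 10, noise_on = FALSE, seed = NULL,
                    record_every = 50, t_pre = 2)
  sched <- data.frame(time = c(0, 4), parameter = c("b", "a"),
                      value = c(0, 0))
  tr <- simulate_tissue(tri, initial_states(tri, "adult"), p_ref, cfg,
                        schedule = sched)
  expect_equal(nrow(tr$events), 2)
  expect_equal(tr$events$time, c(0, 4))
  expect_equal(tr$events$old, c(2000, 1000))
  expect_warning(
    simulate_tissue(tri, initial_states(tri, "adult"), p_ref, cfg,
                    schedule = data.frame(time = 99, parameter = "b",
                                          value = 0)),
    "beyond t_end")
  expect_error(
    simulate_tissue(tri, initial_states(tri, "adult"), p_ref, cfg,
                    schedule = data.frame(time = c(4, 0),
                                          parameter = c("a", "b"),
                                          value = c(0, 0))),
    "sorted")
  expect_error(
    simulate_tissue(tri, initial_states(tri, "adult"), p_ref, cfg,
                    schedule = data.frame(time = 0, parameter = "zz",
                                          value = 0)),
    "unknown parameter")
})

test_that("empty tissues simulate to empty trajectories", {
  tis <- hex_lattice(5, 6, density = 0)
  cfg <- sim_config(t_end = 1, seed = 1)
  tr <- simulate_tissue(tis, initial_states(tis, "adult"), p_ref, cfg)
  expect_equal(dim(tr$states)[1], 0)
  expect_error(population_average(tr), "no cells")
})

test_that("population averages are plain means over cells", {
  two <- graph_tissue(cbind(1, 2))
  init <- initial_states(two, "adult")
  init[2, "Y"] <- 0
  cfg <- sim_config(t_end = 0, seed = NULL, noise_on = FALSE)
  tr <- simulate_tissue(two, init, p_ref, cfg)
  expect_equal(population_average(tr)$Y, 0.5)
  # homogeneous states average to the common value
  tr2 <- simulate_tissue(tri, initial_states(tri, "adult"), p_ref, cfg)
  expect_equal(population_average(tr2)$Y, 1)
})

test_that("trajectory CSV keeps full double precision on round trip", {
  cfg <- sim_config(t_end = 2, seed = 9, record_every = 25)
  tr <- simulate_tissue(tri, initial_states(tri, "embryo"), p_ref, cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read.csv(f)
  df <- as.data.frame(tr)
  for (col in c("A", "X", "Y", "Z"))
    expect_identical(back[[col]], df[[col]])
  fe <- withr::local_tempfile(fileext = ".json")
  write_events(tr, fe)
  expect_true(file.exists(fe))
})
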