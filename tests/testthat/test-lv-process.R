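# Predator-prey simulators: vector field, integrator accuracy and order,
# sensitivities, observation sampling.

test_that("vector field matches hand-evaluated rates and fixed points", {
  p1 <- lv_params(r = 0.1, b = 0.02, m = 0.04)
  p3 <- box1_truth()

  # extinction fixed point for both responses
  expect_equal(lv_derivatives(c(x = 0, y = 0), p1, "typeI"),
               c(dx = 0, dy = 0))
  expect_equal(lv_derivatives(c(x = 0, y = 0), p3, "typeIII"),
               c(dx = 0, dy = 0))

  # interior equilibrium of the linear response: x* = m/b, y* = r/b
  expect_equal(lv_derivatives(c(x = 2, y = 5), p1, "typeI"),
               c(dx = 0, dy = 0), tolerance = 1e-12)

  # direct substitution of the sigmoidal response at (10, 10)
  x <- 10; y <- 10
  feeding <- 0.02 * x^2 * y / (1 + 0.025 * x^2)
  expect_equal(lv_derivatives(c(x = x, y = y), p3, "typeIII"),
               c(dx = 0.1 * x - feeding, dy = feeding - 0.04 * y))
})

test_that("vector field validates densities and response/parameter match", {
  p3 <- box1_truth()
  expect_error(lv_derivatives(c(x = -1, y = 2), p3, "typeIII"), "prey")
  expect_error(lv_derivatives(c(x = 1, y = -2), p3, "typeIII"), "predator")
  expect_error(lv_derivatives(c(x = 1, y = 1), p3, "typeI"), "searching")
  p1 <- lv_params(0.1, 0.02, 0.04)
  expect_error(lv_derivatives(c(x = 1, y = 1), p1, "typeIII"), "searching")
  expect_error(lv_params(-0.1, 0.02, 0.04), "non-negative")
})

test_that("trajectory grid and equilibrium invariance", {
  p1 <- lv_params(r = 0.1, b = 0.02, m = 0.04)
  traj <- lv_integrate(p1, c(x = 2, y = 5), horizon = 130, step = 0.5,
                       response = "typeI")
  expect_equal(nrow(traj), 261)         # 130 / 0.5 + 1
  expect_equal(traj$t, seq(0, 130, 0.5))
  expect_true(all(abs(traj$x - 2) < 1e-10))
  expect_true(all(abs(traj$y - 5) < 1e-10))
  expect_error(lv_integrate(p1, c(x = 2, y = 5), horizon = 130, step = 0.43,
                            response = "typeI"), "multiple")
})

test_that("integrator matches a quarter-step reference within 1e-3", {
  p3 <- box1_truth()
  traj <- lv_integrate(p3, c(x = 10, y = 10), 130, 0.5, "typeIII",
                       h_internal = 0.05)
  ref <- lv_integrate(p3, c(x = 10, y = 10), 130, 0.5, "typeIII",
                      h_internal = 0.0125)
  expect_lt(max(abs(traj$x - ref$x), abs(traj$y - ref$y)), 1e-3)
})

test_that("integrator agrees with an independent adaptive solver", {
  p3 <- box1_truth()
  f <- function(t, u, p) {
    q <- 1 + p[["s"]] * u[1]^2
    g <- p[["b"]] * u[1]^2 * u[2] / q
    list(c(p[["r"]] * u[1] - g, g - p[["m"]] * u[2]))
  }
  ref <- deSolve::ode(c(10, 10), seq(0, 130, 0.5), f,
                      c(r = 0.1, b = 0.02, m = 0.04, s = 0.025),
                      rtol = 1e-10, atol = 1e-10)
  traj <- lv_integrate(p3, c(x = 10, y = 10), 130, 0.5, "typeIII")
  expect_lt(max(abs(traj$x - ref[, 2])), 1e-5)
  expect_lt(max(abs(traj$y - ref[, 3])), 1e-5)
})

test_that("halving the step shrinks the error at 4th order", {
  p3 <- box1_truth()
  ref <- lv_integrate(p3, c(x = 10, y = 10), 130, 0.5, "typeIII",
                      h_internal = 0.0125)
  err <- vapply(c(0.1, 0.05), function(h) {
    tr <- lv_integrate(p3, c(x = 10, y = 10), 130, 0.5, "typeIII",
                       h_internal = h)
    max(abs(tr$x - ref$x))
  }, numeric(1))
  expect_gte(err[1] / err[2], 8)
})

test_that("type I conserved quantity drifts below 1e-4 at step 0.01", {
  p1 <- lv_params(r = 0.1, b = 0.02, m = 0.04)
  traj <- lv_integrate(p1, c(x = 3, y = 4), 130, 0.5, "typeI",
                       h_internal = 0.01)
  H <- lv_conserved(traj, p1)
  expect_lt(max(abs(H - H[1])), 1e-4)
})

test_that("trajectory sensitivities match central finite differences", {
  p3 <- box1_truth()
  traj <- lv_integrate(p3, c(x = 10, y = 10), 50, 0.5, "typeIII",
                       sensitivities = TRUE)
  Sx <- attr(traj, "Sx")
  target <- c(r = 0.1, b = 0.02, m = 0.04, s = 0.025, x0 = 10, y0 = 10)
  summary_at <- function(v) {
    tr <- lv_integrate(lv_params(v[["r"]], v[["b"]], v[["m"]], v[["s"]]),
                       c(x = v[["x0"]], y = v[["y0"]]), 50, 0.5, "typeIII")
    mean(tr$x)
  }
  fd <- fd_grad(summary_at, target)
  an <- colMeans(Sx)
  expect_equal(unname(an), unname(fd), tolerance = 1e-4)
})

test_that("trajectories and observation sets round-trip through CSV", {
  traj <- lv_integrate(box1_truth(), c(x = 10, y = 10), 20, 0.5, "typeIII")
  obs <- lv_observe(traj, 5, 0.1, seed = 2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f1)
  write_observations_csv(obs, f2)
  back_t <- read_trajectory_csv(f1)
  back_o <- read_observations_csv(f2)
  expect_equal(back_t$x, traj$x)
  expect_equal(back_o$x_obs, obs$x_obs)
  unlink(c(f1, f2))
})

test_that("observation sampling is seeded, on-grid and unbiased", {
  traj <- lv_integrate(box1_truth(), c(x = 10, y = 10), 130, 0.5, "typeIII")
  o1 <- lv_observe(traj, 9, noise_sd = 0, seed = 42)
  o2 <- lv_observe(traj, 9, noise_sd = 0, seed = 42)
  expect_identical(o1, o2)
  expect_equal(length(unique(o1$t)), 9)
  expect_equal(o1$x_obs, traj$x[match(o1$t, traj$t)])  # exact when noiseless

  # full recovery at n_obs = grid size, zero noise
  all_obs <- lv_observe(traj, nrow(traj), 0, seed = 1)
  expect_equal(all_obs$x_obs, traj$x)
  expect_error(lv_observe(traj, nrow(traj) + 1, 0, seed = 1), "exceeds")

  # noise is centred and has the requested scale across seeds
  devs <- unlist(lapply(1:300, function(s) {
    o <- lv_observe(traj, 9, noise_sd = 0.5, seed = s)
    o$x_obs - traj$x[match(o$t, traj$t)]
  }))
  expect_lt(abs(mean(devs)), 0.02)
  expect_equal(sd(devs), 0.5, tolerance = 0.05)
})
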