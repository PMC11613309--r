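# Calibration: Gaussian likelihood closed forms, Metropolis sampler
# behaviour, gradient calibration.

test_that("log-likelihood matches closed forms and an independent sum", {
  # initialise at the interior equilibrium (m/b, r/b): constant prey = 2
  pm <- lv_pm("typeI", init = c(x = 2, y = 2))
  theta <- c(r = 0.1, b = 0.05, m = 0.1)
  # constant trajectory at x = 2: perfect predictions for x_obs = 2
  obs <- tibble::tibble(t = seq(0, 50, 0.5), x_obs = 2)
  n <- nrow(obs)
  expect_equal(log_likelihood(pm, theta, obs), n * log(1 / sqrt(2 * pi)))
  # each residual = 1 subtracts n/2
  obs1 <- obs; obs1$x_obs <- 3
  expect_equal(log_likelihood(pm, theta, obs1),
               n * log(1 / sqrt(2 * pi)) - n / 2)
  # random parameters against a dnorm summation oracle
  theta2 <- c(r = 0.11, b = 0.03, m = 0.06)
  pred <- pm_predict(pm, theta2, obs)
  expect_equal(log_likelihood(pm, theta2, obs),
               sum(dnorm(obs$x_obs, pred, 1, log = TRUE)))
})

test_that("log-likelihood is monotone in each residual magnitude", {
  pm <- lv_pm("typeI", init = c(x = 2, y = 2))
  theta <- c(r = 0.1, b = 0.05, m = 0.1)
  base <- tibble::tibble(t = c(0, 1, 2), x_obs = c(2, 2, 2))
  ll0 <- log_likelihood(pm, theta, base)
  for (i in 1:3) for (d in c(0.5, 2)) {
    worse <- base; worse$x_obs[i] <- worse$x_obs[i] + d
    expect_lt(log_likelihood(pm, theta, worse), ll0)
  }
})

test_that("with a flat likelihood the sampler reproduces the prior", {
  pm <- lv_pm("typeI")
  no_data <- tibble::tibble(t = numeric(0), x_obs = numeric(0))
  post <- mcmc_calibrate(pm, no_data, n_iter = 6000, n_chains = 2, seed = 2)
  draws <- post$draws[post$draws$iteration > post$burn, ]
  # thin to de-correlate the random walk before the distributional check
  draws <- draws[seq(1, nrow(draws), by = 10), ]
  b <- post$bounds
  for (j in seq_len(nrow(b))) {
    u <- (draws[[b$name[j]]] - b$lower[j]) / (b$upper[j] - b$lower[j])
    ks <- suppressWarnings(stats::ks.test(u, "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("identical chain seeds give identical draws; runs are reproducible", {
  pm <- lv_pm("typeI")
  traj <- lv_integrate(lv_params(0.1, 0.02, 0.04), c(x = 12, y = 10),
                       40, 0.5, "typeI")
  obs <- lv_observe(traj, 15, 0.2, seed = 3)
  p1 <- mcmc_calibrate(pm, obs, n_iter = 300, n_chains = 2, seed = 5,
                       chain_seeds = c(9, 9))
  d1 <- p1$draws[p1$draws$chain == 1, c("r", "b", "m")]
  d2 <- p1$draws[p1$draws$chain == 2, c("r", "b", "m")]
  expect_identical(d1, d2)
  p2 <- mcmc_calibrate(pm, obs, n_iter = 300, n_chains = 2, seed = 5,
                       chain_seeds = c(9, 9))
  expect_identical(p1$draws, p2$draws)
  b <- lv_bounds("typeI")
  expect_true(all(p1$draws$r >= b$lower[1] & p1$draws$r <= b$upper[1]))
})

test_that("the sampler matches the analytic posterior on a 1-D quadratic", {
  # Gaussian target N(0.3, 0.05^2) truncated to a wide box: the sampled
  # variance must match the analytic variance within 10%
  lp <- function(theta) -0.5 * ((theta[["z"]] - 0.3) / 0.05)^2
  bounds <- tibble::tibble(name = "z", lower = -2, upper = 2)
  ch <- metropolis_sample(lp, bounds, n_iter = 30000, seed = 8)
  z <- ch$draws[15001:30000, "z"]
  expect_equal(mean(z), 0.3, tolerance = 0.02)
  expect_equal(stats::var(z), 0.05^2, tolerance = 0.1)
})

test_that("dense noise-free data concentrate the posterior at the truth", {
  pm <- lv_pm("typeI", init = c(x = 12, y = 10))
  truth <- lv_params(0.1, 0.02, 0.04)
  traj <- lv_integrate(truth, c(x = 12, y = 10), 80, 0.5, "typeI")
  obs <- tibble::tibble(t = traj$t, x_obs = traj$x)
  post <- mcmc_calibrate(pm, obs, n_iter = 4000, seed = 11)
  expect_true(all(abs(post$map - c(0.1, 0.02, 0.04)) /
                    c(0.1, 0.02, 0.04) < 0.05))
  s <- tidy(post)
  expect_true(all(s$estimate > s$conf.low & s$estimate < s$conf.high))
})

test_that("gradient calibration descends and recovers the truth", {
  pm <- lv_pm("typeI", init = c(x = 12, y = 10))
  truth <- lv_params(0.1, 0.02, 0.04)
  traj <- lv_integrate(truth, c(x = 12, y = 10), 80, 0.5, "typeI")
  dense <- tibble::tibble(t = traj$t, x_obs = traj$x)

  # initialised at the truth, noise-free: the loss stays at ~0
  at_truth <- gradient_calibrate(pm, dense,
                                 init = c(r = 0.1, b = 0.02, m = 0.04),
                                 epochs = 50, lr = 1e-6)
  expect_lt(max(at_truth$loss_curve), 1e-8)

  # descent property from a perturbed start
  fit <- gradient_calibrate(pm, dense, init = c(r = 0.12, b = 0.025, m = 0.05),
                            epochs = c(1500, 1500, 500),
                            lr = c(3e-3, 3e-4, 3e-5))
  expect_lt(tail(fit$loss_curve, 1), fit$loss_curve[1])
  expect_true(all(abs(fit$params - c(0.1, 0.02, 0.04)) /
                    c(0.1, 0.02, 0.04) < 0.05))
})

test_that("the compiled descent loop reproduces manual gradient steps", {
  g <- gen_box1(box1_scenario("i"), seed = 1)
  obs <- g$observations[-1, ]
  b <- lv_bounds("typeIII")
  theta <- c(r = 0.12, b = 0.03, m = 0.05, s = 0.02)
  th <- theta
  for (k in 1:3) {
    pred <- pm_predict(g$pm, th, obs, sensitivities = TRUE)
    gr <- 2 * colMeans((pred - obs$x_obs) * attr(pred, "jac"))
    th <- pmin(pmax(th - 1e-5 * gr, setNames(b$lower, b$name)),
               setNames(b$upper, b$name))
  }
  fast <- gradient_calibrate(g$pm, obs, init = theta, epochs = 3, lr = 1e-5,
                             optimizer = "sgd", bounds = b)
  expect_equal(fast$params, th, tolerance = 1e-12)
})

test_that("posterior draws serialise and the MAP round-trips as params", {
  clim <- tiny_climate(120, seed = 44)
  clim$P_obs <- run_flux_pm(clim, flux_params())$P
  post <- mcmc_calibrate(flux_pm(), clim, n_iter = 60, n_chains = 1, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_posterior_csv(post, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 60)
  expect_true(all(c("beta", "logpost", "chain", "iteration") %in% names(back)))
  p <- flux_params(table = dplyr::mutate(flux_param_table(),
                                         value = unname(post$map[.data$name])))
  f2 <- tempfile(fileext = ".csv")
  write_params_csv(p, f2)
  expect_equal(read_params_csv(f2)$value, p$value)
  unlink(c(f, f2))
})
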