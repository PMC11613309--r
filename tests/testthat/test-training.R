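# Protocol mechanics: sparsification, blocked cross-validation, random
# search, Latin hypercube stratification, covariate surrogate and the
# domain-adaptation phases.

test_that("weekly sparsification keeps days 1, 8, ... deterministically", {
  expect_equal(nrow(sparsify_weekly(tibble::tibble(day = 1:28))), 4)
  expect_equal(nrow(sparsify_weekly(tibble::tibble(day = 1:6))), 1)
  s <- sparsify_weekly(tibble::tibble(day = 1:365))
  expect_equal(nrow(s), 53)
  expect_equal(s$day, seq(1, 365, by = 7))
  expect_error(sparsify_weekly(tibble::tibble(day = integer(0))), "empty")

  # stride composability: two rounds at stride 7 equal one at stride 49
  twice <- sparsify_weekly(sparsify_weekly(tibble::tibble(day = 1:365)))
  expect_equal(twice$day, seq(1, 365, by = 49))

  # per-site application
  d <- tibble::tibble(site_id = rep(c("a", "b"), each = 21), day = rep(1:21, 2))
  s2 <- sparsify_weekly(d)
  expect_equal(s2$day, rep(c(1, 8, 15), 2))
})

test_that("blocked CV folds partition blocks and exclude the test block", {
  d <- tidyr::expand_grid(site_id = c("s1", "s2", "s3", "s4"),
                          year = 2004:2008, doy = 1:5)
  plan <- make_cv_plan(d, "temporal_year", test_year = 2008,
                       test_site = NULL)
  expect_equal(length(plan$folds), 4)   # 2004-2007
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$val), 0)
    expect_false(any(d$year[f$val] != f$block))
    expect_false(2008 %in% d$year[c(f$train, f$val)])
    expect_length(intersect(plan$test, c(f$train, f$val)), 0)
  }
  # validation rows across folds partition the pool
  val_all <- sort(unlist(lapply(plan$folds, `[[`, "val")))
  expect_equal(val_all, setdiff(seq_len(nrow(d)), plan$test))

  plan_s <- make_cv_plan(d[d$year %in% 2005, ], "spatial_site",
                         test_site = "s1")
  expect_equal(length(plan_s$folds), 3)
  expect_error(make_cv_plan(d[d$year == 2004 & d$site_id == "s1", ],
                            "temporal_year"), "fewer than 2")
})

test_that("random search returns the planted optimum and logs all draws", {
  d <- tibble::tibble(site_id = "a", year = rep(2001:2003, each = 4),
                      doy = rep(1:4, 3), P_obs = rnorm(12))
  plan <- make_cv_plan(d, "temporal_year")
  # stub evaluator: quadratic in lr with a known optimum
  ev <- function(cand, train_rows, val_rows) (log10(cand$lr) + 3)^2
  res <- random_search(d, plan, "naive", n_draws = 12, seed = 7,
                       evaluator = ev)
  expect_equal(nrow(res$log), 12)
  expect_equal(res$best$lr, res$log$lr[which.min(res$log$val_mse)])
  # deterministic per seed
  res2 <- random_search(d, plan, "naive", n_draws = 12, seed = 7,
                        evaluator = ev)
  expect_identical(res$log, res2$log)
  # n_draws = 1 returns that candidate
  one <- random_search(d, plan, "naive", n_draws = 1, seed = 3,
                       evaluator = ev)
  expect_equal(one$best$lr, one$log$lr[1])
})

test_that("Latin hypercube draws are one per stratum per parameter", {
  bounds <- tibble::tibble(name = c("a", "b", "c"),
                           lower = c(0, -1, 10), upper = c(1, 1, 20))
  n <- 17
  draws <- latin_hypercube(n, bounds, seed = 5)
  expect_equal(dim(draws), c(n, 3))
  for (j in 1:3) {
    u <- (draws[, j] - bounds$lower[j]) / (bounds$upper[j] - bounds$lower[j])
    expect_true(all(u >= 0 & u <= 1))
    strata <- floor(u * n)
    expect_equal(sort(strata), 0:(n - 1))   # exactly one draw per stratum
  }
  expect_identical(latin_hypercube(n, bounds, seed = 5), draws)
})

test_that("the covariate surrogate emits physical, seasonal series", {
  clim <- tiny_climate(730, seed = 19)
  surr <- covariate_surrogate(clim)
  sim <- surr(365, seed = 4)
  expect_equal(nrow(sim), 365)
  expect_true(all(sim$phi >= 0))
  expect_true(all(sim$R >= 0))
  expect_true(all(sim$fappfd >= 0 & sim$fappfd <= 1))
  expect_true(all(sim$D > 0))
  # seasonality survives: simulated summer is warmer than winter
  expect_gt(mean(sim$T[sim$doy %in% 170:230]),
            mean(sim$T[sim$doy %in% c(1:30, 335:365)]) + 3)
  expect_identical(surr(100, seed = 9), surr(100, seed = 9))
})

test_that("domain adaptation pretrains on simulations only, then improves on data", {
  clim <- tiny_climate(730, seed = 23)
  clim$site_id <- "tiny"
  truth <- flux_params(beta = 1.0)
  run <- run_flux_pm(clim, truth)
  clim$P_obs <- run$P + rnorm(nrow(clim), 0, 0.3)

  plan <- adaptation_plan(n_prior_samples = 8, sim_days = 365,
                          pretrain_epochs = 150)
  # 0 fine-tune epochs returns the pure emulator
  emu <- domain_adapt(clim, model_variant("domain_adaptation", hidden = 16),
                      plan = plan, pm_params = flux_params(),
                      full_series = clim, epochs = 0, seed = 1)
  expect_length(emu$finetune_curve, 0)
  expect_true(all(is.finite(predict(emu, clim))))

  fits <- domain_adapt(clim, model_variant("domain_adaptation", hidden = 16),
                       plan = plan, pm_params = flux_params(),
                       full_series = clim, epochs = 400, lr = 2e-3, seed = 1)
  mse_emu <- loss_mse(clim$P_obs, predict(emu, clim))
  mse_fit <- loss_mse(clim$P_obs, predict(fits, clim))
  expect_lt(mse_fit, mse_emu)
})

test_that("emulator quality improves with more prior samples", {
  clim <- tiny_climate(365, seed = 29)
  clim$site_id <- "tiny"
  clim$P_obs <- run_flux_pm(clim, flux_params())$P
  score <- function(n_draws, seed) {
    emu <- domain_adapt(clim, model_variant("domain_adaptation", hidden = 16),
                        plan = adaptation_plan(n_prior_samples = n_draws,
                                               pretrain_epochs = 200),
                        pm_params = flux_params(), full_series = clim,
                        epochs = 0, seed = seed)
    # several fresh PM simulations as validation targets
    taus <- latin_hypercube(4, tibble::tibble(
      name = names(flux_params()$value),
      lower = unname(flux_params()$lower),
      upper = unname(flux_params()$upper)), seed = 1000 + seed)
    mean(vapply(seq_len(nrow(taus)), function(i) {
      val <- clim
      val$P_obs <- pm_predict(flux_pm(), taus[i, ], val)
      loss_mse(val$P_obs, predict(emu, val))
    }, numeric(1)))
  }
  res <- vapply(1:4, function(s) c(few = score(5, s), many = score(50, s)),
                numeric(2))
  expect_lt(median(res["many", ]), median(res["few", ]))
})
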