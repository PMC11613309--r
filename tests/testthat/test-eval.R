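# Metrics and the ICE variable-importance analysis.

test_that("MAE basics and permutation invariance", {
  expect_equal(mae(c(0, 2), c(1, 1)), 1)
  expect_equal(mae(1:5, 1:5), 0)
  y <- rnorm(20); p <- rnorm(20)
  o <- sample(20)
  expect_equal(mae(y, p), mae(y[o], p[o]))
  expect_error(mae(numeric(0), numeric(0)), "empty")
})

test_that("quantile association separates bias from rank skill", {
  y <- rnorm(200)
  qa_perfect <- quantile_association(y, y)
  expect_equal(qa_perfect$spearman, 1)
  expect_equal(qa_perfect$table$q_obs, qa_perfect$table$q_pred)

  qa_anti <- quantile_association(y, -y)
  expect_equal(qa_anti$spearman, -1)

  qa_shift <- quantile_association(y, y + 1)
  expect_equal(qa_shift$spearman, 1)
  expect_equal(qa_shift$table$q_pred, qa_shift$table$q_obs + 1)

  # rank component invariant under strictly monotone transforms
  qa_mono <- quantile_association(y, exp(2 * y))
  expect_equal(qa_mono$spearman, 1)

  expect_true(is.na(quantile_association(y, rep(1, 200))$spearman))
  expect_error(quantile_association(y, y, n_bins = 1), "n_bins")
})

test_that("pooled MAE equals the size-weighted mean of fold MAEs", {
  set.seed(2)
  preds <- dplyr::bind_rows(
    tibble::tibble(model = "m", fold = 1, P_obs = rnorm(10), pred = rnorm(10)),
    tibble::tibble(model = "m", fold = 2, P_obs = rnorm(25), pred = rnorm(25)))
  rep <- evaluate_experiment(preds)
  manual <- with(preds, mean(abs(P_obs - pred)))
  expect_equal(rep$pooled$mae_pooled, manual)
  by_fold <- rep$per_fold
  expect_equal(sum(by_fold$mae * by_fold$n) / sum(by_fold$n), manual)
})

test_that("a perfect injected predictor is flagged best", {
  set.seed(3)
  y <- rnorm(30)
  preds <- dplyr::bind_rows(
    tibble::tibble(model = "perfect", fold = 1, P_obs = y, pred = y),
    tibble::tibble(model = "noisy", fold = 1, P_obs = y, pred = y + rnorm(30)))
  rep <- evaluate_experiment(preds)
  expect_equal(rep$pooled$mae_pooled[rep$pooled$model == "perfect"], 0)
  expect_true(rep$pooled$best[rep$pooled$model == "perfect"])
  expect_false(rep$pooled$best[rep$pooled$model == "noisy"])
  single <- evaluate_experiment(preds[preds$model == "noisy", ])
  expect_true(all(single$pooled$best))   # a lone model is trivially best
})

test_that("report totals equal recomputation from persisted predictions", {
  set.seed(4)
  preds <- tibble::tibble(model = rep(c("a", "b"), each = 40),
                          fold = rep(rep(1:2, each = 20), 2),
                          doy = rep(c(60:79, 152:171), 2),
                          P_obs = rnorm(80), pred = rnorm(80))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(preds, f, row.names = FALSE)
  back <- tibble::as_tibble(utils::read.csv(f))
  expect_equal(evaluate_experiment(back)$pooled,
               evaluate_experiment(preds)$pooled)
  unlink(f)
})

test_that("ICE of the process model is linear in radiation, flat in CO2", {
  clim <- tiny_climate(730, seed = 17)
  clim$site_id <- "tiny"
  pm_fit <- ecopinn:::new_fit(model_variant("pm"), pm_params = flux_params())
  curve <- ice(pm_fit, clim, "phi", year = max(clim$year))
  expect_equal(sort(unique(curve$season)),
               sort(c("spring", "summer", "autumn", "winter")))
  for (sn in unique(curve$season)) {
    cs <- curve[curve$season == sn, ]
    if (max(cs$P_mean) < 1e-9) next   # dormant window: flat at zero
    fit <- lm(P_mean ~ grid_value, data = cs)
    expect_gt(suppressWarnings(summary(fit))$r.squared, 0.999)
  }
  # CO2 has no default modifier: flat within every seasonal window
  flat <- ice(pm_fit, clim, "co2", year = max(clim$year))
  for (sn in unique(flat$season))
    expect_lt(diff(range(flat$P_mean[flat$season == sn])), 1e-9)
  expect_error(ice(pm_fit, clim, "nope"), "not a model input")
})

test_that("ICE grids respect physical ranges and both averaging orders run", {
  clim <- tiny_climate(730, seed = 27)
  clim$site_id <- "tiny"
  pm_fit <- ecopinn:::new_fit(model_variant("pm"), pm_params = flux_params())
  for (v in c("phi", "R", "fappfd")) {
    cv <- ice(pm_fit, clim, v, n_grid = 15)
    expect_gte(min(cv$grid_value), 0)
    if (v == "fappfd") expect_lte(max(cv$grid_value), 1)
  }
  a <- ice(pm_fit, clim, "phi", n_grid = 7, average_first = FALSE)
  b <- ice(pm_fit, clim, "phi", n_grid = 7, average_first = TRUE)
  expect_equal(nrow(a), nrow(b))
  # the PM is linear in phi given states, so both orders agree there
  expect_equal(a$P_mean, b$P_mean, tolerance = 0.15)
})

test_that("ICE of an additive model reproduces its partial function", {
  # naive fit on data generated from an additive function of phi
  clim <- tiny_climate(730, seed = 37)
  clim$site_id <- "tiny"
  clim$P_obs <- 0.2 * clim$phi + 3
  fit <- train_variant(clim, model_variant("naive", hidden = c(16, 16),
                                           activation = "tanh"),
                       epochs = 4000, lr = 5e-3, seed = 1)
  # evaluate the slope over the well-supported interior of the range
  grid <- seq(quantile(clim$phi, 0.1), quantile(clim$phi, 0.9),
              length.out = 10)
  cv <- ice(fit, clim, "phi", grid = grid)
  summer <- cv[cv$season == "summer", ]
  slope <- coef(lm(P_mean ~ grid_value, data = summer))[2]
  expect_equal(unname(slope), 0.2, tolerance = 0.1)
})
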