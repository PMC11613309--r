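# Training protocols: weekly sparsification, blocked cross-validation,
# combined random grid search, Latin hypercube prior sampling, and the
# two-phase domain-adaptation protocol (simulator pretraining followed by
# fine-tuning on observations).

#' Reduce a daily series to one data point per week
#'
#' Keeps every 7th row starting from the first (days 1, 8, 15, ...),
#' systematically and deterministically; applied per site when a
#' `site_id` column is present.
#'
#' @param data daily tibble.
#' @return the sparse tibble.
#' @examples
#' sparsify_weekly(tibble::tibble(day = 1:28))  # 4 rows
#' @export
sparsify_weekly <- function(data) {
  if (nrow(data) == 0) abort("empty input")
  if ("site_id" %in% names(data)) {
    data %>% group_by(.data$site_id) %>%
      filter((row_number() - 1L) %% 7L == 0L) %>% ungroup()
  } else {
    data[seq(1L, nrow(data), by = 7L), , drop = FALSE]
  }
}

#' Blocked cross-validation plan
#'
#' Builds folds that hold out whole contiguous blocks — full years
#' (`"temporal_year"`), whole sites (`"spatial_site"`) or whole sites of a
#' restricted year set (`"spatiotemporal"`) — with a test block (year
#' and/or site) excluded from every fold and reserved for final
#' evaluation.
#'
#' @param data tibble with `year` (and `site_id` for the spatial
#'   blockings) columns.
#' @param blocking blocking scheme.
#' @param test_year held-out evaluation year (excluded everywhere).
#' @param test_site held-out evaluation site (spatial/spatio-temporal).
#' @return object of class `cv_plan`: list of folds, each with integer row
#'   indices `train` and `val`, plus `test` indices.
#' @export
make_cv_plan <- function(data,
                         blocking = c("temporal_year", "spatial_site",
                                      "spatiotemporal"),
                         test_year = NULL, test_site = NULL) {
  blocking <- match.arg(blocking)
  if (!"year" %in% names(data)) abort("`data` needs a `year` column")
  rows <- seq_len(nrow(data))
  is_test <- rep(FALSE, nrow(data))
  if (!is.null(test_year)) is_test <- is_test | data$year %in% test_year
  if (!is.null(test_site)) {
    if (blocking == "temporal_year")
      is_test <- is_test & data$site_id %in% test_site
    else
      is_test <- is_test | data$site_id %in% test_site
  }
  pool <- rows[!is_test]

  block_id <- switch(blocking,
    temporal_year = data$year[pool],
    spatial_site = data$site_id[pool],
    spatiotemporal = data$site_id[pool])
  blocks <- unique(block_id)
  if (length(blocks) < 2) abort("fewer than 2 blocks to cross-validate over")
  folds <- lapply(blocks, function(bl) {
    list(block = bl,
         train = pool[block_id != bl],
         val = pool[block_id == bl])
  })
  structure(list(blocking = blocking, folds = folds,
                 test = rows[is_test],
                 test_year = test_year, test_site = test_site),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %s: %d folds (%s), %d test rows\n", x$blocking,
              length(x$folds),
              paste(vapply(x$folds, function(f) as.character(f$block),
                           character(1)), collapse = ", "),
              length(x$test)))
  invisible(x)
}

#' Hyper-parameter search space
#'
#' @param n_layers range (min, max) of hidden-layer counts.
#' @param width_set candidate layer widths.
#' @param lr_range learning-rate range, sampled uniformly on log10 scale.
#' @param batch_sizes candidate batch sizes (`Inf` = full batch).
#' @param lambda_range range for the regularisation weight (used by the
#'   regularisation variant only).
#' @return object of class `search_space`.
#' @export
search_space <- function(n_layers = c(1, 3), width_set = c(16, 32, 64),
                         lr_range = c(1e-4, 1e-2), batch_sizes = Inf,
                         lambda_range = c(0, 1)) {
  structure(list(n_layers = n_layers, width_set = width_set,
                 lr_range = lr_range, batch_sizes = batch_sizes,
                 lambda_range = lambda_range), class = "search_space")
}

sample_candidate <- function(space, kind) {
  nl <- sample(seq(space$n_layers[1], space$n_layers[2]), 1)
  width <- sample(space$width_set, 1)
  lr <- 10^runif(1, log10(space$lr_range[1]), log10(space$lr_range[2]))
  bs <- if (length(space$batch_sizes) == 1) space$batch_sizes
        else sample(space$batch_sizes, 1)
  lambda <- if (kind == "regularisation")
    runif(1, space$lambda_range[1], space$lambda_range[2]) else NA_real_
  list(hidden = rep(width, nl), lr = lr, batch_size = bs, lambda = lambda)
}

#' Combined random grid search
#'
#' Randomly draws architectures and optimisation parameters (and the
#' regularisation weight, for that variant), trains each candidate on
#' every fold of the plan and scores it by mean validation MSE; the argmin
#' is returned together with the full search log.
#'
#' @param data flux data (with `pm_*` columns where the variant needs
#'   them).
#' @param plan a [make_cv_plan()].
#' @param kind variant kind to search for.
#' @param space a [search_space()].
#' @param n_draws number of candidates.
#' @param epochs training epochs per candidate and fold.
#' @param seed RNG seed.
#' @param evaluator scoring function `(candidate, fold_train, fold_val) ->
#'   validation MSE`; the default trains the variant. Exposed so protocol
#'   mechanics can be exercised with a stub.
#' @return list with `best` (candidate), `log` (tibble, one row per
#'   candidate with mean validation MSE).
#' @export
random_search <- function(data, plan, kind, space = search_space(),
                          n_draws = 10, epochs = 500, seed = 1L,
                          evaluator = NULL) {
  if (n_draws < 1) abort("`n_draws` must be at least 1")
  candidates <- with_seed(seed, {
    lapply(seq_len(n_draws), function(i) sample_candidate(space, kind))
  })
  if (is.null(evaluator)) {
    evaluator <- function(cand, train_rows, val_rows) {
      variant <- model_variant(kind, hidden = cand$hidden,
                               lambda = if (is.na(cand$lambda)) 0.5 else cand$lambda)
      fit <- train_variant(train_rows, variant, epochs = epochs,
                           lr = cand$lr, batch_size = cand$batch_size,
                           seed = seed)
      loss_mse(val_rows$P_obs, predict(fit, val_rows))
    }
  }
  scores <- vapply(candidates, function(cand) {
    fold_scores <- vapply(plan$folds, function(f) {
      evaluator(cand, data[f$train, ], data[f$val, ])
    }, numeric(1))
    mean(fold_scores)
  }, numeric(1))
  if (all(!is.finite(scores))) abort("all candidates diverged")
  log <- tibble(
    draw = seq_len(n_draws),
    hidden = vapply(candidates, function(c) paste(c$hidden, collapse = "x"),
                    character(1)),
    lr = vapply(candidates, `[[`, numeric(1), "lr"),
    batch_size = vapply(candidates, function(c) as.numeric(c$batch_size),
                        numeric(1)),
    lambda = vapply(candidates, `[[`, numeric(1), "lambda"),
    val_mse = scores)
  list(best = candidates[[which.min(scores)]], log = log)
}

#' Latin hypercube sample over parameter bounds
#'
#' Stratified design: each parameter's `n` draws fall one per
#' equal-probability stratum of its prior interval.
#'
#' @param n number of draws.
#' @param bounds tibble with columns `name`, `lower`, `upper`.
#' @param seed RNG seed.
#' @return matrix `n` x `nrow(bounds)` with named columns.
#' @export
latin_hypercube <- function(n, bounds, seed = NULL) {
  with_seed(seed, {
    u <- lhs::randomLHS(n, nrow(bounds))
    out <- sweep(u, 2, bounds$upper - bounds$lower, "*")
    out <- sweep(out, 2, bounds$lower, "+")
    colnames(out) <- bounds$name
    out
  })
}

#' Smooth seasonal covariate surrogate
#'
#' Fits harmonic (Fourier) regressions of each covariate on the day of
#' year (3 annual harmonics by default) and simulates new daily series by
#' adding bootstrap-resampled residuals; physical ranges are enforced
#' (`phi`, `R` >= 0, `fappfd` in `[0, 1]`, precipitation's dry days are
#' preserved by resampling the observed zero pattern).
#'
#' @param covariates observed daily series (`doy`, `T`, `D`, `phi`, `R`,
#'   `fappfd`, `co2`).
#' @param n_harmonics annual harmonics.
#' @return function `(n_days, seed)` returning a simulated covariate
#'   tibble.
#' @export
covariate_surrogate <- function(covariates, n_harmonics = 3) {
  doy <- covariates$doy
  H <- do.call(cbind, lapply(seq_len(n_harmonics), function(k)
    cbind(sin(2 * pi * k * doy / 365.25), cos(2 * pi * k * doy / 365.25))))
  fits <- lapply(c("T", "D", "phi", "fappfd"), function(v) {
    fit <- lm(covariates[[v]] ~ H)
    list(coef = coef(fit), resid = stats::residuals(fit))
  })
  names(fits) <- c("T", "D", "phi", "fappfd")
  R_obs <- covariates$R
  co2 <- median(covariates$co2)
  function(n_days, seed = NULL) {
    with_seed(seed, {
      d <- ((seq_len(n_days) - 1L) %% 365L) + 1L
      Hn <- do.call(cbind, lapply(seq_len(n_harmonics), function(k)
        cbind(sin(2 * pi * k * d / 365.25), cos(2 * pi * k * d / 365.25))))
      sim <- lapply(fits, function(f) {
        mu <- cbind(1, Hn) %*% f$coef
        as.numeric(mu) + sample(f$resid, n_days, replace = TRUE)
      })
      tibble(
        doy = d,
        year = rep(seq_len(ceiling(n_days / 365)), each = 365)[seq_len(n_days)],
        T = sim$T,
        D = pmax(sim$D, 0.01),
        phi = pmax(sim$phi, 0),
        R = sample(R_obs, n_days, replace = TRUE),
        fappfd = pmin(pmax(sim$fappfd, 0), 1),
        co2 = co2)
    })
  }
}

#' Domain-adaptation plan
#'
#' @param n_prior_samples Latin hypercube draws from the parameter priors.
#' @param sim_days simulated days per draw.
#' @param pretrain_epochs,pretrain_lr phase-1 budget (emulator).
#' @param n_harmonics harmonics of the covariate surrogate.
#' @return object of class `adaptation_plan`.
#' @export
adaptation_plan <- function(n_prior_samples = 30, sim_days = 365,
                            pretrain_epochs = 300, pretrain_lr = 1e-3,
                            n_harmonics = 3) {
  structure(list(n_prior_samples = n_prior_samples, sim_days = sim_days,
                 pretrain_epochs = pretrain_epochs,
                 pretrain_lr = pretrain_lr, n_harmonics = n_harmonics),
            class = "adaptation_plan")
}

#' Two-phase domain adaptation
#'
#' Phase 1 pre-trains the network on a purely artificial dataset: for each
#' Latin-hypercube draw from the parameter priors, the covariate surrogate
#' simulates drivers and the process model simulates GPP; the pooled
#' simulations yield an emulator. Phase 2 fine-tunes on the observations.
#' The network input is the same in both phases (parameter draws are not
#' inputs), and phase 1 provably never reads observed GPP: the pretraining
#' table is built from surrogate output only and carries a `provenance`
#' marker that is asserted before training.
#'
#' @param data observed training rows (covariates + `P_obs`).
#' @param variant the `"domain_adaptation"` [model_variant()].
#' @param plan an [adaptation_plan()].
#' @param pm_params calibrated [flux_params()] whose bounds define the
#'   priors.
#' @param full_series full daily series used to fit the covariate
#'   surrogate.
#' @param epochs,lr,batch_size fine-tuning budget (phase 2); 0 epochs
#'   returns the pure emulator.
#' @param seed RNG seed.
#' @return an `ecopinn_fit` with both phases' loss curves.
#' @export
domain_adapt <- function(data, variant = model_variant("domain_adaptation"),
                         plan = adaptation_plan(), pm_params = flux_params(),
                         full_series = data, epochs = 500, lr = 1e-3,
                         batch_size = Inf, seed = 1L) {
  draws <- latin_hypercube(plan$n_prior_samples,
                           tibble(name = names(pm_params$value),
                                  lower = unname(pm_params$lower),
                                  upper = unname(pm_params$upper)),
                           seed = derive_seed(seed, 1L))
  surrogate <- covariate_surrogate(full_series, plan$n_harmonics)
  sims <- lapply(seq_len(plan$n_prior_samples), function(i) {
    xsim <- surrogate(plan$sim_days, seed = derive_seed(seed, 100L + i))
    tau <- flux_params(table = tibble(name = colnames(draws),
                                      value = draws[i, ],
                                      lower = unname(pm_params$lower),
                                      upper = unname(pm_params$upper)))
    run <- run_flux_pm(xsim, tau)
    xsim$P_obs <- run$P
    xsim$site_id <- paste0("sim", i)
    xsim
  })
  pretrain <- bind_rows(sims)
  attr(pretrain, "provenance") <- "simulated"
  stopifnot(identical(attr(pretrain, "provenance"), "simulated"))

  X_pre <- flux_features(pretrain, variant$cyclic_doy, variant$use_co2)
  scaler <- fit_scaler(X_pre)
  spec <- mlp_spec(ncol(X_pre), variant$hidden, 1, variant$activation)
  net <- mlp_init(spec, seed = seed)
  net <- train_mlp(net, apply_scaler(X_pre, scaler), pretrain$P_obs,
                   epochs = plan$pretrain_epochs, lr = plan$pretrain_lr,
                   batch_size = batch_size, seed = seed)
  pretrain_curve <- attr(net, "loss_curve")

  finetune_curve <- numeric(0)
  if (epochs > 0) {
    X_obs <- flux_features(data, variant$cyclic_doy, variant$use_co2)
    net <- train_mlp(net, apply_scaler(X_obs, scaler), data$P_obs,
                     epochs = epochs, lr = lr, batch_size = batch_size,
                     seed = derive_seed(seed, 2L))
    finetune_curve <- attr(net, "loss_curve")
  }
  new_fit(variant, net = net, scaler = scaler,
          loss_curve = c(pretrain_curve, finetune_curve),
          pm_params = pm_params,
          extra = list(pretrain_curve = pretrain_curve,
                       finetune_curve = finetune_curve,
                       n_prior_samples = plan$n_prior_samples))
}
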