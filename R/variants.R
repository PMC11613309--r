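# The six model variants: naive MLP, bias correction, parallel physics,
# physics regularisation, domain adaptation and physics embedding, plus the
# stand-alone process model. A variant bundles network architecture, a
# process-model handle and a loss; `train_variant()` fits it on tabular
# daily flux data and `predict()` applies the variant-specific prediction
# rule:
#   parallel physics   y_NN + y_PHY
#   regularisation     y_NN            (the PM enters only the training loss)
#   naive              y_NN
#   bias correction    net(y_PHY)
#   domain adaptation  y_NN (pretrained on simulations, fine-tuned on data)
#   embedding          bias-net output after the embedded PM forward pass
#   pm                 y_PHY

VARIANT_KINDS <- c("pm", "naive", "bias_correction", "parallel_physics",
                   "regularisation", "domain_adaptation", "embedding")

#' Configure a model variant
#'
#' @param kind one of `"pm"`, `"naive"`, `"bias_correction"`,
#'   `"parallel_physics"`, `"regularisation"`, `"domain_adaptation"`,
#'   `"embedding"`.
#' @param hidden hidden-layer widths of the network(s).
#' @param activation hidden activation.
#' @param lambda loss weight: consistency weight for `"regularisation"`
#'   (in `[0, 1]`), process-term weight for `"embedding"` (default 1).
#' @param cyclic_doy encode day of year as a (sin, cos) pair instead of
#'   feeding the integer directly; removes the artificial discontinuity at
#'   year boundaries.
#' @param use_co2 include the (site-constant) CO2 column as a feature.
#' @return object of class `model_variant`.
#' @export
model_variant <- function(kind, hidden = c(32, 32),
                          activation = c("relu", "tanh"),
                          lambda = if (kind == "embedding") 1 else 0.5,
                          cyclic_doy = TRUE, use_co2 = TRUE) {
  kind <- match.arg(kind, VARIANT_KINDS)
  activation <- match.arg(activation)
  if (lambda < 0 || lambda > 1) abort("`lambda` must be in [0, 1]")
  structure(list(kind = kind, hidden = as.integer(hidden),
                 activation = activation, lambda = lambda,
                 cyclic_doy = cyclic_doy, use_co2 = use_co2),
            class = "model_variant")
}

#' Build the covariate feature matrix
#'
#' @param data flux data tibble with columns `T`, `D`, `phi`, `R`,
#'   `fappfd`, `co2`, `doy`.
#' @param cyclic_doy sin/cos-encode the day of year.
#' @param use_co2 include CO2.
#' @return numeric feature matrix.
#' @export
flux_features <- function(data, cyclic_doy = TRUE, use_co2 = TRUE) {
  base <- c("T", "D", "phi", "R", "fappfd")
  if (use_co2) base <- c(base, "co2")
  X <- as.matrix(data[, base])
  if (cyclic_doy) {
    X <- cbind(X, doy_sin = sin(2 * pi * data$doy / 365.25),
               doy_cos = cos(2 * pi * data$doy / 365.25))
  } else {
    X <- cbind(X, doy = data$doy)
  }
  X
}

# Label maximal contiguous daily runs: a new block starts at a site change
# or any day/year discontinuity (e.g. non-consecutive training years). The
# recursive process model is run per block so its water state never
# carries across a gap.
series_blocks <- function(data) {
  n <- nrow(data)
  site <- if ("site_id" %in% names(data)) as.character(data$site_id)
          else rep("site", n)
  if (!"doy" %in% names(data)) return(site)
  doy <- data$doy
  year <- if ("year" %in% names(data)) data$year else rep(1L, n)
  new_block <- c(TRUE, !(site[-1] == site[-n] &
                           ((diff(doy) == 1 & diff(year) == 0) |
                              (diff(doy) < -300 & diff(year) == 1))))
  paste(site, cumsum(new_block), sep = "#")
}

#' Attach process-model predictions to a flux dataset
#'
#' Runs the flux model per site over the (contiguous, daily) series and
#' binds the prediction columns `pm_P`, `pm_E`, `pm_theta` that the
#' process-aware variants consume. Run this before any subsetting or
#' sparsification so the recursion sees every day.
#'
#' @param data daily flux tibble with a `site_id` column.
#' @param params [flux_params()] used for the run.
#' @return `data` with `pm_P`, `pm_E`, `pm_theta` columns.
#' @export
add_pm_predictions <- function(data, params = flux_params()) {
  blocks <- series_blocks(data)
  data$pm_P <- NA_real_; data$pm_E <- NA_real_; data$pm_theta <- NA_real_
  for (idx in split(seq_len(nrow(data)), blocks)) {
    run <- run_flux_pm(data[idx, ], params)
    data$pm_P[idx] <- run$P
    data$pm_E[idx] <- run$E
    data$pm_theta[idx] <- run$theta
  }
  data
}

need_pm_cols <- function(data) {
  if (!all(c("pm_P", "pm_E", "pm_theta") %in% names(data)))
    abort("this variant needs process-model predictions; run add_pm_predictions() first")
  invisible(data)
}

#' Train a model variant
#'
#' Dispatches on the variant kind. All networks train with Adam on
#' z-scored features (statistics from the training rows); the loss curves
#' are kept on the returned fit. Deterministic for a fixed `seed`.
#'
#' @param data training rows (tibble with covariates, `P_obs`, and for the
#'   process-aware kinds the `pm_*` columns from [add_pm_predictions()]).
#' @param variant a [model_variant()].
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size (`Inf` = full batch).
#' @param seed RNG seed (weight init and shuffling).
#' @param pm_params calibrated [flux_params()] (required for `"pm"`,
#'   `"domain_adaptation"` and `"embedding"`; for the others only the
#'   `pm_*` columns are used).
#' @param full_series full daily series of the training sites (required by
#'   `"embedding"`, whose process model must run over contiguous days, and
#'   by `"domain_adaptation"` to fit the covariate surrogate).
#' @param adaptation an [adaptation_plan()] for `"domain_adaptation"`.
#' @return an object of class `ecopinn_fit`.
#' @export
train_variant <- function(data, variant, epochs = 1000, lr = 1e-3,
                          batch_size = Inf, seed = 1L, pm_params = NULL,
                          full_series = NULL, adaptation = NULL) {
  stopifnot(inherits(variant, "model_variant"))
  kind <- variant$kind
  y <- data$P_obs
  if (anyNA(y)) abort("training rows must have observed P")

  if (kind == "pm") {
    if (is.null(pm_params)) abort("`pm_params` is required for the pm variant")
    return(new_fit(variant, pm_params = pm_params))
  }
  if (kind == "domain_adaptation") {
    if (is.null(pm_params)) abort("`pm_params` is required for domain adaptation")
    if (is.null(full_series)) full_series <- data
    return(domain_adapt(data, variant,
                        plan = adaptation %||% adaptation_plan(),
                        pm_params = pm_params, full_series = full_series,
                        epochs = epochs, lr = lr, batch_size = batch_size,
                        seed = seed))
  }
  if (kind == "embedding") {
    if (is.null(full_series))
      abort("`full_series` is required for the embedding variant")
    return(train_embedding(data, variant, full_series = full_series,
                           pm_params = pm_params %||% flux_params(),
                           epochs = epochs, lr = lr, seed = seed))
  }

  if (kind == "bias_correction") {
    need_pm_cols(data)
    X <- as.matrix(data[, c("pm_P", "pm_E", "pm_theta")])
  } else {
    X <- flux_features(data, variant$cyclic_doy, variant$use_co2)
  }
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(X, scaler)

  offset <- NULL; lambda <- 0; y2 <- NULL
  if (kind == "parallel_physics") {
    need_pm_cols(data)
    offset <- data$pm_P
  } else if (kind == "regularisation") {
    need_pm_cols(data)
    lambda <- variant$lambda
    y2 <- data$pm_P
  }

  spec <- mlp_spec(ncol(Xs), variant$hidden, 1, variant$activation)
  net <- mlp_init(spec, seed = seed)
  net <- train_mlp(net, Xs, y, epochs = epochs, lr = lr, offset = offset,
                   lambda = lambda, y2 = y2, batch_size = batch_size,
                   seed = seed)
  new_fit(variant, net = net, scaler = scaler,
          loss_curve = attr(net, "loss_curve"), pm_params = pm_params)
}

new_fit <- function(variant, net = NULL, scaler = NULL, loss_curve = NULL,
                    pm_params = NULL, extra = list()) {
  structure(c(list(variant = variant, kind = variant$kind, net = net,
                   scaler = scaler, loss_curve = loss_curve,
                   pm_params = pm_params), extra),
            class = "ecopinn_fit")
}

#' @export
print.ecopinn_fit <- function(x, ...) {
  cat("<ecopinn_fit>", x$kind, "\n")
  if (!is.null(x$loss_curve))
    cat(sprintf("  trained %d epochs, final loss %.4g\n",
                length(x$loss_curve), tail(x$loss_curve, 1)))
  invisible(x)
}

#' Predict GPP from a fitted variant
#'
#' Applies the variant-specific prediction rule. Rows must carry the same
#' columns used in training; process-aware kinds need `pm_*` columns
#' (computed with the same calibrated parameters), and `"embedding"` needs
#' a contiguous daily series per site because the process model is re-run
#' inside the forward pass.
#'
#' @param object an `ecopinn_fit`.
#' @param newdata tibble of rows to predict.
#' @param ... unused.
#' @return numeric vector of predicted GPP.
#' @export
predict.ecopinn_fit <- function(object, newdata, ...) {
  kind <- object$kind
  if (kind == "pm") {
    if ("pm_P" %in% names(newdata)) return(newdata$pm_P)
    need_pm_cols(newdata)
  }
  if (kind == "embedding") return(predict_embedding(object, newdata))
  if (kind == "bias_correction") {
    need_pm_cols(newdata)
    X <- as.matrix(newdata[, c("pm_P", "pm_E", "pm_theta")])
  } else {
    X <- flux_features(newdata, object$variant$cyclic_doy,
                       object$variant$use_co2)
  }
  y_nn <- as.numeric(mlp_forward(object$net, apply_scaler(X, object$scaler)))
  if (kind == "parallel_physics") {
    need_pm_cols(newdata)
    y_nn + newdata$pm_P
  } else {
    y_nn
  }
}

# --- physics embedding -----------------------------------------------------

squash_to_bounds <- function(m, lower, upper) {
  lower + (upper - lower) * plogis(m)
}

#' Forward pass of the physics embedding
#'
#' Runs the three embedded steps on one contiguous daily series: (1) the
#' parameter network maps covariates to per-day raw parameter outputs,
#' which are averaged over data points and squashed into the prior bounds,
#' giving a single parameter vector per series; (2) the process model runs
#' with those parameters; (3) the bias-correction network maps the
#' standardised process outputs (P, E, theta) to the fitted GPP.
#'
#' @param param_net parameter network (`output_dim` = number of PM
#'   parameters).
#' @param bias_net bias-correction network (3 inputs, 1 output).
#' @param covariates contiguous daily series (one site).
#' @param pm_params [flux_params()] carrying the prior bounds.
#' @param x_scaler,phy_scaler standardisers for covariate features and
#'   process outputs.
#' @param variant the [model_variant()] (feature flags).
#' @param sens also return the Jacobians needed for backpropagation.
#' @return list with `y_nn`, `y_phy` (tibble `P`, `E`, `theta`), `tau`
#'   (the squashed parameter vector) and intermediates when `sens = TRUE`.
#' @export
embedding_forward <- function(param_net, bias_net, covariates, pm_params,
                              x_scaler, phy_scaler, variant = model_variant("embedding"),
                              sens = FALSE) {
  X <- flux_features(covariates, variant$cyclic_doy, variant$use_co2)
  Xs <- apply_scaler(X, x_scaler)
  cache_p <- mlp_forward_full(param_net, Xs)
  raw <- cache_p$A[[length(param_net$W)]]            # n x n_par
  m <- colMeans(raw)                                  # average, then squash
  tau <- squash_to_bounds(m, pm_params$lower, pm_params$upper)
  stopifnot(all(tau >= pm_params$lower & tau <= pm_params$upper))
  run <- run_flux_pm(covariates, flux_params(table = tibble(
    name = names(pm_params$value), value = unname(tau),
    lower = unname(pm_params$lower), upper = unname(pm_params$upper))),
    sensitivities = sens)
  phy <- cbind(P = run$P, E = run$E, theta = run$theta)
  phys <- apply_scaler(phy, phy_scaler)
  cache_b <- mlp_forward_full(bias_net, phys)
  y_nn <- as.numeric(cache_b$A[[length(bias_net$W)]])
  out <- list(y_nn = y_nn, y_phy = as_tibble(as.data.frame(phy)), tau = tau)
  if (sens) {
    out$Xs <- Xs; out$cache_p <- cache_p; out$phys <- phys
    out$cache_b <- cache_b; out$m <- m
    out$JP <- attr(run, "JP"); out$JE <- attr(run, "JE")
    out$Jtheta <- attr(run, "Jtheta")
  }
  out
}

train_embedding <- function(data, variant, full_series, pm_params,
                            epochs = 200, lr = 1e-3, seed = 1L) {
  lambda <- variant$lambda
  sites <- split(full_series, series_blocks(full_series))
  # match loss rows into each site series
  masks <- lapply(sites, function(s) {
    key_s <- paste(s$site_id, s$year, s$doy)
    key_d <- paste(data$site_id, data$year, data$doy)
    match(key_d[key_d %in% key_s], key_s)
  })
  ys <- lapply(sites, function(s) {
    key_s <- paste(s$site_id, s$year, s$doy)
    key_d <- paste(data$site_id, data$year, data$doy)
    data$P_obs[key_d %in% key_s]
  })
  n_total <- sum(lengths(ys))
  if (n_total == 0) abort("no training rows match the full series")

  X_all <- flux_features(full_series, variant$cyclic_doy, variant$use_co2)
  x_scaler <- fit_scaler(X_all)
  ref <- bind_rows(lapply(sites, function(s) {
    r <- run_flux_pm(s, pm_params)
    tibble(P = r$P, E = r$E, theta = r$theta)
  }))
  phy_scaler <- fit_scaler(as.matrix(ref))

  n_par <- length(pm_params$value)
  d_in <- ncol(X_all)
  param_net <- mlp_init(mlp_spec(d_in, variant$hidden, n_par,
                                 variant$activation), seed = seed)
  bias_net <- mlp_init(mlp_spec(3, variant$hidden, 1, variant$activation),
                       seed = derive_seed(seed, 7L))

  pars <- c(param_net$W, param_net$b, bias_net$W, bias_net$b)
  opt <- adam_new(lapply(pars, function(p) dim(p) %||% length(p)))
  n_pw <- length(param_net$W); n_pb <- length(param_net$b)
  n_bw <- length(bias_net$W)
  loss_curve <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    grads <- lapply(pars, function(p) array(0, dim = dim(p) %||% length(p)))
    loss <- 0
    for (si in seq_along(sites)) {
      s <- sites[[si]]; idx <- masks[[si]]; y <- ys[[si]]
      if (!length(idx)) next
      fw <- embedding_forward(param_net, bias_net, s, pm_params,
                              x_scaler, phy_scaler, variant, sens = TRUE)
      y_nn <- fw$y_nn[idx]
      P_hat <- fw$y_phy$P[idx]
      loss <- loss + sum((y - y_nn)^2) / n_total +
        lambda * sum((y - P_hat)^2) / n_total

      # d loss / d bias-net output (only loss rows contribute)
      g_out <- matrix(0, nrow(s), 1)
      g_out[idx, 1] <- 2 * (y_nn - y) / n_total
      bb <- mlp_backward(bias_net, fw$phys, fw$cache_b, g_out)
      # through the phy standardiser to raw (P, E, theta)
      g_phy <- sweep(bb$gX, 2, phy_scaler$sd, "/")
      g_phy[idx, 1] <- g_phy[idx, 1] + lambda * 2 * (P_hat - y) / n_total
      # through the PM to tau
      g_tau <- colSums(g_phy[, 1] * fw$JP) + colSums(g_phy[, 2] * fw$JE) +
        colSums(g_phy[, 3] * fw$Jtheta)
      # through squash and the data-point average to the raw outputs
      sg <- plogis(fw$m) * (1 - plogis(fw$m))
      g_m <- g_tau * (pm_params$upper - pm_params$lower) * sg
      g_raw <- matrix(g_m / nrow(s), nrow(s), n_par, byrow = TRUE)
      pb <- mlp_backward(param_net, fw$Xs, fw$cache_p, g_raw)

      for (l in seq_len(n_pw)) grads[[l]] <- grads[[l]] + pb$gW[[l]]
      for (l in seq_len(n_pb)) grads[[n_pw + l]] <- grads[[n_pw + l]] + pb$gb[[l]]
      for (l in seq_len(n_bw)) grads[[n_pw + n_pb + l]] <-
          grads[[n_pw + n_pb + l]] + bb$gW[[l]]
      for (l in seq_along(bias_net$b)) grads[[n_pw + n_pb + n_bw + l]] <-
          grads[[n_pw + n_pb + n_bw + l]] + bb$gb[[l]]
    }
    upd <- adam_update(opt, pars, grads, lr)
    opt <- upd$state; pars <- upd$params
    for (l in seq_len(n_pw)) param_net$W[[l]] <- pars[[l]]
    for (l in seq_len(n_pb)) param_net$b[[l]] <- as.numeric(pars[[n_pw + l]])
    for (l in seq_len(n_bw)) bias_net$W[[l]] <- pars[[n_pw + n_pb + l]]
    for (l in seq_along(bias_net$b)) bias_net$b[[l]] <-
        as.numeric(pars[[n_pw + n_pb + n_bw + l]])
    loss_curve[ep] <- loss
    if (!is.finite(loss)) abort(sprintf("non-finite loss at epoch %d", ep))
  }

  new_fit(variant, loss_curve = loss_curve, pm_params = pm_params,
          extra = list(param_net = param_net, bias_net = bias_net,
                       x_scaler = x_scaler, phy_scaler = phy_scaler))
}

predict_embedding <- function(fit, newdata) {
  if (!"site_id" %in% names(newdata)) newdata$site_id <- "site"
  sites <- split(newdata, series_blocks(newdata))
  out <- lapply(sites, function(s) {
    fw <- embedding_forward(fit$param_net, fit$bias_net, s, fit$pm_params,
                            fit$x_scaler, fit$phy_scaler, fit$variant)
    tibble(key = paste(s$site_id, s$year, s$doy), y = fw$y_nn)
  })
  pred <- bind_rows(out)
  pred$y[match(paste(newdata$site_id, newdata$year, newdata$doy), pred$key)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
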