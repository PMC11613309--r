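# Stand-alone process-model calibration: adaptive random-walk Metropolis
# with a Gaussian likelihood (sd fixed at 1 by default), and gradient
# descent through the simulators' analytic parameter sensitivities.

#' Process-model predictions for calibration data
#'
#' Uniform prediction interface over the two process models. For the
#' predator-prey model, `data` is an observation tibble `(t, x_obs)` and
#' predictions are prey densities at those grid times. For the flux model,
#' `data` is a daily covariate series (per site when `site_id` is present)
#' and predictions are daily GPP.
#'
#' @param pm an [lv_pm()] or [flux_pm()] handle.
#' @param params named parameter vector (or [flux_params()]).
#' @param data calibration data (see Details).
#' @param sensitivities also return the Jacobian of the predictions with
#'   respect to the parameters (attribute `jac`).
#' @return numeric predictions aligned with the rows of `data`.
#' @export
pm_predict <- function(pm, params, data, sensitivities = FALSE) {
  UseMethod("pm_predict")
}

#' @export
pm_predict.lv_pm <- function(pm, params, data, sensitivities = FALSE) {
  if (inherits(params, "lv_params")) {
    params <- unlist(params[!vapply(params, is.null, logical(1))])
  }
  pn <- lv_par_names(pm)
  # call the compiled integrator directly: calibration loops hit this path
  # thousands of times and must not pay tibble-construction overhead
  res <- lv_integrate_cpp(params[["r"]], params[["b"]], params[["m"]],
                          if (pm$response == "typeIII") params[["s"]] else 0,
                          pm$init[["x"]], pm$init[["y"]],
                          pm$horizon, pm$step,
                          if (pm$response == "typeIII") 3L else 1L,
                          pm$h_internal, sensitivities)
  idx <- lv_time_index(pm, data$t)
  pred <- res$x[idx]
  if (sensitivities) {
    jac <- res$Sx[idx, seq_along(pn), drop = FALSE]
    colnames(jac) <- pn
    attr(pred, "jac") <- jac
  }
  pred
}

#' @export
pm_predict.flux_pm <- function(pm, params, data, sensitivities = FALSE) {
  params <- if (inherits(params, "flux_params")) params else
    flux_params(table = mutate(pm$bounds, value = unname(params[.data$name])))
  parts <- split(seq_len(nrow(data)), series_blocks(data))
  pred <- numeric(nrow(data))
  jac <- if (sensitivities)
    matrix(0, nrow(data), length(params$value),
           dimnames = list(NULL, names(params$value)))
  for (idx in parts) {
    run <- run_flux_pm(data[idx, ], params, init = pm$init,
                       sensitivities = sensitivities)
    pred[idx] <- run$P
    if (sensitivities) jac[idx, ] <- attr(run, "JP")
  }
  if (sensitivities) attr(pred, "jac") <- jac
  pred
}

#' Gaussian log-likelihood of process-model parameters
#'
#' Sum over observations of the normal log-density with the model
#' prediction as mean and fixed standard deviation (`sd = 1` by default).
#' Rows without an observed target are ignored. A failing model run
#' returns `-Inf` so the proposal is rejected.
#'
#' @param pm process-model handle.
#' @param params named parameter vector.
#' @param data calibration data; target column is `x_obs` (predator-prey)
#'   or `P_obs` (flux).
#' @param sd observation-error standard deviation.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(pm, params, data, sd = 1) {
  y <- if (inherits(pm, "lv_pm")) data$x_obs else data$P_obs
  keep <- !is.na(y)
  pred <- tryCatch(pm_predict(pm, params, data),
                   error = function(e) NULL)
  if (is.null(pred) || any(!is.finite(pred[keep]))) return(-Inf)
  sum(dnorm(y[keep], mean = pred[keep], sd = sd, log = TRUE))
}

#' Default prior bounds for predator-prey calibration
#'
#' Weakly informative boxes on the positive rates. They are deliberately
#' wide: a structurally mis-specified model often fits best far from the
#' generating values, and tight truth-centred priors would silently
#' forbid that compensation.
#'
#' @param response functional response; type III adds the searching time.
#' @return tibble with columns `name`, `lower`, `upper`.
#' @export
lv_bounds <- function(response = c("typeI", "typeIII")) {
  response <- match.arg(response)
  out <- tibble(name = c("r", "b", "m"),
                lower = c(0.001, 0.001, 0.001),
                upper = c(0.5, 0.3, 0.5))
  if (response == "typeIII")
    out <- bind_rows(out, tibble(name = "s", lower = 0.001, upper = 0.1))
  out
}

pm_bounds <- function(pm) {
  if (inherits(pm, "flux_pm")) pm$bounds[, c("name", "lower", "upper")]
  else lv_bounds(pm$response)
}

#' Adaptive random-walk Metropolis within a bounded box
#'
#' The sampler behind [mcmc_calibrate()], usable with any log-posterior.
#' Proposals are Gaussian with per-parameter steps proportional to the
#' prior width; a global scale (initially `2.4^2/d` times a tenth of the
#' width) adapts towards 23.4% acceptance during `burn` iterations.
#' Proposals outside the bounds are rejected, so with a flat log-posterior
#' the chain targets the uniform prior on the box.
#'
#' @param logpost function of a named parameter vector returning the log
#'   posterior (`-Inf` allowed).
#' @param bounds tibble with `name`, `lower`, `upper`.
#' @param n_iter iterations.
#' @param seed RNG seed.
#' @param burn adaptation window (iterations); defaults to half.
#' @return list with `draws` (matrix), `lps`, `acc_rate`.
#' @export
metropolis_sample <- function(logpost, bounds, n_iter, seed = 1L,
                              burn = floor(n_iter / 2)) {
  d <- nrow(bounds)
  width <- bounds$upper - bounds$lower
  with_seed(seed, {
    theta <- setNames(runif(d, bounds$lower, bounds$upper), bounds$name)
    lp <- logpost(theta)
    scale <- 2.4^2 / d * 0.1
    draws <- matrix(NA_real_, n_iter, d, dimnames = list(NULL, bounds$name))
    lps <- numeric(n_iter)
    acc <- 0L; acc_win <- 0L
    for (i in seq_len(n_iter)) {
      prop <- theta + rnorm(d, 0, scale * width)
      if (all(prop >= bounds$lower & prop <= bounds$upper)) {
        lp_prop <- logpost(setNames(prop, bounds$name))
        if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
          theta <- setNames(prop, bounds$name); lp <- lp_prop
          acc <- acc + 1L; acc_win <- acc_win + 1L
        }
      }
      draws[i, ] <- theta; lps[i] <- lp
      if (i <= burn && i %% 50L == 0L) {
        rate <- acc_win / 50
        scale <- min(10, max(1e-8, scale * exp(rate - 0.234)))
        acc_win <- 0L
      }
    }
    if (acc == 0L)
      warn("zero acceptance in a chain; consider smaller steps or more iterations")
    list(draws = draws, lps = lps, acc_rate = acc / n_iter)
  })
}

#' Calibrate a process model by adaptive Metropolis MCMC
#'
#' Random-walk Metropolis within uniform prior bounds: proposals outside
#' the bounds are rejected, per-parameter step sizes start at
#' `2.4^2 / d` times a fraction of the prior width and a global scale is
#' adapted towards 23.4% acceptance during burn-in (first half, discarded
#' for summaries). The MAP estimate is the highest-posterior draw over all
#' post-burn-in samples.
#'
#' @param pm process-model handle.
#' @param data calibration data (see [log_likelihood()]).
#' @param bounds prior bounds tibble (`name`, `lower`, `upper`); defaults
#'   to the handle's bounds.
#' @param n_iter iterations per chain.
#' @param n_chains number of chains.
#' @param seed master seed; per-chain seeds derive from it.
#' @param chain_seeds optional explicit per-chain seeds (identical seeds
#'   give identical chains).
#' @param sd Gaussian likelihood standard deviation.
#' @return object of class `ecopinn_posterior`.
#' @export
mcmc_calibrate <- function(pm, data, bounds = NULL, n_iter = 2000,
                           n_chains = 3, seed = 1L, chain_seeds = NULL,
                           sd = 1) {
  bounds <- bounds %||% pm_bounds(pm)
  d <- nrow(bounds)
  width <- bounds$upper - bounds$lower
  if (is.null(chain_seeds))
    chain_seeds <- vapply(seq_len(n_chains), function(k) derive_seed(seed, k),
                          numeric(1))
  burn <- floor(n_iter / 2)

  logpost <- function(theta) log_likelihood(pm, theta, data, sd = sd)
  chains <- lapply(seq_len(n_chains), function(ch) {
    metropolis_sample(logpost, bounds, n_iter, seed = chain_seeds[ch],
                      burn = burn)
  })

  draws <- bind_rows(lapply(seq_len(n_chains), function(ch) {
    out <- as_tibble(as.data.frame(chains[[ch]]$draws))
    out$logpost <- chains[[ch]]$lps
    out$chain <- ch
    out$iteration <- seq_len(n_iter)
    out
  }))
  post <- draws[draws$iteration > burn, ]
  map_row <- post[which.max(post$logpost), ]
  map <- setNames(as.numeric(map_row[, bounds$name]), bounds$name)

  structure(list(draws = draws, bounds = bounds, burn = burn,
                 n_iter = n_iter, n_chains = n_chains,
                 acceptance = vapply(chains, `[[`, numeric(1), "acc_rate"),
                 map = map, sd = sd),
            class = "ecopinn_posterior")
}

#' @export
print.ecopinn_posterior <- function(x, ...) {
  cat(sprintf("<ecopinn_posterior> %d chains x %d iterations (burn-in %d)\n",
              x$n_chains, x$n_iter, x$burn))
  cat("  acceptance:", paste(sprintf("%.2f", x$acceptance), collapse = ", "), "\n")
  cat("  MAP:", paste(sprintf("%s=%.4g", names(x$map), x$map), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn mcmc_calibrate posterior draws summarised per parameter
#'   (post-burn-in mean, sd, quantiles and MAP).
#' @param x an `ecopinn_posterior`.
#' @export
tidy.ecopinn_posterior <- function(x, ...) {
  post <- x$draws[x$draws$iteration > x$burn, ]
  bind_rows(lapply(x$bounds$name, function(p) {
    v <- post[[p]]
    tibble(term = p, estimate = mean(v), std.error = sd(v),
           conf.low = unname(quantile(v, 0.025)),
           conf.high = unname(quantile(v, 0.975)),
           map = unname(x$map[p]))
  }))
}

#' @export
glance.ecopinn_posterior <- function(x, ...) {
  post <- x$draws[x$draws$iteration > x$burn, ]
  tibble(n_chains = x$n_chains, n_iter = x$n_iter,
         mean_acceptance = mean(x$acceptance),
         max_logpost = max(post$logpost))
}

#' Calibrate a process model by gradient descent
#'
#' Minimises the mean squared error between model predictions and
#' observations by Adam (or plain gradient descent) steps, using the
#' simulators' analytic parameter sensitivities; parameters are clipped to
#' the prior bounds after every step. `epochs` and `lr` may be equal-length
#' vectors describing a staged schedule.
#'
#' @param pm process-model handle.
#' @param data calibration data (see [log_likelihood()]).
#' @param init named initial parameter vector; defaults to the bounds
#'   midpoint.
#' @param epochs steps per stage.
#' @param lr learning rate per stage.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param bounds prior bounds tibble; defaults to the handle's bounds.
#' @param n_starts when no `init` is given, screen this many Latin
#'   hypercube draws from the bounds by their loss (one forward run each)
#'   and descend from the best — multi-start initialisation for
#'   multi-modal calibration surfaces.
#' @param seed seed for the multi-start screen.
#' @return list of class `ecopinn_gradfit`: `params` (fitted vector),
#'   `loss_curve`, `init`.
#' @export
gradient_calibrate <- function(pm, data, init = NULL, epochs = 2000,
                               lr = 1e-3, optimizer = c("adam", "sgd"),
                               bounds = NULL, n_starts = 1, seed = 1L) {
  optimizer <- match.arg(optimizer)
  bounds <- bounds %||% pm_bounds(pm)
  if (length(epochs) != length(lr))
    abort("`epochs` and `lr` must have the same length (schedule stages)")
  y_screen <- if (inherits(pm, "lv_pm")) data$x_obs else data$P_obs
  keep_screen <- which(!is.na(y_screen))
  if (is.null(init) && n_starts > 1) {
    starts <- latin_hypercube(n_starts, bounds, seed = seed)
    losses <- apply(starts, 1, function(v) {
      pred <- tryCatch(pm_predict(pm, setNames(v, bounds$name), data),
                       error = function(e) rep(Inf, length(y_screen)))
      mean((pred[keep_screen] - y_screen[keep_screen])^2)
    })
    init <- setNames(starts[which.min(losses), ], bounds$name)
  }
  # compiled fast path: the whole screen + descent loop for the
  # predator-prey model runs in C++ (plain gradient descent only)
  if (inherits(pm, "lv_pm") && optimizer == "sgd" && length(epochs) == 1) {
    starts <- if (!is.null(init)) {
      matrix(init[bounds$name], nrow = 1)
    } else if (n_starts > 1) {
      latin_hypercube(n_starts, bounds, seed = seed)
    } else {
      matrix((bounds$lower + bounds$upper) / 2, nrow = 1)
    }
    idx0 <- lv_time_index(pm, data$t) - 1L
    res <- lv_calibrate_cpp(data$x_obs, as.integer(idx0), starts,
                            bounds$lower, bounds$upper,
                            pm$init[["x"]], pm$init[["y"]],
                            pm$horizon, pm$step,
                            if (pm$response == "typeIII") 3L else 1L,
                            pm$h_internal, as.integer(epochs), lr)
    return(structure(list(params = setNames(res$params, bounds$name),
                          loss_curve = res$loss_curve,
                          init = setNames(res$init, bounds$name),
                          bounds = bounds),
                     class = "ecopinn_gradfit"))
  }
  theta <- init %||% setNames((bounds$lower + bounds$upper) / 2, bounds$name)
  theta <- theta[bounds$name]
  y <- if (inherits(pm, "lv_pm")) data$x_obs else data$P_obs
  keep <- which(!is.na(y))
  opt <- adam_new(list(length(theta)))
  loss_curve <- numeric(sum(epochs))
  step <- 0L
  for (stage in seq_along(epochs)) {
    for (e in seq_len(epochs[stage])) {
      step <- step + 1L
      pred <- pm_predict(pm, theta, data, sensitivities = TRUE)
      jac <- attr(pred, "jac")
      res <- pred[keep] - y[keep]
      loss_curve[step] <- mean(res^2)
      if (!is.finite(loss_curve[step]))
        abort(sprintf("non-finite loss at step %d", step))
      grad <- 2 * colMeans(res * jac[keep, , drop = FALSE])
      if (optimizer == "adam") {
        upd <- adam_update(opt, list(theta), list(grad), lr[stage])
        opt <- upd$state
        theta <- setNames(as.numeric(upd$params[[1]]), bounds$name)
      } else {
        theta <- theta - lr[stage] * grad
      }
      theta <- pmin(pmax(theta, setNames(bounds$lower, bounds$name)),
                    setNames(bounds$upper, bounds$name))
    }
  }
  structure(list(params = theta, loss_curve = loss_curve,
                 init = init, bounds = bounds),
            class = "ecopinn_gradfit")
}

#' @export
print.ecopinn_gradfit <- function(x, ...) {
  cat("<ecopinn_gradfit>\n  ",
      paste(sprintf("%s=%.4g", names(x$params), x$params), collapse = ", "),
      sprintf("\n  final MSE %.4g after %d steps\n",
              tail(x$loss_curve, 1), length(x$loss_curve)))
  invisible(x)
}
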