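# Evaluation metrics (mean absolute error, quantile association, blocked
# cross-validation spread) and the post hoc individual-conditional-
# expectation (ICE) variable-importance analysis over seasonal windows.

#' Mean absolute error
#' @param y observed values.
#' @param y_hat predictions.
#' @return scalar MAE (same units as `y`).
#' @export
mae <- function(y, y_hat) {
  if (length(y) == 0) abort("empty input")
  if (length(y) != length(y_hat)) abort("length mismatch")
  mean(abs(y - y_hat))
}

#' Quantile association between predictions and observations
#'
#' Reports (a) empirical quantile pairs of predictions vs observations at
#' bin midpoints (a Q-Q view that exposes bias in the lower/higher ranges
#' separately from rank skill) and (b) the Spearman rank correlation.
#' Constant series have undefined correlation, reported as `NA`.
#'
#' @param y observations.
#' @param y_hat predictions.
#' @param n_bins number of quantile bins (>= 2).
#' @return object of class `quantile_association`: list with `table`
#'   (tibble `prob`, `q_obs`, `q_pred`) and `spearman`.
#' @export
quantile_association <- function(y, y_hat, n_bins = 10) {
  if (n_bins < 2) abort("`n_bins` must be at least 2")
  if (length(y) != length(y_hat)) abort("length mismatch")
  probs <- (seq_len(n_bins) - 0.5) / n_bins
  tab <- tibble(prob = probs,
                q_obs = unname(quantile(y, probs)),
                q_pred = unname(quantile(y_hat, probs)))
  rho <- if (sd(y) < 1e-12 || sd(y_hat) < 1e-12) NA_real_
         else cor(y, y_hat, method = "spearman")
  structure(list(table = tab, spearman = rho),
            class = "quantile_association")
}

#' @export
print.quantile_association <- function(x, ...) {
  cat(sprintf("<quantile_association> Spearman rho = %s\n",
              format(x$spearman, digits = 3)))
  print(x$table)
  invisible(x)
}

#' @export
tidy.quantile_association <- function(x, ...) x$table

#' @export
glance.quantile_association <- function(x, ...) {
  tibble(spearman = x$spearman, n_bins = nrow(x$table))
}

# Seasonal 2-week windows: days 1-14 of March, June, September and
# December, expressed as day-of-year ranges (no leap days in the synthetic
# calendar).
season_windows <- function() {
  list(spring = 60:73, summer = 152:165, autumn = 244:257, winter = 335:348)
}

# One-step process-model recomputation for ICE: given the reference run's
# lagged states (previous-day soil, previous-day smoothed temperature),
# recompute P and E for rows whose covariates were modified, without
# re-running the whole recursion. This isolates the same-day partial
# effect of a covariate; effects routed through multi-day water storage
# (e.g. precipitation) are deliberately not propagated.
pm_onestep <- function(data, params, soil_prev, tacc_prev) {
  p <- params$value
  tacc <- tacc_prev + (data$T - tacc_prev) / p[["t_acc"]]
  f_temp <- plogis(p[["kT"]] * (tacc - p[["T0"]]))
  f_vpd <- exp(-p[["kappa"]] * pmax(data$D, 0))
  w <- soil_prev / p[["capacity"]]
  f_water <- pmin(1, pmax(0, (w - p[["wilt"]]) / (p[["sat"]] - p[["wilt"]])))
  P <- p[["beta"]] * data$phi * data$fappfd * f_temp * f_vpd * f_water
  Dc <- pmax(data$D, 1e-3)
  E <- p[["alpha"]] * P * Dc^p[["nu"]] * f_water
  list(P = P, E = E)
}

# reference lagged states per row, from a full-series PM run
pm_ref_states <- function(data, params) {
  if (!"site_id" %in% names(data)) data$site_id <- "site"
  parts <- split(seq_len(nrow(data)), data$site_id)
  soil_prev <- numeric(nrow(data)); tacc_prev <- numeric(nrow(data))
  theta_ref <- numeric(nrow(data))
  for (idx in parts) {
    run <- run_flux_pm(data[idx, ], params)
    soil0 <- if (is.na(flux_initial_state()$theta_soil))
      0.7 * params$value[["capacity"]] else flux_initial_state()$theta_soil
    soil_prev[idx] <- c(soil0, head(run$theta_soil, -1))
    tacc_prev[idx] <- c(data$T[idx][1], head(run$T_acc, -1))
    theta_ref[idx] <- run$theta
  }
  list(soil_prev = soil_prev, tacc_prev = tacc_prev, theta_ref = theta_ref)
}

ice_predict <- function(model, data, rows, variable, value, ref) {
  data2 <- data
  data2[[variable]][rows] <- value
  kind <- model$kind
  needs_pm <- kind %in% c("pm", "parallel_physics", "bias_correction")
  if (needs_pm) {
    os <- pm_onestep(data2[rows, ], model$pm_params,
                     ref$soil_prev[rows], ref$tacc_prev[rows])
    data2$pm_P[rows] <- os$P
    data2$pm_E[rows] <- os$E
    data2$pm_theta[rows] <- ref$theta_ref[rows]
  }
  if (kind == "pm") return(data2$pm_P[rows])
  if (kind == "embedding") return(predict(model, data2)[rows])
  predict(model, data2[rows, ])
}

#' Individual conditional expectations over seasonal windows
#'
#' Varies one explanatory variable over a predefined grid while holding
#' all other covariates at their observed values, predicts daily GPP for
#' each day of four 2-week seasonal windows (early March, June, September,
#' December) of the evaluation year, and averages over each window. The
#' grid spans the variable's observed range in `data` extended by 10%,
#' clamped to the physical range. By default per-day curves are computed
#' first and averaged afterwards; `average_first = TRUE` averages the
#' window's covariates before predicting instead.
#'
#' @param model an `ecopinn_fit` (any kind, including the stand-alone
#'   process model).
#' @param data full daily series containing the evaluation year (per
#'   site).
#' @param variable covariate to vary (`"T"`, `"D"`, `"phi"`, `"R"`,
#'   `"fappfd"`, `"co2"`).
#' @param year evaluation year (default: the last year in `data`).
#' @param grid explicit grid values (overrides `n_grid`).
#' @param n_grid grid size.
#' @param average_first average the window before predicting.
#' @return tibble of class `ecopinn_ice` with columns `season`,
#'   `variable`, `grid_value`, `P_mean`.
#' @export
ice <- function(model, data, variable, year = NULL, grid = NULL,
                n_grid = 25, average_first = FALSE) {
  if (!variable %in% names(data))
    abort(sprintf("variable `%s` is not a model input column", variable))
  year <- year %||% max(data$year)
  if (is.null(grid)) {
    rng <- range(data[[variable]])
    ext <- 0.1 * diff(rng)
    lo <- rng[1] - ext; hi <- rng[2] + ext
    if (variable %in% c("phi", "R", "D")) lo <- max(lo, 0)
    if (variable == "fappfd") { lo <- max(lo, 0); hi <- min(hi, 1) }
    grid <- seq(lo, hi, length.out = n_grid)
  }
  needs_pm <- model$kind %in% c("pm", "parallel_physics", "bias_correction")
  if (needs_pm) {
    if (is.null(model$pm_params)) abort("fit carries no process-model parameters")
    ref <- pm_ref_states(data, model$pm_params)
    if (!"pm_P" %in% names(data)) {
      data$pm_P <- NA_real_; data$pm_E <- NA_real_; data$pm_theta <- NA_real_
    }
  } else ref <- NULL

  windows <- season_windows()
  out <- list()
  for (sn in names(windows)) {
    rows <- which(data$year == year & data$doy %in% windows[[sn]])
    if (!length(rows)) next
    if (average_first) {
      avg <- data[rows, ] %>%
        summarise(across(where(is.numeric), mean),
                  site_id = data$site_id[rows][1] %||% "site")
      avg$year <- year
      curve <- vapply(grid, function(g) {
        ref_avg <- if (needs_pm)
          list(soil_prev = mean(ref$soil_prev[rows]),
               tacc_prev = mean(ref$tacc_prev[rows]),
               theta_ref = mean(ref$theta_ref[rows]))
        else NULL
        mean(ice_predict(model, avg, 1L, variable, g, ref_avg))
      }, numeric(1))
    } else {
      curve <- vapply(grid, function(g) {
        mean(ice_predict(model, data, rows, variable, g, ref))
      }, numeric(1))
    }
    out[[sn]] <- tibble(season = sn, variable = variable,
                        grid_value = grid, P_mean = curve)
  }
  res <- bind_rows(out)
  class(res) <- c("ecopinn_ice", class(res))
  res
}

#' Normalised ICE departure of a model from the process model
#'
#' For each candidate variable, computes the root-mean-square difference
#' between the model's and the process model's window-averaged ICE curves
#' (averaged over seasons), normalised by the standard deviation of
#' observed GPP. Ranks which covariate the data-driven component corrects
#' most — the planted-mismatch detector.
#'
#' @param model fitted variant.
#' @param pm_fit the process-model fit (kind `"pm"`).
#' @param data full daily series with `P_obs`.
#' @param variables covariates to score.
#' @param ... passed to [ice()].
#' @return tibble `variable`, `departure`, sorted decreasing.
#' @export
ice_departure <- function(model, pm_fit, data,
                          variables = c("T", "D", "phi", "R"), ...) {
  sd_y <- sd(data$P_obs, na.rm = TRUE)
  dep <- vapply(variables, function(v) {
    a <- ice(model, data, v, ...)
    b <- ice(pm_fit, data, v, ...)
    j <- inner_join(a, b, by = c("season", "variable", "grid_value"),
                    suffix = c("_m", "_pm"))
    sqrt(mean((j$P_mean_m - j$P_mean_pm)^2)) / sd_y
  }, numeric(1))
  tibble(variable = variables, departure = unname(dep)) %>%
    arrange(desc(.data$departure))
}

#' Evaluate per-fold predictions into a report
#'
#' @param predictions tibble with columns `model`, `fold`, `P_obs` and
#'   `pred` (one row per evaluated day and fold).
#' @return object of class `ecopinn_eval`: per-fold MAE, pooled MAE with
#'   across-fold spread, quantile association and seasonal bias per model,
#'   with the lowest-MAE model flagged as best.
#' @export
evaluate_experiment <- function(predictions) {
  need <- c("model", "fold", "P_obs", "pred")
  miss <- setdiff(need, names(predictions))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  per_fold <- predictions %>%
    group_by(.data$model, .data$fold) %>%
    summarise(mae = mae(.data$P_obs, .data$pred), n = n(), .groups = "drop")
  pooled <- per_fold %>%
    group_by(.data$model) %>%
    summarise(mae_pooled = sum(.data$mae * .data$n) / sum(.data$n),
              mae_sd = if (n() > 1) sd(.data$mae) else NA_real_,
              n = sum(.data$n), .groups = "drop")
  qa <- predictions %>%
    group_by(.data$model) %>%
    summarise(spearman = quantile_association(.data$P_obs, .data$pred)$spearman,
              .groups = "drop")
  pooled <- left_join(pooled, qa, by = "model") %>%
    mutate(best = .data$mae_pooled == min(.data$mae_pooled))
  seasonal <- NULL
  if ("doy" %in% names(predictions)) {
    win <- season_windows()
    season_of <- function(doy) {
      s <- rep(NA_character_, length(doy))
      for (nm in names(win)) s[doy %in% win[[nm]]] <- nm
      # assign remaining days to meteorological seasons
      s[is.na(s) & doy %in% c(335:365, 1:59)] <- "winter"
      s[is.na(s) & doy %in% 60:151] <- "spring"
      s[is.na(s) & doy %in% 152:243] <- "summer"
      s[is.na(s)] <- "autumn"
      s
    }
    seasonal <- predictions %>%
      mutate(season = season_of(.data$doy)) %>%
      group_by(.data$model, .data$season) %>%
      summarise(bias = mean(.data$pred - .data$P_obs), .groups = "drop")
  }
  structure(list(per_fold = per_fold, pooled = pooled, seasonal = seasonal,
                 predictions = predictions),
            class = "ecopinn_eval")
}

#' @export
print.ecopinn_eval <- function(x, ...) {
  cat("<ecopinn_eval>\n")
  print(x$pooled)
  invisible(x)
}

#' @export
tidy.ecopinn_eval <- function(x, ...) x$per_fold

#' @export
glance.ecopinn_eval <- function(x, ...) x$pooled
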