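# Miniature light-use-efficiency flux model: GPP, evapotranspiration and a
# three-pool soil water store, coupled day by day. The daily core is
#   P_k = beta * phi_k * faPPFD_k * f_temp * f_vpd * f_W,P
# with multiplicative modifiers in [0, 1], evapotranspiration
#   E_k = alpha * P_k * D_k^nu * f_W,E
# and a bucket water balance with snow, surface and soil pools. This is a
# deliberately small stand-in for full light-use-efficiency ecosystem
# models: it keeps their structure (theta <-> P coupling through f_W,P,
# E tied to P and theta through f_W,E) with few free parameters, and is
# exactly differentiable in all of them.

#' Default flux-model parameter table
#'
#' Name, default value and prior bounds for the 11 parameters of the flux
#' model. Units: `beta` g C per mol absorbed PAR; `T0` deg C (midpoint of
#' the temperature response, applied to exponentially smoothed air
#' temperature); `kT` 1/deg C; `kappa` 1/kPa; `wilt`, `sat` fractions of
#' bucket capacity bounding the soil-water ramp; `capacity` mm; `melt`
#' mm/(deg C day) degree-day snow melt; `alpha` mm per (g C m^-2);
#' `nu` unitless VPD exponent of E; `t_acc` days (e-folding time of the
#' temperature smoother).
#'
#' @return tibble with columns `name`, `value`, `lower`, `upper`.
#' @export
flux_param_table <- function() {
  tibble(
    name  = c("beta", "T0", "kT", "kappa", "wilt", "sat", "capacity",
              "melt", "alpha", "nu", "t_acc"),
    value = c(0.8, 2, 0.3, 0.4, 0.1, 0.5, 250, 3, 0.25, 0.5, 7),
    lower = c(0.2, -5, 0.05, 0.01, 0.01, 0.3, 100, 0.5, 0.05, 0.1, 1),
    upper = c(2.0, 10, 2.0, 2.0, 0.25, 0.95, 500, 10, 1.0, 1.0, 30)
  )
}

#' Flux-model parameter vector with prior bounds
#'
#' @param ... named parameter values overriding the defaults of
#'   [flux_param_table()].
#' @param table a full parameter table (columns `name`, `value`, `lower`,
#'   `upper`) replacing the default one.
#' @return object of class `flux_params`: list with named numeric `value`,
#'   `lower`, `upper`.
#' @examples
#' flux_params(beta = 1.1, kappa = 0.3)
#' @export
flux_params <- function(..., table = flux_param_table()) {
  override <- list(...)
  value <- setNames(table$value, table$name)
  lower <- setNames(table$lower, table$name)
  upper <- setNames(table$upper, table$name)
  if (length(override)) {
    bad <- setdiff(names(override), names(value))
    if (length(bad)) abort(paste("unknown parameter:", paste(bad, collapse = ", ")))
    value[names(override)] <- unlist(override)
  }
  out_of_bounds <- value < lower | value > upper
  if (any(out_of_bounds))
    abort(paste("parameter outside prior bounds:",
                paste(names(value)[out_of_bounds], collapse = ", ")))
  structure(list(value = value, lower = lower, upper = upper),
            class = "flux_params")
}

#' @export
print.flux_params <- function(x, ...) {
  cat("<flux_params>\n")
  print(tibble(name = names(x$value), value = unname(x$value),
               lower = unname(x$lower), upper = unname(x$upper)), n = Inf)
  invisible(x)
}

as_flux_params <- function(x) {
  if (inherits(x, "flux_params")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    tab <- flux_param_table()
    return(flux_params(table = mutate(tab, value = unname(x[.data$name]))))
  }
  abort("cannot interpret `params` as flux parameters")
}

#' Initial water-pool state
#'
#' @param theta_soil soil pool (mm); `NA` means 0.7 x capacity (the
#'   default spin-up-free initialisation).
#' @param theta_snow snow pool (mm).
#' @param theta_surface surface pool (mm); always drained by day end.
#' @return object of class `flux_state`.
#' @export
flux_initial_state <- function(theta_soil = NA_real_, theta_snow = 0,
                               theta_surface = 0) {
  structure(list(theta_soil = theta_soil, theta_snow = theta_snow,
                 theta_surface = theta_surface), class = "flux_state")
}

check_covariates <- function(covariates, need = c("T", "D", "phi", "R", "fappfd")) {
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    abort(paste("missing covariate columns:", paste(miss, collapse = ", ")))
  if ("doy" %in% names(covariates) && nrow(covariates) > 1) {
    d <- diff(covariates$doy)
    ok <- d == 1 | d < -300   # +1 within a year, or a year-boundary wrap
    if (!all(ok)) abort("gap in the daily series (doy must be contiguous)")
  }
  invisible(covariates)
}

#' Daily environmental modifiers
#'
#' Computes the multiplicative modifiers for one day: a logistic
#' temperature response on the smoothed temperature state, an exponential
#' vapour-pressure-deficit decay, and the shared soil-water ramp used for
#' both `f_W,P` and `f_W,E` (piecewise linear in soil water between the
#' wilting and saturation fractions of capacity).
#'
#' @param state list with `theta_soil` (previous day, mm) and `T_acc`
#'   (smoothed temperature, deg C).
#' @param cov one-day covariates (needs `D`).
#' @param params a [flux_params()] object.
#' @return named vector `c(f_temp, f_vpd, f_water)`, all in `[0, 1]`.
#' @export
flux_modifiers <- function(state, cov, params) {
  p <- params$value
  f_temp <- plogis(p[["kT"]] * (state$T_acc - p[["T0"]]))
  f_vpd <- exp(-p[["kappa"]] * max(cov$D, 0))
  w <- state$theta_soil / p[["capacity"]]
  f_water <- min(1, max(0, (w - p[["wilt"]]) / (p[["sat"]] - p[["wilt"]])))
  c(f_temp = f_temp, f_vpd = f_vpd, f_water = f_water)
}

#' One day of gross primary productivity
#'
#' The light-use-efficiency core: `P = beta * phi * faPPFD *` product of
#' modifiers. Non-negative by construction.
#'
#' @param cov one-day covariates (needs `phi`, `fappfd`).
#' @param mods modifiers from [flux_modifiers()] (uses `f_temp`, `f_vpd`,
#'   `f_water`).
#' @param params a [flux_params()] object.
#' @return scalar P (g C m^-2 day^-1).
#' @export
gpp_step <- function(cov, mods, params) {
  unname(params$value[["beta"]] * cov$phi * cov$fappfd *
           mods[["f_temp"]] * mods[["f_vpd"]] * mods[["f_water"]])
}

#' One day of the water balance
#'
#' Routes precipitation to the snow pool below 0 deg C and through the
#' surface pool (fully drained to soil the same day) otherwise; melts snow
#' at a degree-day rate; extracts the evapotranspiration demand limited by
#' available water; and drains the soil pool above capacity. All pools stay
#' non-negative, and `theta_k - theta_{k-1} = R_k - E_k - drainage_k`
#' closes exactly.
#'
#' @param state list with pools `theta_soil`, `theta_snow` (mm).
#' @param cov one-day covariates (needs `T`, `R`).
#' @param params a [flux_params()] object.
#' @param e_demand evapotranspiration demand for the day (mm, default 0).
#' @return list with the next-day pools plus realised `E`, `melt`,
#'   `drainage`.
#' @export
water_balance_step <- function(state, cov, params, e_demand = 0) {
  p <- params$value
  if (!all(is.finite(c(cov$T, cov$R)))) abort("non-finite covariates")
  rain <- if (cov$T < 0) 0 else cov$R
  snow_in <- if (cov$T < 0) cov$R else 0
  snow <- state$theta_snow + snow_in
  melt <- min(snow, p[["melt"]] * max(cov$T, 0))
  snow <- snow - melt
  avail <- state$theta_soil + rain + melt
  E <- min(e_demand, avail)
  soil <- avail - E
  drainage <- max(soil - p[["capacity"]], 0)
  soil <- soil - drainage
  list(theta_soil = soil, theta_snow = snow, theta_surface = 0,
       E = E, melt = melt, drainage = drainage)
}

#' Run the flux process model over a daily series
#'
#' Day-by-day recursion over a contiguous daily covariate series, returning
#' the three coupled state series P (GPP), E (evapotranspiration) and theta
#' (total stored water), the individual pools, the modifiers and the
#' smoothed temperature. With `sensitivities = TRUE`, exact Jacobians of
#' P, E and theta with respect to all 11 parameters are attached as
#' attributes `JP`, `JE`, `Jtheta` (each n x 11) — computed by analytic
#' chain rule through the recursion, not by finite differences.
#'
#' @param covariates tibble with daily columns `T`, `D`, `phi`, `R`,
#'   `fappfd` (and optionally `doy`, used to detect gaps).
#' @param params a [flux_params()] object (or named vector).
#' @param init a [flux_initial_state()].
#' @param sensitivities attach parameter Jacobians.
#' @return tibble: input columns plus `P`, `E`, `theta`, `theta_soil`,
#'   `theta_snow`, `theta_surface`, `f_temp`, `f_vpd`, `f_water`, `T_acc`.
#' @examples
#' cov <- tibble::tibble(T = rep(15, 10), D = 0.5, phi = 30, R = 2,
#'                       fappfd = 0.8)
#' run_flux_pm(cov, flux_params())
#' @export
run_flux_pm <- function(covariates, params = flux_params(),
                        init = flux_initial_state(), sensitivities = FALSE) {
  params <- as_flux_params(params)
  check_covariates(covariates)
  res <- flux_run_cpp(covariates$T, covariates$D, covariates$phi,
                      covariates$R, covariates$fappfd, unname(params$value),
                      init$theta_soil, init$theta_snow, sensitivities,
                      -1, 1)
  out <- bind_cols(as_tibble(covariates),
                   as_tibble(res[c("P", "E", "theta", "theta_soil",
                                   "theta_snow", "theta_surface",
                                   "f_temp", "f_vpd", "f_water", "T_acc")]))
  class(out) <- c("flux_run", class(out))
  attr(out, "params") <- params
  if (sensitivities) {
    for (nm in c("JP", "JE", "Jtheta")) {
      colnames(res[[nm]]) <- names(params$value)
      attr(out, nm) <- res[[nm]]
    }
  }
  out
}

# Pure-R reference recursion built from the exported day-step functions;
# used as the independent route in tests against the compiled kernel.
run_flux_pm_r <- function(covariates, params = flux_params(),
                          init = flux_initial_state()) {
  params <- as_flux_params(params)
  p <- params$value
  n <- nrow(covariates)
  soil <- if (is.na(init$theta_soil)) 0.7 * p[["capacity"]] else init$theta_soil
  snow <- init$theta_snow
  t_acc_state <- covariates$T[1]
  out <- vector("list", n)
  for (k in seq_len(n)) {
    cov <- covariates[k, ]
    t_acc_state <- t_acc_state + (cov$T - t_acc_state) / p[["t_acc"]]
    mods <- flux_modifiers(list(theta_soil = soil, T_acc = t_acc_state),
                           cov, params)
    P <- gpp_step(cov, mods, params)
    Dc <- max(cov$D, 1e-3)
    e_demand <- p[["alpha"]] * P * Dc^p[["nu"]] * mods[["f_water"]]
    wb <- water_balance_step(list(theta_soil = soil, theta_snow = snow),
                             cov, params, e_demand = e_demand)
    soil <- wb$theta_soil; snow <- wb$theta_snow
    out[[k]] <- tibble(P = P, E = wb$E, theta = soil + snow,
                       theta_soil = soil, theta_snow = snow,
                       theta_surface = 0,
                       f_temp = mods[["f_temp"]], f_vpd = mods[["f_vpd"]],
                       f_water = mods[["f_water"]], T_acc = t_acc_state)
  }
  bind_cols(as_tibble(covariates), bind_rows(out))
}

#' Flux process-model handle
#'
#' Bundles prior bounds and initial pools so the flux model can be passed
#' around as a calibration target and PINN component.
#'
#' @param bounds parameter table as in [flux_param_table()].
#' @param init a [flux_initial_state()].
#' @return an object of class `flux_pm`.
#' @export
flux_pm <- function(bounds = flux_param_table(), init = flux_initial_state()) {
  structure(list(kind = "flux", bounds = bounds, init = init),
            class = c("flux_pm", "ecopinn_pm"))
}
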