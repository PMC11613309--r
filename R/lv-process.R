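# Predator-prey (Lotka-Volterra) simulators: the type III data-generating
# model and the simplified type I model, sharing one differentiable
# fixed-step RK4 integrator.

#' Predator-prey model parameters
#'
#' Bundles the rates of the Lotka-Volterra system. The prey searching time
#' `s` is only meaningful for the sigmoidal (type III) functional response
#' and must be omitted (`NULL`) for the linear (type I) response.
#'
#' @param r prey growth rate (1/time).
#' @param b predator feeding rate (1/(density x time)).
#' @param m predator mortality rate (1/time).
#' @param s prey searching time (type III only); `NULL` for type I.
#' @return an object of class `lv_params`.
#' @examples
#' lv_params(r = 0.1, b = 0.02, m = 0.04, s = 0.025)
#' @export
lv_params <- function(r, b, m, s = NULL) {
  for (v in c("r", "b", "m")) stopifnot_scalar(get(v), v)
  if (any(c(r, b, m) < 0)) abort("all rates must be non-negative")
  if (!is.null(s)) {
    stopifnot_scalar(s)
    if (s < 0) abort("`s` must be non-negative")
  }
  structure(list(r = r, b = b, m = m, s = s), class = "lv_params")
}

#' @export
print.lv_params <- function(x, ...) {
  cat("<lv_params>", if (is.null(x$s)) "type I" else "type III", "\n")
  cat(sprintf("  r = %g, b = %g, m = %g%s\n", x$r, x$b, x$m,
              if (is.null(x$s)) "" else sprintf(", s = %g", x$s)))
  invisible(x)
}

check_response <- function(params, response) {
  response <- match.arg(response, c("typeI", "typeIII"))
  if (response == "typeIII" && is.null(params$s))
    abort("type III functional response requires the searching time `s`")
  if (response == "typeI" && !is.null(params$s))
    abort("type I functional response must not carry a searching time `s`")
  response
}

#' Instantaneous predator-prey rates of change
#'
#' Evaluates the right-hand side of the predator-prey system. With the
#' type III (sigmoidal) response the feeding term is
#' `b x^2 y / (1 + s x^2)`; the type I (linear) response uses `b x y`.
#'
#' @param state named vector or list with prey density `x`, predator
#'   density `y` (both non-negative) and optionally time `t`.
#' @param params an [lv_params()] object.
#' @param response `"typeI"` or `"typeIII"`.
#' @return named numeric vector `c(dx, dy)`.
#' @examples
#' p <- lv_params(0.1, 0.02, 0.04, 0.025)
#' lv_derivatives(c(x = 10, y = 10), p, "typeIII")
#' @export
lv_derivatives <- function(state, params, response = c("typeI", "typeIII")) {
  response <- check_response(params, response)
  x <- state[["x"]]; y <- state[["y"]]
  if (x < 0) abort("negative prey density `x`")
  if (y < 0) abort("negative predator density `y`")
  feeding <- if (response == "typeIII") {
    params$b * x^2 * y / (1 + params$s * x^2)
  } else {
    params$b * x * y
  }
  c(dx = params$r * x - feeding, dy = feeding - params$m * y)
}

#' Simulate a predator-prey trajectory
#'
#' Integrates the system with a classical fixed-step 4th-order Runge-Kutta
#' scheme at internal step `h_internal`, subsampled to the requested output
#' grid. With `sensitivities = TRUE` the forward sensitivity equations are
#' integrated alongside, giving exact gradients of every grid-point density
#' with respect to `(r, b, m, s, x0, y0)` — the substrate that lets
#' calibration and embedding-style training backpropagate through the
#' simulator.
#'
#' @param params an [lv_params()] object.
#' @param init named vector `c(x = , y = )` of initial densities.
#' @param horizon simulation length (time units); must be a multiple of `step`.
#' @param step output grid spacing (time units).
#' @param response `"typeI"` or `"typeIII"`.
#' @param h_internal internal integrator step (default 0.05).
#' @param sensitivities also return gradient matrices `Sx`, `Sy`
#'   (columns `r, b, m, s, x0, y0`) as attributes.
#' @return a tibble with columns `t`, `x`, `y` of class `lv_trajectory`.
#' @examples
#' p <- lv_params(0.1, 0.02, 0.04, 0.025)
#' traj <- lv_integrate(p, c(x = 10, y = 10), horizon = 130, step = 0.5,
#'                      response = "typeIII")
#' nrow(traj)  # 261 grid points
#' @export
lv_integrate <- function(params, init, horizon, step,
                         response = c("typeI", "typeIII"),
                         h_internal = 0.05, sensitivities = FALSE) {
  response <- check_response(params, response)
  if (step <= 0) abort("`step` must be positive")
  n_out <- round(horizon / step)
  if (abs(n_out * step - horizon) > 1e-8 * max(1, horizon))
    abort("`horizon` must be a multiple of `step`")
  res <- lv_integrate_cpp(params$r, params$b, params$m,
                          if (is.null(params$s)) 0 else params$s,
                          init[["x"]], init[["y"]], horizon, step,
                          if (response == "typeIII") 3L else 1L,
                          h_internal, sensitivities)
  out <- tibble(t = res$t, x = res$x, y = res$y)
  class(out) <- c("lv_trajectory", class(out))
  attr(out, "params") <- params
  attr(out, "response") <- response
  attr(out, "init") <- c(x = init[["x"]], y = init[["y"]])
  if (sensitivities) {
    cn <- c("r", "b", "m", "s", "x0", "y0")
    colnames(res$Sx) <- cn; colnames(res$Sy) <- cn
    attr(out, "Sx") <- res$Sx
    attr(out, "Sy") <- res$Sy
  }
  out
}

#' Observe noisy prey densities at random grid times
#'
#' Draws `n_obs` distinct times uniformly without replacement from the
#' trajectory's grid and returns the prey density there, perturbed by
#' additive Gaussian noise. Negative noisy readings are kept as-is.
#'
#' @param traj an [lv_integrate()] trajectory.
#' @param n_obs number of observations (at most the grid size).
#' @param noise_sd standard deviation of the observation noise (>= 0).
#' @param seed RNG seed; the same seed reproduces the same observations.
#' @return tibble with columns `t`, `x_obs` (sorted by time) and the grid
#'   row indices as attribute `idx`.
#' @export
lv_observe <- function(traj, n_obs, noise_sd = 0, seed = NULL) {
  if (n_obs > nrow(traj))
    abort(sprintf("n_obs = %d exceeds the %d grid points", n_obs, nrow(traj)))
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  with_seed(seed, {
    idx <- sort(sample.int(nrow(traj), n_obs, replace = FALSE))
    obs <- tibble(t = traj$t[idx],
                  x_obs = traj$x[idx] + rnorm(n_obs, 0, noise_sd))
    attr(obs, "idx") <- idx
    obs
  })
}

#' Conserved quantity of the type I system
#'
#' Along exact interior orbits of the linear-response system the quantity
#' `H(x, y) = b x + b y - m log(x) - r log(y)` is constant; its drift under
#' the integrator measures integration error.
#'
#' @param traj an [lv_integrate()] trajectory (type I, positive densities).
#' @param params an [lv_params()] object.
#' @return numeric vector of `H` along the trajectory.
#' @export
lv_conserved <- function(traj, params) {
  if (any(traj$x <= 0 | traj$y <= 0))
    abort("conserved quantity requires strictly positive densities")
  params$b * traj$x + params$b * traj$y -
    params$m * log(traj$x) - params$r * log(traj$y)
}

#' Predator-prey process-model handle
#'
#' A lightweight description of the predator-prey model used as process
#' model inside calibration and PINN variants: functional response,
#' assumed initial conditions, horizon and output step. The assumed initial
#' conditions are part of the model configuration, not estimated.
#'
#' @param response `"typeI"` or `"typeIII"`.
#' @param init assumed initial densities, named vector `c(x = , y = )`.
#' @param horizon,step simulation grid.
#' @param h_internal internal RK4 step.
#' @return an object of class `lv_pm`.
#' @export
lv_pm <- function(response = c("typeI", "typeIII"), init = c(x = 12, y = 10),
                  horizon = 130, step = 0.5, h_internal = 0.05) {
  response <- match.arg(response)
  structure(list(kind = "lv", response = response,
                 init = c(x = init[["x"]], y = init[["y"]]),
                 horizon = horizon, step = step, h_internal = h_internal),
            class = c("lv_pm", "ecopinn_pm"))
}

# parameter names calibrated for a given lv handle
lv_par_names <- function(pm) {
  if (pm$response == "typeIII") c("r", "b", "m", "s") else c("r", "b", "m")
}

lv_params_from_vec <- function(pm, value) {
  lv_params(value[["r"]], value[["b"]], value[["m"]],
            if (pm$response == "typeIII") value[["s"]] else NULL)
}

# grid index of an observation time
lv_time_index <- function(pm, t) {
  idx <- round(t / pm$step) + 1L
  if (any(abs((idx - 1L) * pm$step - t) > 1e-8))
    abort("observation times must lie on the simulation grid")
  idx
}
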