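# Serialisation: CSV for trajectories, observations, daily flux series,
# parameter tables and posterior draws; JSON (with an architecture echo)
# for network checkpoints; YAML for run configuration.

#' Write / read predator-prey trajectories and observation sets
#'
#' Trajectories use columns `t, x, y`; observation sets use `t, x_obs`.
#'
#' @param traj an [lv_integrate()] trajectory.
#' @param obs an [lv_observe()] observation set.
#' @param path file path.
#' @return the read tibble (readers) or the path, invisibly (writers).
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(as.data.frame(traj[, c("t", "x", "y")]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  out <- as_tibble(read.csv(path))
  if (!all(c("t", "x", "y") %in% names(out)))
    abort("trajectory CSV needs columns t, x, y")
  out
}

#' @rdname write_trajectory_csv
#' @export
write_observations_csv <- function(obs, path) {
  write.csv(as.data.frame(obs[, c("t", "x_obs")]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_observations_csv <- function(path) {
  out <- as_tibble(read.csv(path))
  if (!all(c("t", "x_obs") %in% names(out)))
    abort("observation CSV needs columns t, x_obs")
  out
}

#' Write / read a daily flux series CSV
#'
#' The on-disk schema is `site_id, date, year, doy, T, D, phi, R, fappfd,
#' co2` plus any of `P_obs`, `P_true`, `pm_P`, `pm_E`, `pm_theta` present.
#'
#' @param data flux tibble.
#' @param path file path.
#' @return (`read_flux_csv`) the tibble, schema-checked.
#' @export
write_flux_csv <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flux_csv
#' @export
read_flux_csv <- function(path) {
  out <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("site_id", "year", "doy", "T", "D", "phi", "R", "fappfd", "co2")
  miss <- setdiff(need, names(out))
  if (length(miss))
    abort(paste("flux CSV lacks columns:", paste(miss, collapse = ", ")))
  if ("date" %in% names(out)) out$date <- as.Date(out$date)
  out
}

#' Write / read a process-model parameter table
#'
#' Plain CSV with columns `name, value, lower, upper`, the interchange
#' format between calibration output and the variants that consume a
#' calibrated model.
#'
#' @param params a [flux_params()] object.
#' @param path file path.
#' @return (`read_params_csv`) a [flux_params()] object.
#' @export
write_params_csv <- function(params, path) {
  write.csv(data.frame(name = names(params$value),
                       value = unname(params$value),
                       lower = unname(params$lower),
                       upper = unname(params$upper)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params_csv
#' @export
read_params_csv <- function(path) {
  tab <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  flux_params(table = tab)
}

#' Write posterior draws to CSV
#'
#' One row per (chain, iteration) with the parameter columns and the log
#' posterior.
#'
#' @param posterior an `ecopinn_posterior`.
#' @param path file path.
#' @export
write_posterior_csv <- function(posterior, path) {
  write.csv(as.data.frame(posterior$draws), path, row.names = FALSE)
  invisible(path)
}

#' Save / load a network checkpoint
#'
#' JSON with the architecture echoed alongside the flattened weights, so
#' a checkpoint is self-describing and human-inspectable.
#'
#' @param net an `ecopinn_mlp`.
#' @param path file path.
#' @return (`read_checkpoint`) the restored network.
#' @export
write_checkpoint <- function(net, path) {
  payload <- list(
    spec = list(input_dim = net$spec$input_dim, hidden = net$spec$hidden,
                output_dim = net$spec$output_dim,
                activation = net$spec$activation),
    W = lapply(net$W, function(w) list(dim = dim(w), data = as.numeric(w))),
    b = net$b)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- mlp_spec(payload$spec$input_dim, payload$spec$hidden,
                   payload$spec$output_dim, payload$spec$activation)
  W <- if (is.data.frame(payload$W)) {
    lapply(seq_len(nrow(payload$W)), function(i)
      matrix(payload$W$data[[i]], payload$W$dim[[i]][1], payload$W$dim[[i]][2]))
  } else {
    lapply(payload$W, function(w) matrix(w$data, w$dim[1], w$dim[2]))
  }
  b <- if (is.list(payload$b)) lapply(payload$b, as.numeric)
       else list(as.numeric(payload$b))
  structure(list(spec = spec, W = W, b = b), class = "ecopinn_mlp")
}

#' Read a YAML run configuration
#'
#' @param path YAML file with experiment settings (`experiment`,
#'   `scenario`, `variant`, `seeds`, budgets, ...).
#' @return named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
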