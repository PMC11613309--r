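# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}

#' Fit a feature standardiser
#'
#' Computes per-column means and standard deviations used to z-score model
#' inputs. Constant columns get unit scale so they pass through unchanged
#' (minus their mean), which keeps site-constant covariates such as CO2
#' usable as features.
#'
#' @param X numeric matrix (rows = observations).
#' @return an object of class `ecopinn_scaler`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  sigma[!is.finite(sigma) | sigma < 1e-12] <- 1
  structure(list(mean = mu, sd = sigma), class = "ecopinn_scaler")
}

#' Apply (or invert) a fitted standardiser
#'
#' @param X numeric matrix.
#' @param scaler object from [fit_scaler()].
#' @param invert if `TRUE`, map standardised values back to the data scale.
#' @return matrix of the same shape as `X`.
#' @export
apply_scaler <- function(X, scaler, invert = FALSE) {
  X <- as.matrix(X)
  if (invert) sweep(sweep(X, 2, scaler$sd, "*"), 2, scaler$mean, "+")
  else sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

# seeds derived from a master seed stay below 2^31, also under nesting
derive_seed <- function(seed, k) {
  s <- as.numeric(seed) %% 65011
  as.integer((s * 1103 + as.numeric(k) * 12345) %% 2147480017)
}
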