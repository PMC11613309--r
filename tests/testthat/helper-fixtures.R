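# Shared fixtures, all generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a
`%>%` <- dplyr::`%>%`

box1_truth <- function() lv_params(r = 0.1, b = 0.02, m = 0.04, s = 0.025)

# a short synthetic daily climate for one site (deterministic per seed)
tiny_climate <- function(n_days = 400, seed = 11) {
  s <- site_spec("tiny", mat = 8, t_amp = 10, precip_mean = 2,
                 wet_prob = 0.4, years = 2001:(2000 + ceiling(n_days / 365)))
  clim <- gen_climate(s, seed = seed)
  clim[seq_len(n_days), ]
}

# a bias-correction network constructed to reproduce the (standardised) P
# input exactly on its linear region: hidden unit = relu(P_std + shift)
# with a large shift, undone in the output layer. Used to test the
# embedding composition identity.
identity_bias_net <- function(phy_scaler, shift = 50) {
  spec <- mlp_spec(3, hidden = 1, output_dim = 1, activation = "relu")
  net <- mlp_init(spec, seed = 1)
  net$W[[1]] <- matrix(c(1, 0, 0), 3, 1)
  net$b[[1]] <- shift
  net$W[[2]] <- matrix(phy_scaler$sd[["P"]], 1, 1)
  net$b[[2]] <- phy_scaler$mean[["P"]] - shift * phy_scaler$sd[["P"]]
  net
}

# central finite-difference gradient of f at x (vector-valued x)
fd_grad <- function(f, x, h = NULL) {
  vapply(seq_along(x), function(j) {
    hj <- if (is.null(h)) max(1e-6, abs(x[j]) * 1e-6) else h
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    (f(xp) - f(xm)) / (2 * hj)
  }, numeric(1))
}
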