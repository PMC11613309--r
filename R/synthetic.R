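# Synthetic study systems: (a) the complete predator-prey scenario suite
# (data sparsity / structural error / observation noise); (b) multi-site
# daily flux datasets with controlled structural mismatch between the
# data-generating "truth" and the process model, emulating a network of
# five forest sites with distinct climates and 4-7 years of daily data.
#
# All functional forms and parameter tables here are package inventions
# standing in for real eddy-covariance data, chosen so that every
# prediction problem (temporal, spatial, spatio-temporal transfer) and
# data scenario (rich/sparse) can be exercised end to end. The synthetic
# calendar has no leap days (every year has 365 days).

#' Predator-prey benchmark scenario
#'
#' The three printed conditions: (i) data sparsity only (process model
#' structurally correct), (ii) sparsity plus structural error (linear
#' instead of sigmoidal feeding), (iii) additionally Gaussian observation
#' noise with sd 0.5. Nine prey observations in all scenarios.
#'
#' @param id `"i"`, `"ii"` or `"iii"`.
#' @return list of class `box1_scenario`.
#' @export
box1_scenario <- function(id = c("i", "ii", "iii")) {
  id <- match.arg(id)
  structure(list(
    id = id,
    generator_response = "typeIII",
    pm_response = if (id == "i") "typeIII" else "typeI",
    pm_init = if (id == "i") c(x = 10, y = 10) else c(x = 12, y = 10),
    noise_sd = if (id == "iii") 0.5 else 0,
    n_obs = 9L), class = "box1_scenario")
}

#' Generate one predator-prey scenario realisation
#'
#' Simulates the sigmoidal-feeding truth (r = 0.1, b = 0.02, m = 0.04,
#' s = 0.025, initial densities 10/10) over 130 time units at step 0.5,
#' draws 9 prey observations at random grid times with the scenario's
#' noise, and returns the (possibly mis-specified) process-model handle
#' with its assumed initial conditions.
#'
#' @param scenario a [box1_scenario()] (or its id string).
#' @param seed RNG seed for the observation draw.
#' @return list with `trajectory`, `observations`, `pm` ([lv_pm()]
#'   handle), `truth` ([lv_params()]), `scenario`.
#' @export
gen_box1 <- function(scenario = box1_scenario("i"), seed = 1L) {
  if (is.character(scenario)) scenario <- box1_scenario(scenario)
  truth <- lv_params(r = 0.1, b = 0.02, m = 0.04, s = 0.025)
  traj <- lv_integrate(truth, c(x = 10, y = 10), horizon = 130, step = 0.5,
                       response = "typeIII")
  obs <- lv_observe(traj, scenario$n_obs, scenario$noise_sd, seed = seed)
  pm <- lv_pm(response = scenario$pm_response, init = scenario$pm_init)
  list(trajectory = traj, observations = obs, pm = pm, truth = truth,
       scenario = scenario)
}

#' Synthetic forest-site specification
#'
#' Climate and truth-model settings for one site: seasonal temperature
#' regime, precipitation regime, radiation amplitude, canopy phenology
#' (evergreen or deciduous faPPFD trajectory, delivered at 8-day
#' resolution), site-specific parameter offsets for the data-generating
#' model, and the structural-mismatch flags (`phi_sat` — radiation
#' saturation absent from the process model; `fw_gamma` — site-varying
#' curvature of the soil-water response).
#'
#' @param site_id site label.
#' @param mat mean annual temperature (deg C).
#' @param t_amp seasonal temperature amplitude (deg C).
#' @param precip_mean mean precipitation (mm/day, long-run).
#' @param wet_prob probability of a wet day.
#' @param winter_wet concentrate rain in winter (mediterranean regime).
#' @param rad_peak midsummer clear-sky PAR (mol m^-2 day^-1).
#' @param phenology `"evergreen"` or `"deciduous"`.
#' @param fappfd_range min/max canopy absorption fraction.
#' @param co2 site CO2 (ppm, constant).
#' @param years calendar years covered.
#' @param beta_mult site multiplier on the truth light-use efficiency.
#' @param t0_offset shift (deg C) of the truth temperature-response
#'   midpoint; coniferous canopies photosynthesise at lower temperatures
#'   than deciduous ones, a contrast a single shared process-model
#'   calibration must compromise on.
#' @param phi_sat radiation saturation scale (mol m^-2 day^-1); `NA`
#'   disables the mismatch.
#' @param fw_gamma exponent on the soil-water modifier in the truth model
#'   (1 = no mismatch).
#' @param noise_floor,noise_scale heteroscedastic observation noise:
#'   sd = floor + scale * sqrt(P).
#' @return list of class `site_spec`.
#' @export
site_spec <- function(site_id, mat, t_amp, precip_mean, wet_prob,
                      winter_wet = FALSE, rad_peak = 45,
                      phenology = c("evergreen", "deciduous"),
                      fappfd_range = c(0.7, 0.85), co2 = 400,
                      years = 2004:2008, beta_mult = 1,
                      t0_offset = if (match.arg(phenology) == "evergreen")
                        -2.5 else 2.5,
                      phi_sat = 25, fw_gamma = 1,
                      noise_floor = 0.3, noise_scale = 0.15) {
  phenology <- match.arg(phenology)
  if (length(years) < 1) abort("a site needs at least one year")
  structure(list(site_id = site_id, mat = mat, t_amp = t_amp,
                 precip_mean = precip_mean, wet_prob = wet_prob,
                 winter_wet = winter_wet, rad_peak = rad_peak,
                 phenology = phenology, fappfd_range = fappfd_range,
                 co2 = co2, years = years, beta_mult = beta_mult,
                 t0_offset = t0_offset,
                 phi_sat = phi_sat, fw_gamma = fw_gamma,
                 noise_floor = noise_floor, noise_scale = noise_scale),
            class = "site_spec")
}

#' Default five-site network
#'
#' Five synthetic forest sites spanning boreal to mediterranean climates
#' and evergreen to deciduous canopies, 4-7 years each, all containing the
#' 2005 and 2008 calendar years used by the transfer experiments. The
#' boreal site is the transfer target. All sites share the radiation
#' saturation mismatch (`phi_sat = 25`); the soil-water curvature varies
#' by site.
#'
#' @return named list of [site_spec()]s.
#' @export
default_sites <- function() {
  list(
    boreal = site_spec("boreal", mat = 4, t_amp = 13, precip_mean = 1.7,
                       wet_prob = 0.45, rad_peak = 42,
                       phenology = "evergreen", fappfd_range = c(0.72, 0.82),
                       co2 = 395, years = 2003:2008, beta_mult = 1,
                       fw_gamma = 1),
    temperate = site_spec("temperate", mat = 9, t_amp = 9, precip_mean = 2.2,
                          wet_prob = 0.42, rad_peak = 46,
                          phenology = "deciduous", fappfd_range = c(0.15, 0.9),
                          co2 = 400, years = 2004:2008, beta_mult = 1.15,
                          fw_gamma = 0.8),
    mountain = site_spec("mountain", mat = 6, t_amp = 9.5, precip_mean = 2.6,
                         wet_prob = 0.5, rad_peak = 48,
                         phenology = "evergreen", fappfd_range = c(0.68, 0.8),
                         co2 = 398, years = 2004:2008, beta_mult = 0.9,
                         fw_gamma = 1.2),
    mediterranean = site_spec("mediterranean", mat = 14, t_amp = 8,
                              precip_mean = 1.6, wet_prob = 0.3,
                              winter_wet = TRUE, rad_peak = 52,
                              phenology = "deciduous",
                              fappfd_range = c(0.2, 0.85),
                              co2 = 402, years = 2002:2008, beta_mult = 1.1,
                              fw_gamma = 1.5),
    oceanic = site_spec("oceanic", mat = 12, t_amp = 6.5, precip_mean = 2.6,
                        wet_prob = 0.55, rad_peak = 46,
                        phenology = "evergreen", fappfd_range = c(0.7, 0.85),
                        co2 = 401, years = 2005:2008, beta_mult = 1.05,
                        fw_gamma = 0.7)
  )
}

# daily faPPFD phenology curve, then held constant within 8-day blocks
# (satellite-product resolution converted to daily by constancy)
fappfd_curve <- function(doy, site) {
  lo <- site$fappfd_range[1]; hi <- site$fappfd_range[2]
  daily <- if (site$phenology == "evergreen") {
    hi - (hi - lo) * 0.5 * (1 + cos(2 * pi * (doy - 200) / 365)) * 0.25
  } else {
    lo + (hi - lo) * plogis((doy - 115) / 9) * (1 - plogis((doy - 285) / 11))
  }
  block <- (doy - 1) %/% 8
  vapply(split(seq_along(doy), block), function(ix) mean(daily[ix]),
         numeric(1))[as.character(block)]
}

#' Generate a daily climate series for one site
#'
#' Temperature is a seasonal sinusoid plus AR(1) noise; PAR is a seasonal
#' clear-sky curve damped by cloudiness (coupled to wet days); VPD grows
#' exponentially with temperature and drops on wet days; precipitation is
#' a seasonal occurrence/intensity process; faPPFD follows the phenology
#' curve at 8-day block resolution; CO2 is constant.
#'
#' @param site a [site_spec()].
#' @param seed RNG seed (deterministic series per seed).
#' @return daily tibble: `site_id`, `year`, `doy`, `date`, `T`, `D`,
#'   `phi`, `R`, `fappfd`, `co2`.
#' @export
gen_climate <- function(site, seed = 1L) {
  with_seed(seed, {
    years <- site$years
    n <- 365L * length(years)
    year <- rep(years, each = 365L)
    doy <- rep(1:365, length(years))

    ar <- numeric(n); ar[1] <- rnorm(1, 0, 2.2)
    innov <- rnorm(n, 0, 2.2 * sqrt(1 - 0.7^2))
    for (k in 2:n) ar[k] <- 0.7 * ar[k - 1] + innov[k]
    T <- site$mat + site$t_amp * cos(2 * pi * (doy - 200) / 365) + ar

    wet_season <- if (site$winter_wet)
      0.2 * cos(2 * pi * (doy - 15) / 365)
    else
      0.08 * cos(2 * pi * (doy - 180) / 365)
    p_wet <- pmin(0.95, pmax(0.05, site$wet_prob + wet_season))
    wet <- rbinom(n, 1, p_wet)
    intensity <- site$precip_mean / site$wet_prob
    R <- wet * rgamma(n, shape = 0.9, scale = intensity / 0.9)

    # cloudiness: an AR(1)-driven index largely independent of the wet-day
    # process, so radiation carries day-to-day information that no other
    # covariate proxies
    arc <- numeric(n); arc[1] <- rnorm(1)
    innov_c <- rnorm(n, 0, sqrt(1 - 0.5^2))
    for (k in 2:n) arc[k] <- 0.5 * arc[k - 1] + innov_c[k]
    cloudiness <- plogis(arc + 0.6 * wet)
    clear <- pmax(2, site$rad_peak *
                    (0.28 + 0.72 * 0.5 * (1 + cos(2 * pi * (doy - 172) / 365))))
    phi <- clear * (1 - 0.65 * cloudiness)

    D <- pmax(0.01, 0.12 * exp(0.055 * T) * (1 - 0.15 * wet) +
                rnorm(n, 0, 0.06))

    fap <- as.numeric(fappfd_curve(doy, site))

    tibble(site_id = site$site_id, year = year, doy = doy,
           date = as.Date(paste(year, "01", "01", sep = "-")) + (doy - 1),
           T = T, D = D, phi = phi, R = R, fappfd = fap, co2 = site$co2)
  })
}

# truth-model parameters for a site: defaults with the site offsets
site_truth_params <- function(site) {
  tab <- flux_param_table()
  tab$value[tab$name == "beta"] <- tab$value[tab$name == "beta"] * site$beta_mult
  tab$value[tab$name == "T0"] <- tab$value[tab$name == "T0"] +
    (site$t0_offset %||% 0)
  flux_params(table = tab)
}

#' Generate observed GPP from the structural truth model
#'
#' Runs the flux model with site-offset parameters plus the structural
#' perturbations the process model does not contain (radiation saturation
#' `phi_sat`; soil-water curvature `fw_gamma`), then adds heteroscedastic
#' Gaussian observation noise (sd = floor + scale * sqrt(P)). The
#' noise-free truth is kept in `P_true` for oracle checks.
#'
#' @param covariates a [gen_climate()] series.
#' @param site the [site_spec()].
#' @param seed RNG seed for the noise.
#' @param noise add observation noise (disable for exact-truth checks).
#' @return `covariates` plus columns `P_true` and `P_obs`.
#' @export
gen_flux_truth <- function(covariates, site, seed = 1L, noise = TRUE) {
  params <- site_truth_params(site)
  res <- flux_run_cpp(covariates$T, covariates$D, covariates$phi,
                      covariates$R, covariates$fappfd,
                      unname(params$value), NA_real_, 0, FALSE,
                      if (is.na(site$phi_sat)) -1 else site$phi_sat,
                      site$fw_gamma)
  out <- covariates
  out$P_true <- res$P
  out$P_obs <- if (noise) {
    with_seed(seed, res$P + rnorm(length(res$P),
                                  0, site$noise_floor +
                                    site$noise_scale * sqrt(res$P)))
  } else res$P
  out
}

#' Generate the full multi-site flux dataset
#'
#' @param sites list of [site_spec()]s (default: [default_sites()]).
#' @param seed master seed; per-site climate and noise seeds derive from
#'   it.
#' @return daily tibble over all sites with covariates, `P_true` and
#'   `P_obs`; the generator manifest (sites, seeds, flags) is attached as
#'   attribute `manifest`.
#' @export
gen_flux_dataset <- function(sites = default_sites(), seed = 1L) {
  out <- bind_rows(lapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    clim <- gen_climate(s, seed = derive_seed(seed, i))
    gen_flux_truth(clim, s, seed = derive_seed(seed, 1000L + i))
  }))
  attr(out, "manifest") <- list(
    seed = seed,
    sites = lapply(sites, function(s)
      list(site_id = s$site_id, years = range(s$years),
           phenology = s$phenology, phi_sat = s$phi_sat,
           fw_gamma = s$fw_gamma, beta_mult = s$beta_mult)))
  attr(out, "provenance") <- "observed"
  out
}
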