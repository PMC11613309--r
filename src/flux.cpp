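#include <Rcpp.h>
using namespace Rcpp;

// Miniature light-use-efficiency flux model.
//
// Daily recursion over covariates (T, D, phi, R, fappfd). States: soil and
// snow water pools (mm) plus an exponentially smoothed temperature used for
// seasonal acclimation. Outputs per day: gross primary productivity P,
// evapotranspiration E, total water storage theta, the pools, and the
// multiplicative modifiers.
//
// Parameter vector p (length 11), in this order:
//   0 beta      potential light-use efficiency (g C / mol)
//   1 T0        temperature response midpoint (degC, on smoothed T)
//   2 kT        temperature response steepness (1/degC)
//   3 kappa     VPD sensitivity (1/kPa), f_D = exp(-kappa * D)
//   4 wilt      wilting point as fraction of capacity
//   5 sat       saturation point as fraction of capacity
//   6 capacity  soil bucket capacity (mm)
//   7 melt      degree-day snow melt rate (mm / degC / day)
//   8 alpha     evapotranspiration coefficient (mm per g C m^-2)
//   9 nu        VPD exponent in E
//  10 t_acc     e-folding time of the temperature smoother (days)
//
// Water modifiers f_W,P = f_W,E = clamp((w - wilt)/(sat - wilt), 0, 1) with
// w = soil_{k-1}/capacity (previous-day coupling). Precipitation falls as
// snow below 0 degC, else rains through a surface pool that drains fully to
// the soil the same day; melt is degree-day limited by the snow store;
// drainage caps the soil pool at capacity.
//
// Sensitivities: dsoil/dp, dsnow/dp, dTacc/dp are propagated day by day by
// the chain rule (piecewise-smooth branches use the active branch's
// derivative), yielding exact Jacobians dP/dp, dE/dp, dtheta/dp.
//
// Structural-perturbation hooks (generator only, incompatible with sens):
//   phi_sat > 0 replaces phi by phi_sat * (1 - exp(-phi / phi_sat))
//   fw_gamma != 1 replaces f_W,P by f_W,P^gamma

static const int NP = 11;

// [[Rcpp::export]]
List flux_run_cpp(NumericVector T, NumericVector D, NumericVector phi,
                  NumericVector R, NumericVector fappfd,
                  NumericVector p, double init_soil, double init_snow,
                  bool sens, double phi_sat, double fw_gamma) {
  int n = T.size();
  if (D.size() != n || phi.size() != n || R.size() != n || fappfd.size() != n)
    stop("covariate columns have unequal lengths");
  if (p.size() != NP) stop("parameter vector must have length %d", NP);
  if (sens && (phi_sat > 0.0 || fw_gamma != 1.0))
    stop("sensitivities are not available with structural perturbations");

  const double beta = p[0], T0 = p[1], kT = p[2], kappa = p[3], wilt = p[4],
               sat = p[5], capacity = p[6], melt_rate = p[7], alpha = p[8],
               nu = p[9], t_acc = p[10];
  if (t_acc < 1e-8) stop("t_acc must be positive");
  if (sat <= wilt) stop("sat must exceed wilt");

  NumericVector P(n), E(n), theta(n), soil_out(n), snow_out(n), surface_out(n),
      f_temp(n), f_vpd(n), f_water(n), Tacc_out(n);
  NumericMatrix JP, JE, JT;
  if (sens) { JP = NumericMatrix(n, NP); JE = NumericMatrix(n, NP); JT = NumericMatrix(n, NP); }

  // state and its parameter gradients
  double soil, snow = init_snow, Tacc = T[0];
  double dsoil[NP] = {0}, dsnow[NP] = {0}, dTacc[NP] = {0};
  if (ISNA(init_soil)) {        // default: 0.7 * capacity, so d/dcapacity = 0.7
    soil = 0.7 * capacity;
    dsoil[6] = 0.7;
  } else {
    soil = init_soil;
  }

  const double a = 1.0 / t_acc;
  const double da_dtacc = -1.0 / (t_acc * t_acc);

  double g[NP];  // scratch gradient

  for (int k = 0; k < n; ++k) {
    if (!std::isfinite(T[k]) || !std::isfinite(D[k]) || !std::isfinite(phi[k]) ||
        !std::isfinite(R[k]) || !std::isfinite(fappfd[k]))
      stop("non-finite covariate at row %d", k + 1);

    // temperature smoother: Tacc <- Tacc + a (T_k - Tacc)
    double resid = T[k] - Tacc;
    Tacc += a * resid;
    if (sens) {
      for (int j = 0; j < NP; ++j) dTacc[j] *= (1.0 - a);
      dTacc[10] += resid * da_dtacc;
    }

    // modifiers (water uses previous-day soil)
    double arg = kT * (Tacc - T0);
    double ft = 1.0 / (1.0 + std::exp(-arg));
    double Dpos = D[k] > 0.0 ? D[k] : 0.0;
    double fd = std::exp(-kappa * Dpos);
    double w = soil / capacity;
    double u = (w - wilt) / (sat - wilt);
    double fw = u < 0.0 ? 0.0 : (u > 1.0 ? 1.0 : u);

    double dft[NP] = {0}, dfd[NP] = {0}, dfw[NP] = {0};
    if (sens) {
      double ftp = ft * (1.0 - ft);
      for (int j = 0; j < NP; ++j) dft[j] = ftp * kT * dTacc[j];
      dft[1] += ftp * (-kT);              // T0
      dft[2] += ftp * (Tacc - T0);        // kT
      dfd[3] = -Dpos * fd;                // kappa
      if (u > 0.0 && u < 1.0) {
        double denom = sat - wilt;
        for (int j = 0; j < NP; ++j) dfw[j] = dsoil[j] / capacity / denom;
        double dw_dcap = -soil / (capacity * capacity);
        dfw[6] += dw_dcap / denom;
        dfw[4] += (-1.0 + u) / denom;     // wilt: (-(denom) + (w-wilt))/denom^2
        dfw[5] += -u / denom;             // sat
      }
    }

    // GPP (light-use efficiency core)
    double phi_eff = phi[k];
    if (phi_sat > 0.0) phi_eff = phi_sat * (1.0 - std::exp(-phi[k] / phi_sat));
    double fwP = fw;
    if (fw_gamma != 1.0) fwP = std::pow(fw, fw_gamma);
    double core = phi_eff * fappfd[k];
    double Pk = beta * core * ft * fd * fwP;

    double dP[NP] = {0};
    if (sens) {
      for (int j = 0; j < NP; ++j)
        dP[j] = beta * core * (dft[j] * fd * fw + ft * dfd[j] * fw + ft * fd * dfw[j]);
      dP[0] += core * ft * fd * fw;       // beta
    }

    // evapotranspiration demand E0 = alpha * P * D^nu * f_W,E
    double Dc = Dpos > 1e-3 ? Dpos : 1e-3;
    double Dnu = std::pow(Dc, nu);
    double E0 = alpha * Pk * Dnu * fw;
    double dE0[NP] = {0};
    if (sens) {
      for (int j = 0; j < NP; ++j)
        dE0[j] = alpha * Dnu * (dP[j] * fw + Pk * dfw[j]);
      dE0[8] += Pk * Dnu * fw;                      // alpha
      dE0[9] += alpha * Pk * Dnu * std::log(Dc) * fw; // nu
    }

    // water balance
    double rain = 0.0, snow_in = 0.0;
    if (T[k] < 0.0) snow_in = R[k]; else rain = R[k];
    double snow_tmp = snow + snow_in;
    double melt_pot = melt_rate * (T[k] > 0.0 ? T[k] : 0.0);
    double melt_k;
    bool melt_limited = snow_tmp < melt_pot;
    melt_k = melt_limited ? snow_tmp : melt_pot;

    double avail = soil + rain + melt_k;
    bool e_limited = E0 > avail;
    double Ek = e_limited ? avail : E0;
    double soil_tmp = avail - Ek;
    double over = soil_tmp - capacity;
    double drain = over > 0.0 ? over : 0.0;

    if (sens) {
      double dmelt[NP];
      for (int j = 0; j < NP; ++j) dmelt[j] = melt_limited ? dsnow[j] : 0.0;
      if (!melt_limited) dmelt[7] = (T[k] > 0.0 ? T[k] : 0.0);
      for (int j = 0; j < NP; ++j) {
        double davail = dsoil[j] + dmelt[j];
        double dEk = e_limited ? davail : dE0[j];
        double dsoil_tmp = davail - dEk;
        double ddrain = over > 0.0 ? dsoil_tmp : 0.0;
        if (over > 0.0 && j == 6) ddrain -= 1.0;    // capacity
        g[j] = dsoil_tmp - ddrain;                  // new dsoil
        dsnow[j] = dsnow[j] - dmelt[j];
        JE(k, j) = dEk;
      }
      for (int j = 0; j < NP; ++j) dsoil[j] = g[j];
      for (int j = 0; j < NP; ++j) { JP(k, j) = dP[j]; JT(k, j) = dsoil[j] + dsnow[j]; }
    }

    snow = snow_tmp - melt_k;
    soil = soil_tmp - drain;

    P[k] = Pk; E[k] = Ek;
    soil_out[k] = soil; snow_out[k] = snow; surface_out[k] = 0.0;
    theta[k] = soil + snow;
    f_temp[k] = ft; f_vpd[k] = fd; f_water[k] = fw; Tacc_out[k] = Tacc;
  }

  List out = List::create(
      _["P"] = P, _["E"] = E, _["theta"] = theta,
      _["theta_soil"] = soil_out, _["theta_snow"] = snow_out,
      _["theta_surface"] = surface_out,
      _["f_temp"] = f_temp, _["f_vpd"] = f_vpd, _["f_water"] = f_water,
      _["T_acc"] = Tacc_out);
  if (sens) { out["JP"] = JP; out["JE"] = JE; out["Jtheta"] = JT; }
  return out;
}
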