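#include <Rcpp.h>
using namespace Rcpp;

// Coupled per-cell integrator: size-spectrum ecology (upwind advection in
// mass, exponential mortality/harvest decay) + open-access effort dynamics.
// Cells are independent; forcing is annual and constant within a year.
//
// B0:      biomass array (ncell x ngroup x nbin), g m^-2 per bin
// effort0: nominal effort per cell, W m^-2 (recycled if length 1)
// sst/npp: (ncell x nyear)
// q/price/cost: per-year scalars (catchability m^2 W^-1 yr^-1, $ kg^-1,
//               $ W^-1 yr^-1)
// effort_mode: 0 = profit-driven (open access), 1 = fixed effort
// Returns final state plus annual per-cell harvest (g m^-2 yr^-1, year mean),
// effort and total biomass (year means).
// [[Rcpp::export]]
List cpp_run_coupled(NumericVector B0, NumericVector effort0,
                     NumericMatrix sst, NumericMatrix npp,
                     NumericVector q_year, NumericVector price_year,
                     NumericVector cost_year,
                     List pars,
                     NumericMatrix psi, NumericMatrix sel,
                     IntegerVector last_bin,
                     NumericVector m, NumericVector dm,
                     IntegerVector n_sub, int effort_mode) {
  const int nc = sst.nrow(), ny = sst.ncol();
  const int ng = psi.nrow(), nb = psi.ncol();

  const double eps   = as<double>(pars["eps_trophic"]);
  const double ppmr  = as<double>(pars["ppmr"]);
  const double A     = as<double>(pars["growth_A"]);
  const double b     = as<double>(pars["growth_b"]);
  const double zeta  = as<double>(pars["mort_zeta"]);
  const double h     = as<double>(pars["mort_h"]);
  const double Ea    = as<double>(pars["Ea"]);
  const double s_egg = as<double>(pars["s_egg"]);
  const double K     = as<double>(pars["recruit_K"]);
  const double Tref  = as<double>(pars["T_ref"]);
  const double m_p   = as<double>(pars["m_phyto"]);
  const double k_e   = as<double>(pars["k_e"]);
  const double E_floor = as<double>(pars["E_floor"]);

  const double kB = 8.617e-5;
  const double n_steps = std::log(10.0 / m_p) / std::log(ppmr); // m_min = 10 g
  const double npp2wet = (12.011 / 1000.0) * 365.0 * 10.0;

  std::vector<double> amb1(nb), amb(nb), zb(nb);
  for (int i = 0; i < nb; ++i) {
    amb1[i] = A * std::pow(m[i], b - 1.0);
    amb[i]  = A * std::pow(m[i], b);
    zb[i]   = zeta * std::pow(m[i], h - 1.0);
  }

  NumericVector B = clone(B0);
  NumericVector E(nc);
  for (int c = 0; c < nc; ++c)
    E[c] = (effort0.size() == 1) ? effort0[0] : effort0[c];

  NumericMatrix harv_out(nc, ny), eff_out(nc, ny), biom_out(nc, ny);

  std::vector<double> dec(ng * nb), fracF(ng * nb);
  const int cg = nc, cgg = nc * ng; // strides: (c,g,i) -> c + nc*g + nc*ng*i

  for (int y = 0; y < ny; ++y) {
    const double q = q_year[y], price = price_year[y], cost = cost_year[y];
    for (int c = 0; c < nc; ++c) {
      const int ns = (n_sub.size() == 1) ? n_sub[0] : n_sub[c];
      const double dt = 1.0 / ns;
      const double T = sst(c, y);
      const double tau = std::exp(-Ea / kB * (1.0 / (T + 273.15) - 1.0 / (Tref + 273.15)));
      const double e_in = npp(c, y) * npp2wet * std::pow(eps, n_steps) / tau;
      const double R_sat = e_in / ng;

      bool cache_decay = (effort_mode == 1);
      if (cache_decay) {
        const double qE = q * E[c];
        for (int g = 0; g < ng; ++g)
          for (int i = 0; i < last_bin[g]; ++i) {
            const double Z = tau * zb[i];
            const double F = qE * sel(g, i);
            const double Zt = Z + F;
            dec[g + ng * i] = std::exp(-Zt * dt);
            fracF[g + ng * i] = (Zt > 0.0) ? F / Zt : 0.0;
          }
      }

      double harv_year = 0.0, eff_year = 0.0, biom_year = 0.0;
      for (int s = 0; s < ns; ++s) {
        // food limitation from unconstrained demand
        double D = 0.0;
        for (int g = 0; g < ng; ++g)
          for (int i = 0; i < last_bin[g]; ++i)
            D += B[c + cg * g + cgg * i] * amb1[i];
        D *= tau;
        const double xi = (D > 0.0 && D > e_in) ? e_in / D : 1.0;

        const double qE = q * E[c];
        double harv_sub = 0.0, btot = 0.0;
        for (int g = 0; g < ng; ++g) {
          // egg production and recruitment
          double e_g = 0.0;
          for (int i = 0; i < last_bin[g]; ++i)
            e_g += psi(g, i) * amb1[i] * B[c + cg * g + cgg * i];
          e_g *= s_egg * xi * tau;
          const double Rg = (e_g > 0.0) ? R_sat * e_g / (e_g + K) : 0.0;

          // upwind advection (explicit) then exponential decay
          double phin = Rg;
          for (int i = 0; i < last_bin[g]; ++i) {
            const int idx = c + cg * g + cgg * i;
            const double gam = tau * xi * amb[i] * (1.0 - psi(g, i));
            const double phout = gam * B[idx] / dm[i];
            double Bs = B[idx] + dt * (phin - phout);
            phin = phout;
            double d, fF;
            if (cache_decay) {
              d = dec[g + ng * i];
              fF = fracF[g + ng * i];
            } else {
              const double Z = tau * zb[i];
              const double F = qE * sel(g, i);
              const double Zt = Z + F;
              d = std::exp(-Zt * dt);
              fF = (Zt > 0.0) ? F / Zt : 0.0;
            }
            const double Bn = Bs * d;
            harv_sub += (Bs - Bn) * fF;
            B[idx] = Bn;
            btot += Bn;
          }
        }
        const double h_rate = harv_sub / dt;   // g m^-2 yr^-1
        harv_year += harv_sub;
        biom_year += btot;
        eff_year += E[c];
        if (effort_mode == 0) {
          E[c] += dt * k_e * (price * h_rate / 1000.0 - cost * E[c]);
          if (E[c] < E_floor) E[c] = E_floor;
        }
      }
      harv_out(c, y) = harv_year;             // g m^-2 over 1 yr
      eff_out(c, y)  = eff_year / ns;
      biom_out(c, y) = biom_year / ns;
    }
  }
  return List::create(_["B"] = B, _["effort"] = E,
                      _["harvest"] = harv_out, _["effort_mean"] = eff_out,
                      _["biomass"] = biom_out);
}
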