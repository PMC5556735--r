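#' Logarithmic body-mass axis
#'
#' Thirty log-spaced bins spanning 10 g to 1e5 g wet weight, shared by the
#' three community groups (asymptotic masses 3e2, 1e4 and 1e5 g). Each group
#' occupies the bins up to its asymptotic mass; growth out of a group's last
#' bin is an advective sink (death of the oldest/largest fish).
#'
#' @param n_bins Number of bins.
#' @param m_min,m_max Axis limits, g.
#' @param m_asym Group asymptotic masses, g.
#' @return List of class `fc_axis`: `edges`, `m` (geometric bin centres),
#'   `dm` (bin widths, g), `m_asym`, `last_bin` (per-group last occupied bin).
#' @export
mass_axis <- function(n_bins = fc_const$n_bins,
                      m_min = fc_const$m_min, m_max = fc_const$m_max,
                      m_asym = fc_const$m_asymptotic) {
  edges <- exp(seq(log(m_min), log(m_max), length.out = n_bins + 1))
  m <- sqrt(edges[-1] * edges[-(n_bins + 1)])
  dm <- diff(edges)
  last_bin <- vapply(m_asym, function(M) max(which(m <= M)), integer(1))
  structure(list(edges = edges, m = m, dm = dm, m_asym = m_asym,
                 last_bin = last_bin, n_bins = n_bins, n_groups = length(m_asym)),
            class = "fc_axis")
}

#' Arrhenius temperature factor
#'
#' `exp(-Ea/kB * (1/(T+273.15) - 1/(T_ref+273.15)))`: 1 at the reference
#' temperature, increasing with temperature for positive activation energy.
#' A single factor scales growth and mortality and (inversely) trophic
#' transfer.
#'
#' @param T_c Temperature, degC.
#' @param Ea Activation energy, eV.
#' @param T_ref Reference temperature, degC.
#' @return Dimensionless factor.
#' @export
temperature_factor <- function(T_c, Ea, T_ref = 10) {
  exp(-Ea / fc_const$k_boltzmann * (1 / (T_c + 273.15) - 1 / (T_ref + 273.15)))
}

#' Energy input to the fish community
#'
#' Converts net primary production to wet-biomass production
#' (12.011e-3 g C mmol^-1, 365 d yr^-1, 10 g wet per g C) and discounts it by
#' `eps_trophic^n` where `n = log(m_min/m_phyto)/log(ppmr)` is the number of
#' predator-prey steps from phytoplankton to the smallest resolved fish.
#' Warming lowers the realized transfer through division by the Arrhenius
#' factor (respiratory losses grow with metabolic rate).
#'
#' @param npp NPP, mmol C m^-2 d^-1.
#' @param T_c Temperature, degC.
#' @param params [fc_params()].
#' @return Energy input, g wet m^-2 yr^-1.
#' @export
energy_input <- function(npp, T_c, params) {
  phi <- npp * (fc_const$g_c_per_mol / 1000) * fc_const$days_per_yr *
    fc_const$wet_per_c
  n_steps <- log(fc_const$m_min / params$m_phyto) / log(params$ppmr)
  phi * params$eps_trophic^n_steps /
    temperature_factor(T_c, params$Ea, params$T_ref)
}

#' Somatic growth rate
#'
#' `A * tau(T) * m^b * food_limitation * (1 - psi(m))`, where `psi` is the
#' logistic maturity allocation toward reproduction and `food_limitation`
#' caps community energy acquisition at the available input.
#'
#' @param m Body mass, g.
#' @param T_c Temperature, degC.
#' @param params [fc_params()].
#' @param food_limitation In `[0, 1]`.
#' @param psi Maturity allocation at `m` (default 0).
#' @return g yr^-1.
#' @export
growth_rate <- function(m, T_c, params, food_limitation = 1, psi = 0) {
  stopifnot(all(food_limitation >= 0), all(food_limitation <= 1))
  params$growth_A * temperature_factor(T_c, params$Ea, params$T_ref) *
    m^params$growth_b * food_limitation * (1 - psi)
}

#' Natural mortality rate
#'
#' `zeta * tau(T) * m^(h-1)`: allometric, declining with mass for `h < 1`.
#'
#' @inheritParams growth_rate
#' @return yr^-1.
#' @export
natural_mortality <- function(m, T_c, params) {
  params$mort_zeta * temperature_factor(T_c, params$Ea, params$T_ref) *
    m^(params$mort_h - 1)
}

# Maturity allocation psi(m): logistic in log10 mass, midpoint at
# psi_center * m_asym, rising to repro_frac. Matrix (group x bin).
fc_psi <- function(axis, params) {
  t(vapply(axis$m_asym, function(M) {
    params$repro_frac /
      (1 + exp(-(log10(axis$m) - log10(params$psi_center * M)) / params$psi_width))
  }, numeric(axis$n_bins)))
}

# Harvest selectivity: logistic in ln mass, 0.5 at sel_ratio * m_asym.
fc_sel <- function(axis, params) {
  t(vapply(axis$m_asym, function(M) {
    1 / (1 + exp(-(log(axis$m) - log(params$sel_ratio * M)) / params$sel_width))
  }, numeric(axis$n_bins)))
}

# Occupancy mask (group x bin): TRUE up to the group's last bin.
fc_mask <- function(axis) {
  t(vapply(axis$last_bin, function(l) seq_len(axis$n_bins) <= l,
           logical(axis$n_bins)))
}

#' Food limitation, egg production and recruitment
#'
#' The community's unconstrained energy demand is
#' `D = sum(B * A * tau * m^(b-1))`; the realized acquisition is capped at the
#' energy input through `xi = min(1, E_in / D)`. Each group's egg-production
#' flux is `e_g = s_egg * sum(psi * A * tau * m^(b-1) * xi * B)` and
#' recruitment into the smallest bin saturates as
#' `R_g = (E_in / n_groups) * e_g / (e_g + recruit_K)` (Beverton-Holt).
#'
#' @param B Biomass matrix (group x bin), g m^-2.
#' @param T_c,npp Cell temperature (degC) and NPP (mmol C m^-2 d^-1).
#' @param params [fc_params()].
#' @param axis [mass_axis()].
#' @return List: `xi` (food limitation), `e` (egg flux per group),
#'   `R` (recruitment flux per group, g m^-2 yr^-1), `E_in`, `demand`.
#' @export
recruitment_flux <- function(B, T_c, npp, params, axis = mass_axis()) {
  tau <- temperature_factor(T_c, params$Ea, params$T_ref)
  mask <- fc_mask(axis)
  amb1 <- params$growth_A * tau * axis$m^(params$growth_b - 1)
  E_in <- energy_input(npp, T_c, params)
  demand <- sum(t(t(B * mask) * amb1))
  xi <- if (demand > 0) min(1, E_in / demand) else 1
  psi <- fc_psi(axis, params)
  e <- params$s_egg * xi * rowSums(t(t(B * mask * psi) * amb1))
  R_sat <- E_in / axis$n_groups
  R <- R_sat * e / (e + params$recruit_K)
  R[e <= 0] <- 0
  list(xi = xi, e = e, R = R, E_in = E_in, demand = demand)
}

#' Advance the size spectra of one cell by one sub-step
#'
#' First-order upwind flux-form discretization of
#' `df/dt + d(gamma f)/dm = -(Z_nat + F) f` per group on the log-mass axis.
#' Recruitment enters as the boundary flux at the smallest bin; growth out of
#' a group's last bin is lost. Advection is explicit (CFL-limited); mortality
#' and harvest are applied as exact exponential decay within the sub-step, so
#' biomass stays non-negative for any admissible `dt` and the mass budget
#' closes to round-off.
#'
#' @param B Biomass matrix (group x bin), g m^-2.
#' @param T_c,npp Cell forcing.
#' @param F_mort Fishing mortality (group x bin) or scalar, yr^-1.
#' @param dt Sub-step, yr; must satisfy `dt <= 0.8 * min(dm / gamma)`.
#' @param params,axis Model configuration.
#' @return List: `B` (updated), and the step budget in g m^-2:
#'   `recruit_in`, `natural_loss`, `harvest`, `top_loss`.
#' @export
step_ecology <- function(B, T_c, npp, F_mort, dt, params, axis = mass_axis()) {
  ng <- axis$n_groups; nb <- axis$n_bins
  if (length(F_mort) == 1) F_mort <- matrix(F_mort, ng, nb)
  mask <- fc_mask(axis)
  tau <- temperature_factor(T_c, params$Ea, params$T_ref)
  psi <- fc_psi(axis, params)
  rec <- recruitment_flux(B, T_c, npp, params, axis)

  gamma <- params$growth_A * tau * rec$xi *
    outer(rep(1, ng), axis$m^params$growth_b) * (1 - psi)
  cfl <- dt * max(t(t(gamma * mask) / axis$dm))
  if (cfl > 0.8 + 1e-12) {
    worst <- which.max(t(t(gamma * mask) / axis$dm))
    stop(sprintf("dt = %.4g exceeds the stability limit (CFL %.2f at bin %d)",
                 dt, cfl, (worst - 1) %/% ng + 1), call. = FALSE)
  }
  Z <- outer(rep(1, ng), natural_mortality(axis$m, T_c, params))

  phi <- t(t(B * mask) / axis$dm) * gamma          # upwind flux out of each bin
  B_star <- B
  top_loss <- 0
  for (g in seq_len(ng)) {
    l <- axis$last_bin[g]
    inflow <- c(rec$R[g], phi[g, seq_len(l - 1)])
    B_star[g, 1:l] <- B[g, 1:l] + dt * (inflow - phi[g, 1:l])
    top_loss <- top_loss + dt * phi[g, l]
  }
  Ztot <- Z + F_mort
  decay <- exp(-Ztot * dt)
  B_new <- B_star * decay
  loss <- (B_star - B_new) * mask
  frac_F <- ifelse(Ztot > 0, F_mort / Ztot, 0)
  harvest <- sum(loss * frac_F)
  natural <- sum(loss) - harvest
  B_new[!mask] <- 0

  list(B = B_new * mask,
       recruit_in = dt * sum(rec$R),
       natural_loss = natural,
       harvest = harvest,
       top_loss = top_loss,
       xi = rec$xi)
}

#' Stability limit for the ecology sub-step
#'
#' `0.8 * min(dm_i / gamma_max_i)` with the growth rate evaluated at the
#' warmest temperature the run will see, unlimited food and zero maturity
#' allocation (the fastest admissible advection).
#'
#' @param params,axis Model configuration.
#' @param T_max Warmest SST of the forcing, degC.
#' @return List: `dt` (yr), `n_sub` (sub-steps per year, `ceiling(1/dt)`).
#' @export
stability_dt <- function(params, axis = mass_axis(), T_max = 35) {
  tau <- temperature_factor(T_max, params$Ea, params$T_ref)
  gmax <- params$growth_A * tau * axis$m^params$growth_b
  dt <- 0.8 * min(axis$dm / gmax)
  # keep the explicit effort update comfortably stable as well
  dt <- min(dt, 0.2 / (params$k_e * params$cost0))
  n_sub <- ceiling(1 / dt)
  list(dt = 1 / n_sub, n_sub = n_sub)
}

# Per-cell sub-step counts from each cell's warmest temperature: cold cells
# advect slowly and need far fewer sub-steps than warm ones.
fc_nsub_cells <- function(params, axis, T_max_cells) {
  vapply(T_max_cells, function(Tm) {
    as.integer(stability_dt(params, axis, T_max = max(Tm, params$T_ref))$n_sub)
  }, integer(1))
}

#' Unfished (pristine) equilibrium of one or more cells
#'
#' Solves the discrete steady state of the spectrum equations under zero
#' fishing: given the food limitation `xi` and recruitment fluxes, the upwind
#' scheme's equilibrium follows bin-by-bin in closed form; `xi` and the
#' recruitment fluxes are then iterated to self-consistency (damped fixed
#' point). Used to seed spin-up and constant-q equilibrium runs.
#'
#' @param T_c,npp Vectors over cells (degC, mmol C m^-2 d^-1).
#' @param params,axis Model configuration.
#' @param F_mort Optional fishing mortality: scalar, or (group x bin) matrix
#'   applied to every cell.
#' @param dt Sub-step the equilibrium should be consistent with (the decay
#'   factor enters the discrete steady state); defaults to the stability step.
#' @param tol Relative fixed-point tolerance.
#' @param max_iter Iteration cap.
#' @return Array (cell x group x bin) of biomass, g m^-2.
#' @export
equilibrium_spectrum <- function(T_c, npp, params, axis = mass_axis(),
                                 F_mort = 0, dt = NULL,
                                 tol = 1e-10, max_iter = 400) {
  nc <- length(T_c); ng <- axis$n_groups; nb <- axis$n_bins
  if (is.null(dt)) dt <- 1 / fc_nsub_cells(params, axis, T_c)
  dt <- rep_len(dt, nc)   # per-cell sub-step, matching the integrator's
  if (length(F_mort) == 1) F_mort <- matrix(F_mort, ng, nb)
  mask <- fc_mask(axis)
  psi <- fc_psi(axis, params)
  tau <- temperature_factor(T_c, params$Ea, params$T_ref)
  E_in <- energy_input(npp, T_c, params)
  amb1 <- params$growth_A * axis$m^(params$growth_b - 1)   # x tau later
  Zb <- params$mort_zeta * axis$m^(params$mort_h - 1)      # x tau later

  xi <- rep(1, nc)
  R <- matrix(E_in / (2 * ng), nc, ng)   # starting guess
  B <- array(0, c(nc, ng, nb))
  for (it in seq_len(max_iter)) {
    for (g in seq_len(ng)) {
      phi_in <- R[, g]
      for (i in seq_len(axis$last_bin[g])) {
        gam <- params$growth_A * tau * xi * axis$m[i]^params$growth_b *
          (1 - psi[g, i])
        Ztot <- tau * Zb[i] + F_mort[g, i]
        denom <- expm1(Ztot * dt) / dt + gam / axis$dm[i]
        Bi <- phi_in / denom
        B[, g, i] <- Bi
        phi_in <- gam * Bi / axis$dm[i]
      }
    }
    amb1_gb <- matrix(amb1, ng, nb, byrow = TRUE)
    Bmat <- matrix(B, nc, ng * nb)
    demand <- tau * as.vector(Bmat %*% as.vector(mask * amb1_gb))
    xi_new <- ifelse(demand > 0, pmin(1, E_in / demand), 1)
    e <- vapply(seq_len(ng), function(g) {
      as.vector(matrix(B[, g, ], nc, nb) %*% (mask[g, ] * psi[g, ] * amb1))
    }, numeric(nc))
    e <- params$s_egg * xi_new * tau * matrix(e, nc, ng)
    R_new <- (E_in / ng) * e / (e + params$recruit_K)
    R_new[e <= 0] <- 0
    d1 <- max(abs(xi_new - xi))
    d2 <- max(abs(R_new - R) / (abs(R) + 1e-12))
    xi <- 0.5 * xi + 0.5 * xi_new
    R <- 0.5 * R + 0.5 * R_new
    if (max(d1, d2) < tol) break
  }
  B
}

#' Spin up a cell to its pristine state
#'
#' Integrates the spectrum with zero fishing under constant forcing until the
#' relative change of total biomass per decade drops below `tol`. Unless an
#' initial state is supplied, the closed-form equilibrium seeds the
#' integration, so convergence is typically immediate; from arbitrary initial
#' states the integration runs until converged or `max_years`.
#'
#' @param T_c,npp Constant (climatological) forcing for the cell.
#' @param params,axis Model configuration.
#' @param tol Relative biomass change per decade at convergence.
#' @param max_years Give up (with an error reporting the residual) after this
#'   many years.
#' @param init Optional initial biomass matrix (group x bin).
#' @return List: `B` (group x bin), `pristine_biomass` (total g m^-2),
#'   `years` integrated.
#' @export
spinup_pristine <- function(T_c, npp, params, axis = mass_axis(),
                            tol = 1e-4, max_years = 500, init = NULL) {
  st <- stability_dt(params, axis, T_max = max(T_c, params$T_ref))
  if (is.null(init)) {
    B <- equilibrium_spectrum(T_c, npp, params, axis, dt = st$dt)[1, , ]
  } else {
    B <- init
  }
  total <- sum(B)
  yrs <- 0
  repeat {
    out <- fc_cpp_run(array(B, c(1, dim(B))), effort = 0,
                      sst = matrix(T_c, 1, 10), npp = matrix(npp, 1, 10),
                      q_year = rep(0, 10), price_year = rep(0, 10),
                      cost_year = rep(0, 10),
                      params = params, axis = axis, n_sub = st$n_sub,
                      effort_mode = 1L)
    B <- out$B[1, , ]
    yrs <- yrs + 10
    new_total <- sum(B)
    rel <- abs(new_total - total) / max(total, 1e-300)
    total <- new_total
    if (rel < tol) break
    if (yrs >= max_years) {
      stop(sprintf("pristine spin-up did not converge after %d years (residual %.3g per decade)",
                   yrs, rel), call. = FALSE)
    }
  }
  list(B = B, pristine_biomass = total, years = yrs)
}
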