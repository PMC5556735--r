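test_that("temperature factor matches the Arrhenius form", {
  expect_identical(temperature_factor(10, 0.45, 10), 1)
  # frozen value from independent hand evaluation of
  # exp(-0.45/8.617e-5 * (1/293.15 - 1/283.15))
  expect_equal(temperature_factor(20, 0.45, 10), 1.87615, tolerance = 1e-4)
  Ts <- seq(-2, 35, by = 0.5)
  expect_true(all(diff(temperature_factor(Ts, 0.45, 10)) > 0))
})

test_that("energy input converts and discounts NPP correctly", {
  p <- fc_params()
  expect_identical(energy_input(0, 15, p), 0)
  # eps = 1: no trophic loss, full converted NPP at the reference temperature
  p1 <- fc_params(eps_trophic = 1 - 1e-12)
  expect_equal(energy_input(30, p1$T_ref, p1),
               30 * 12.011e-3 * 365 * 10, tolerance = 1e-6)
  # eps = 0.1 over exactly three trophic steps -> factor 1e-3
  p3 <- fc_params(eps_trophic = 0.1, ppmr = 10^(10 / 3))
  p3$m_phyto <- 1e-9
  expect_equal(energy_input(30, p3$T_ref, p3),
               1e-3 * 30 * 12.011e-3 * 365 * 10, tolerance = 1e-9)
  # warming lowers the realized transfer
  expect_lt(energy_input(30, 25, p), energy_input(30, 10, p))
  # linear in npp
  expect_equal(energy_input(60, 18, p), 2 * energy_input(30, 18, p))
})

test_that("growth and mortality follow their allometric forms", {
  p <- fc_params(growth_A = 4.5, growth_b = 0.7, mort_zeta = 1.5, mort_h = 0.5)
  expect_identical(growth_rate(100, p$T_ref, p, food_limitation = 0), 0)
  expect_equal(growth_rate(100, p$T_ref, p), 4.5 * 100^0.7, tolerance = 1e-12)
  # allocation only ever reduces growth
  expect_lt(growth_rate(100, p$T_ref, p, psi = 0.5),
            growth_rate(100, p$T_ref, p))
  expect_equal(natural_mortality(10, p$T_ref, p), 1.5 * 10^-0.5,
               tolerance = 1e-12)
  expect_equal(natural_mortality(20, p$T_ref, p) /
                 natural_mortality(10, p$T_ref, p), 2^-0.5, tolerance = 1e-12)
  # h -> 1: mortality independent of mass
  ph <- fc_params(mort_h = 1 - 1e-12)
  expect_equal(natural_mortality(10, 10, ph), natural_mortality(1e4, 10, ph),
               tolerance = 1e-6)
})

test_that("recruitment saturates with the Beverton-Holt form", {
  p <- fc_params()
  axis <- mass_axis()
  B0 <- matrix(0, axis$n_groups, axis$n_bins)
  expect_equal(recruitment_flux(B0, 15, 30, p, axis)$R,
               rep(0, axis$n_groups))

  B <- matrix(0.05, axis$n_groups, axis$n_bins)
  out <- recruitment_flux(B, 15, 30, p, axis)
  # independent recomputation of the egg flux from its definition
  tau <- temperature_factor(15, p$Ea, p$T_ref)
  psi <- fishcast:::fc_psi(axis, p)
  mask <- fishcast:::fc_mask(axis)
  amb1 <- p$growth_A * tau * axis$m^(p$growth_b - 1)
  e_manual <- p$s_egg * out$xi *
    rowSums(t(t(B * mask * psi) * amb1))
  expect_equal(out$e, e_manual, tolerance = 1e-12)
  R_sat <- out$E_in / axis$n_groups
  expect_equal(out$R, R_sat * out$e / (out$e + p$recruit_K), tolerance = 1e-12)
  # monotone, bounded by R_sat
  out2 <- recruitment_flux(B * 10, 15, 30, p, axis)
  expect_true(all(out2$R >= out$R - 1e-12))
  expect_true(all(out2$R < R_sat))
})

test_that("pure mortality decays every bin exponentially", {
  # nearly massless growth, near-constant mortality (h ~ 1), no recruitment
  p <- fc_params(growth_A = 1e-9, mort_zeta = 0.7, mort_h = 1 - 1e-9,
                 s_egg = 1e-12)
  axis <- mass_axis()
  B <- matrix(runif(axis$n_groups * axis$n_bins, 0.01, 1),
              axis$n_groups, axis$n_bins) * fishcast:::fc_mask(axis)
  out <- step_ecology(B, p$T_ref, 30, F_mort = 0, dt = 0.5, params = p,
                      axis = axis)
  mask <- fishcast:::fc_mask(axis)
  expect_equal(out$B[mask], B[mask] * exp(-0.7 * 0.5), tolerance = 1e-6)
})

test_that("the step closes its mass budget to near round-off", {
  p <- fc_params()
  axis <- mass_axis()
  set.seed(42)
  B <- matrix(runif(axis$n_groups * axis$n_bins, 0, 2),
              axis$n_groups, axis$n_bins) * fishcast:::fc_mask(axis)
  for (Fm in c(0, 0.4)) {
    out <- step_ecology(B, 18, 40, F_mort = Fm, dt = 0.02, params = p,
                        axis = axis)
    lhs <- sum(out$B) - sum(B)
    rhs <- out$recruit_in - out$natural_loss - out$harvest - out$top_loss
    expect_lt(abs(lhs - rhs) / max(sum(B), 1), 1e-8)
  }
})

test_that("an inadmissible step is rejected with the stability limit", {
  p <- fc_params()
  axis <- mass_axis()
  B <- matrix(0.1, axis$n_groups, axis$n_bins)
  expect_error(step_ecology(B, 30, 40, 0, dt = 1, params = p, axis = axis),
               "stability")
})

test_that("positivity holds for admissible steps under heavy fishing", {
  p <- fc_params()
  axis <- mass_axis()
  st <- stability_dt(p, axis, T_max = 30)
  set.seed(7)
  B <- matrix(runif(axis$n_groups * axis$n_bins, 0, 5),
              axis$n_groups, axis$n_bins) * fishcast:::fc_mask(axis)
  for (i in 1:50) {
    out <- step_ecology(B, 28, 60, F_mort = 8, dt = st$dt, params = p,
                        axis = axis)
    B <- out$B
    expect_true(all(B >= 0))
  }
})

test_that("community energy acquisition never exceeds the energy input", {
  p <- fc_params()
  axis <- mass_axis()
  set.seed(11)
  for (i in 1:20) {
    B <- matrix(runif(axis$n_groups * axis$n_bins, 0, 10),
                axis$n_groups, axis$n_bins)
    rec <- recruitment_flux(B, runif(1, -2, 30), runif(1, 1, 100), p, axis)
    expect_lte(rec$xi * rec$demand, rec$E_in * (1 + 1e-12))
  }
})

test_that("the R step and the compiled integrator agree", {
  p <- fc_params()
  axis <- mass_axis()
  set.seed(3)
  B <- matrix(runif(axis$n_groups * axis$n_bins, 0, 1),
              axis$n_groups, axis$n_bins) * fishcast:::fc_mask(axis)
  E_fix <- 2e-5
  q <- 5000
  Fm <- q * E_fix * fishcast:::fc_sel(axis, p) * fishcast:::fc_mask(axis)
  n_sub <- 20L
  B_r <- B
  harv_r <- 0
  for (s in seq_len(n_sub)) {
    r_step <- step_ecology(B_r, 16, 35, Fm, dt = 1 / n_sub, params = p,
                           axis = axis)
    B_r <- r_step$B
    harv_r <- harv_r + r_step$harvest
  }
  cpp <- fishcast:::fc_cpp_run(array(B, c(1, dim(B))), effort = E_fix,
                               sst = matrix(16, 1, 1), npp = matrix(35, 1, 1),
                               q_year = q, price_year = 0, cost_year = 0,
                               params = p, axis = axis, n_sub = n_sub,
                               effort_mode = 1L)
  expect_equal(cpp$B[1, , ], B_r, tolerance = 1e-10)
  expect_equal(cpp$harvest[1, 1], harv_r, tolerance = 1e-8)
})

test_that("pristine spin-up behaves physically", {
  p <- fc_params()
  sp0 <- spinup_pristine(15, 0, p)
  expect_equal(sp0$pristine_biomass, 0, tolerance = 1e-12)

  sp1 <- spinup_pristine(15, 20, p)
  sp2 <- spinup_pristine(15, 60, p)
  expect_gt(sp2$pristine_biomass, sp1$pristine_biomass)

  # warmer water, same NPP: less standing biomass
  spw <- spinup_pristine(28, 20, p)
  expect_lt(spw$pristine_biomass, sp1$pristine_biomass)

  # independence from the initial condition
  axis <- mass_axis()
  B_alt <- matrix(0.5, axis$n_groups, axis$n_bins) * fishcast:::fc_mask(axis)
  tol <- 1e-4
  sp_alt <- spinup_pristine(15, 20, p, tol = tol, max_years = 2000,
                            init = B_alt)
  expect_equal(sp_alt$pristine_biomass, sp1$pristine_biomass,
               tolerance = 2 * tol * 10)

  # convergence threshold is not doing the work
  sp_loose <- spinup_pristine(15, 20, p, tol = 2e-4)
  expect_lt(abs(sp_loose$pristine_biomass - sp1$pristine_biomass) /
              sp1$pristine_biomass, 2e-3)
})
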