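test_that("selectivity is a logistic in log mass", {
  p <- fc_params()
  m_asym <- 1e4
  expect_equal(selectivity(p$sel_ratio * m_asym, m_asym, p), 0.5,
               tolerance = 1e-12)
  m <- exp(seq(log(10), log(1e5), length.out = 50))
  s <- selectivity(m, m_asym, p)
  expect_true(all(diff(s) > 0))
  expect_gt(selectivity(1e5, 1e5 * 0.2, p), 0.95)
  expect_lt(selectivity(10, 1e5, p), 0.05)
})

test_that("harvest is linear in catchability and sums over bins", {
  p <- fc_params()
  axis <- mass_axis()
  set.seed(5)
  B <- matrix(runif(axis$n_groups * axis$n_bins), axis$n_groups,
              axis$n_bins) * fishcast:::fc_mask(axis)
  h0 <- harvest_rate(B, effort = 0, q = 5000, p, axis)
  expect_identical(h0$h, 0)
  h1 <- harvest_rate(B, effort = 1e-5, q = 5000, p, axis)
  h2 <- harvest_rate(B, effort = 1e-5, q = 10000, p, axis)
  expect_equal(h2$h, 2 * h1$h, tolerance = 1e-12)
  # independent bin-by-bin summation
  sel <- fishcast:::fc_sel(axis, p)
  mask <- fishcast:::fc_mask(axis)
  manual <- 0
  for (g in seq_len(axis$n_groups)) {
    for (i in seq_len(axis$n_bins)) {
      manual <- manual + 5000 * 1e-5 * sel[g, i] * mask[g, i] * B[g, i]
    }
  }
  expect_equal(h1$h, manual, tolerance = 1e-12)
})

test_that("effort follows profit and respects the floor", {
  p <- fc_params()
  # bionomic equilibrium: zero profit leaves effort unchanged
  E <- 1e-5
  h <- p$cost0 * E * 1000 / p$price0   # revenue exactly offsets cost
  expect_equal(step_effort(E, h, p$price0, p$cost0, p, dt = 1), E,
               tolerance = 1e-12)
  # losses drive effort toward the floor
  E_decay <- step_effort(E, 0, p$price0, p$cost0, p, dt = 1)
  expect_lt(E_decay, E)
  for (i in 1:500) E_decay <- step_effort(E_decay, 0, p$price0, p$cost0, p, 0.5)
  expect_identical(E_decay, p$E_floor)
  # direct arithmetic: dE = k_e * profit * dt
  p2 <- fc_params(k_e = 1e-9)
  expect_equal(step_effort(0.5, 0.02 * 1000 / 1, 1, 0, p2, dt = 1) - 0.5,
               2e-11, tolerance = 1e-6)
})

test_that("technology schedules compound as specified", {
  p <- fc_params()
  scn <- scenario(tech_mode = "exponential", tech_rate = 0.05,
                  tech_t_ref = 1950)
  q <- catchability_schedule(scn, p, c(1950, 2000))
  expect_equal(q[1], p$q0)
  expect_equal(q[2] / q[1], 1.05^50, tolerance = 1e-12)
  expect_gte(q[2] / q[1], 10)   # an order of magnitude over 50 years

  none <- scenario(tech_mode = "constant")
  expect_true(all(catchability_schedule(none, p, 1950:2100) == p$q0))

  stab <- scenario(tech_mode = "stabilizing", tech_rate = 0.05,
                   tech_t_ref = 1950, ramp_start = 2006, ramp_end = 2036)
  yrs <- 1950:2100
  qs <- catchability_schedule(stab, p, yrs)
  # matches pure exponential until the ramp starts
  expect_equal(qs[yrs <= 2006], p$q0 * 1.05^(1950:2006 - 1950),
               tolerance = 1e-10)
  # independent product oracle over the ramp-down
  g <- 0.05 * (1 - (2006:2035 - 2006) / 30)
  expect_equal(qs[yrs == 2036] / qs[yrs == 2006], prod(1 + g),
               tolerance = 1e-10)
  # constant afterwards
  expect_true(all(qs[yrs >= 2036] == qs[yrs == 2036]))
})

test_that("price schedules hit the end-member values", {
  p <- fc_params()
  lin <- scenario(price_mode = "linear", p_start = 1, p_end = 3,
                  price_t_start = 2006, price_t_end = 2100)
  expect_equal(price_schedule(lin, p, 2006), 1)
  expect_equal(price_schedule(lin, p, 2100), 3)
  expect_equal(price_schedule(lin, p, 2053), 2)
  cst <- scenario(price_mode = "constant", p_start = 1.4)
  expect_true(all(price_schedule(cst, p, 1950:2100) == 1.4))
  tab <- scenario(price_mode = "table",
                  price_table = data.frame(year = c(1950, 2000),
                                           value = c(1, 2)))
  expect_equal(price_schedule(tab, p, 1975), 1.5)
})

test_that("steady-state cost identity inverts the effort equation", {
  cc <- cost_from_steady_state(1, 6e10, 1e10)
  expect_equal(cc, 6)
  expect_equal(cost_from_steady_state(2, 6e10, 1e10), 12)
  expect_error(cost_from_steady_state(1, 6e10, 0), "positive")
  # plugging the implied cost back in gives zero effort change
  p <- fc_params()
  E <- 1e-5
  h <- 0.3                      # g m^-2 yr^-1
  c_star <- cost_from_steady_state(p$price0, h / 1000, E)
  expect_equal(step_effort(E, h, p$price0, c_star, p, dt = 1), E,
               tolerance = 1e-12)
})

test_that("a profitable cell dissipates rent to the bionomic equilibrium", {
  p <- fc_params()
  scn <- scenario(tech_mode = "constant")
  tr <- run_cell(rich_cell$T_c, rich_cell$npp, years = 1:400, params = p,
                 scn = scn)
  late <- tr[tr$year > 380, ]
  revenue <- p$price0 * late$harvest / 1000
  cost <- p$cost0 * late$effort
  expect_lt(abs(mean(revenue / cost) - 1), 0.01)
  # equivalent statement on the exploitable stock:
  # price * q * B_sel / 1000 = cost, with B_sel = h / (q E)
  B_sel <- mean(late$harvest) / (p$q0 * mean(late$effort))
  expect_lt(abs(p$price0 * p$q0 * B_sel / 1000 / p$cost0 - 1), 0.01)
})

test_that("equilibrium biomass responds monotonically to economic drivers", {
  p <- fc_params()
  scn <- scenario(tech_mode = "constant")
  eq_biomass <- function(params, scn_use = scn) {
    tr <- run_cell(rich_cell$T_c, rich_cell$npp, years = 1:350,
                   params = params, scn = scn_use)
    mean(tr$biomass[tr$year > 330])
  }
  b_q <- vapply(c(0.6, 1, 1.8), function(f)
    eq_biomass(set_params(p, c(q0 = p$q0 * f))), numeric(1))
  expect_true(all(diff(b_q) < 1e-9))
  b_price <- vapply(c(0.7, 1, 1.5), function(f) {
    eq_biomass(p, scenario(tech_mode = "constant", price_mode = "constant",
                           p_start = f))
  }, numeric(1))
  expect_true(all(diff(b_price) < 1e-9))
  b_cost <- vapply(c(0.7, 1, 1.5), function(f) {
    pp <- p; pp$cost0 <- pp$cost0 * f
    eq_biomass(pp)
  }, numeric(1))
  expect_true(all(diff(b_cost) > -1e-9))
})
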