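test_that("a cell without catchability keeps its pristine state", {
  p <- fc_params(q0 = 1e-6)
  tr <- run_cell(14, 40, years = 1950:2010, params = p)
  expect_length(tr$year, 61)
  expect_true(all(tr$harvest < 1e-6))
  expect_true(all(abs(tr$biomass_fraction - 1) < 0.01))
})

test_that("richer cells support larger open-access equilibrium harvest", {
  p <- fc_params()
  scn <- scenario(tech_mode = "constant")
  eq_h <- function(npp) {
    tr <- run_cell(14, npp, years = 1:350, params = p, scn = scn)
    mean(tr$harvest[tr$year > 330])
  }
  expect_gt(eq_h(60), eq_h(30) * 1.05)
})

test_that("the global runner reproduces an independent single-cell run", {
  fs <- coarse_spec(noise_sd = 0, year_end = 1990)
  f <- generate_synthetic_forcing(fs)
  p <- fc_params()
  run <- run_hindcast(f, p)
  # pick a productive coastal cell and rerun it on its own
  oc <- f$grid[f$grid$ocean, ]
  j <- which.max(f$npp[, 1] * (abs(oc$lat) < 50))
  tr <- run_cell(f$sst[j, ], f$npp[j, ], years = f$years, params = p,
                 scn = scenario(tech_mode = "exponential", tech_rate = 0.05,
                                tech_t_ref = 1950))
  cellj <- run$cells[run$cells$cell == oc$cell[j], ]
  expect_equal(cellj$harvest, tr$harvest, tolerance = 1e-8)
  expect_equal(cellj$effort, tr$effort, tolerance = 1e-8)
})

test_that("global aggregation is the area-weighted sum of cells", {
  fs <- coarse_spec(year_end = 1980)
  f <- generate_synthetic_forcing(fs)
  run <- run_hindcast(f, fc_params())
  oc <- f$grid[f$grid$ocean, ]
  d <- run$cells[run$cells$year == 1975, ]
  manual <- sum(d$harvest * oc$area[match(d$cell, oc$cell)]) / 1e12
  expect_equal(run$global$harvest_Mt[run$global$year == 1975], manual,
               tolerance = 1e-10)
  expect_true(all(run$global$harvest_Mt >= 0))
})

test_that("hindcast drivers reproduce the observed-trend attribution", {
  fs <- coarse_spec()
  f <- generate_synthetic_forcing(fs)
  p <- fc_params()
  # technology off, constant price: no long-term increase after transient
  flat <- run_hindcast(f, p, tech_rate = 0)
  g <- flat$global[flat$global$year >= 1970, ]
  trend <- coef(lm(harvest_Mt ~ year, data = g))[["year"]]
  expect_lte(trend, 0.05)
  # 5 %/yr technology: the harvest rises and peaks inside the window
  tech <- run_hindcast(f, p, tech_rate = 0.05)
  gt <- tech$global[tech$global$year >= 1950, ]
  pk <- detect_peak(gt)
  expect_gt(pk$ratio, 2)
  expect_lt(pk$year, 2030)
  expect_false(pk$boundary)
})

test_that("fishing expands from the coast into the open ocean", {
  fs <- coarse_spec()
  f <- generate_synthetic_forcing(fs)
  run <- run_hindcast(f, fc_params())
  cs50 <- coastal_share(run$cells, run$grid, 1950)
  cs00 <- coastal_share(run$cells, run$grid, 2000)
  expect_lt(cs00, cs50)
  # productive coastal cells peak before low-productivity open-ocean cells
  oc <- f$grid[f$grid$ocean, ]
  peak_year <- vapply(split(run$cells, run$cells$cell), function(d) {
    if (max(d$harvest) < 1e-4) return(NA_real_)
    d$year[which.max(d$harvest)]
  }, numeric(1))
  peak_year <- peak_year[match(oc$cell, as.integer(names(peak_year)))]
  rich_coastal <- oc$coastal & f$npp[, 1] > quantile(f$npp[, 1], 0.75)
  poor_open <- !oc$coastal & f$npp[, 1] < quantile(f$npp[, 1], 0.5)
  expect_lt(mean(peak_year[rich_coastal], na.rm = TRUE),
            mean(peak_year[poor_open], na.rm = TRUE))
})

test_that("MSY is a quasi-static envelope consistent with brute force", {
  fs <- coarse_spec(year_end = 1880)
  f <- generate_synthetic_forcing(fs)
  p <- fc_params()
  m <- compute_msy(f, p)
  expect_false(m$boundary_flag)
  # global value is the area-weighted sum of cell maxima
  a <- f$grid$area[f$grid$ocean]
  expect_equal(m$global_Mt, sum(m$cells$msy * a) / 1e12, tolerance = 1e-10)

  # brute-force constant-F equilibrium oracle on five sample cells
  oc <- f$grid[f$grid$ocean, ]
  clim <- climatology(f)
  set.seed(1)
  idx <- sample(which(m$cells$msy > quantile(m$cells$msy, 0.5)), 5)
  F_levels <- exp(seq(log(0.05), log(15), length.out = 20))
  for (j in idx) {
    y <- equilibrium_yield(clim$sst[j, 1], clim$npp[j, 1],
                           F_levels, p, years = 250)
    # parabolic refinement of the grid maximum in log-F
    i0 <- min(max(which.max(y), 2), length(y) - 1)
    fit <- lm(y[i0 + (-1:1)] ~ poly(log(F_levels[i0 + (-1:1)]), 2, raw = TRUE))
    cf <- coef(fit)
    brute <- if (cf[3] < 0) {
      x_star <- -cf[2] / (2 * cf[3])
      cf[1] + cf[2] * x_star + cf[3] * x_star^2
    } else {
      max(y)
    }
    expect_lt(abs(m$cells$msy[j] - brute) / brute, 0.05)
  }
})

test_that("MSY does not depend on price or cost", {
  fs <- coarse_spec(year_end = 1880)
  f <- generate_synthetic_forcing(fs)
  p <- fc_params()
  m0 <- compute_msy(f, p)
  p_hi <- p; p_hi$price0 <- p$price0 * 1.5; p_hi$cost0 <- p$cost0 * 0.5
  p_lo <- p; p_lo$price0 <- p$price0 * 0.5; p_lo$cost0 <- p$cost0 * 1.5
  expect_equal(compute_msy(f, p_hi)$global_Mt, m0$global_Mt, tolerance = 1e-12)
  expect_equal(compute_msy(f, p_lo)$global_Mt, m0$global_Mt, tolerance = 1e-12)
})

test_that("cells with no production contribute nothing to MSY", {
  fs <- coarse_spec(year_end = 1880)
  f <- generate_synthetic_forcing(fs)
  f$npp[3, ] <- 0
  m <- compute_msy(f, fc_params())
  expect_equal(m$cells$msy[3], 0, tolerance = 1e-15)
})

test_that("climate trends lower the production ceiling", {
  p <- fc_params()
  f0 <- generate_synthetic_forcing(coarse_spec(year_end = 1880))
  m0 <- compute_msy(f0, p)
  f1 <- generate_synthetic_forcing(
    coarse_spec(year_end = 1880, warming_trend = 3, npp_trend = -15))
  clim_late <- climatology(f1, years = 1871:1880)
  m1 <- compute_msy(clim_late, p, clim_years = clim_late$years)
  expect_lt(m1$global_Mt, m0$global_Mt)
})

test_that("projection scenarios keep their qualitative ordering", {
  fs <- coarse_spec(year_end = 2100)
  f <- generate_synthetic_forcing(fs)
  p <- fc_params()
  stab <- run_projection(f, p, "stabilizing", "constant")
  cont <- run_projection(f, p, "exponential", "constant")
  plin <- run_projection(f, p, "exponential", "linear")

  # technology stabilization: harvest plateaus (drift < 1 %/decade post-2050)
  g <- stab$global[stab$global$year >= 2050, ]
  drift <- coef(lm(log(g$harvest_Mt) ~ g$year))[[2]] * 10
  expect_lt(abs(drift), 0.01)

  # continued technological progress: late-century harvest below its peak
  gc <- cont$global[cont$global$year >= 1950, ]
  pk <- detect_peak(gc)
  late <- mean(gc$harvest_Mt[gc$year >= 2090])
  expect_lt(late, 0.8 * pk$value)

  # rising prices intensify depletion
  bf_cont <- mean(cont$global$biomass_fraction[cont$global$year >= 2090])
  bf_plin <- mean(plin$global$biomass_fraction[plin$global$year >= 2090])
  expect_lt(bf_plin, bf_cont)
})
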